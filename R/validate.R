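#' Observed biopsy positive rates by biopsy round
#'
#' Orders each patient's non-missing biopsies and tabulates, for the first,
#' second, ... round, how many patients were biopsied and how many results
#' were Gleason >= 7. Rounds with zero biopsies are omitted.
#'
#' @param cohort An [as_cohort()] object.
#' @return `data.frame` with columns `round`, `n_biopsied`, `n_positive`,
#'   `rate`.
#' @export
biopsy_positive_rates <- function(cohort) {
  validate_cohort(cohort)
  obs <- cohort$observations
  obs <- obs[!is.na(obs$biopsy), , drop = FALSE]
  if (nrow(obs) == 0)
    return(data.frame(round = integer(), n_biopsied = integer(),
                      n_positive = integer(), rate = numeric()))
  obs <- obs[order(obs$patient_id, obs$year), , drop = FALSE]
  round_idx <- stats::ave(rep(1L, nrow(obs)), obs$patient_id, FUN = cumsum)
  pos <- obs$biopsy == "GS7_PLUS"
  n_biopsied <- tapply(pos, round_idx, length)
  n_positive <- tapply(pos, round_idx, sum)
  data.frame(round = as.integer(names(n_biopsied)),
             n_biopsied = as.integer(n_biopsied),
             n_positive = as.integer(n_positive),
             rate = as.numeric(n_positive / n_biopsied),
             row.names = NULL)
}

#' Observed versus model-simulated biopsy positive rates
#'
#' Internal-validation diagnostic: simulates `n_sim` replicate cohorts from
#' the model (same number of patients, same follow-up horizon, biopsy offer
#' years from `protocol`, missingness rates estimated from the observed
#' cohort) and compares the observed per-round biopsy positive rates with
#' the simulated mean and a 2.5/97.5 percentile band across replicates.
#' A well-calibrated model keeps the observed rates inside the bands.
#'
#' @param cohort The observed (or held-out) [as_cohort()].
#' @param params [hmm_params()] fitted on, or compatible with, the cohort.
#' @param protocol [biopsy_protocol()] of biopsy offer years; default
#'   annual.
#' @param n_sim Number of replicate simulated cohorts.
#' @param seed Integer seed.
#' @return `data.frame` with one row per biopsy round observed in the
#'   cohort: `round`, `n_biopsied`, `observed`, `simulated_mean`,
#'   `lower`, `upper` (percentile band) and `outside` (flag).
#' @export
compare_observed_simulated <- function(cohort, params,
                                       protocol = biopsy_protocol("jh"),
                                       n_sim = 200, seed = 1) {
  validate_cohort(cohort)
  validate_hmm_params(params)
  obs_rates <- biopsy_positive_rates(cohort)
  if (nrow(obs_rates) == 0) stop("cohort contains no biopsies")
  horizon <- max(cohort$observations$year)
  sched_years <- protocol$years[protocol$years <= horizon]
  on_sched <- cohort$observations$year %in% sched_years
  p_miss_bio <- if (any(on_sched))
    mean(is.na(cohort$observations$biopsy[on_sched])) else 0
  p_miss_bio <- min(p_miss_bio, 0.95)
  p_miss_psa <- mean(is.na(cohort$observations$log_psa))
  n <- n_patients(cohort)
  rounds <- obs_rates$round
  sim_rates <- matrix(NA_real_, n_sim, length(rounds))
  for (s in seq_len(n_sim)) {
    g <- generate_cohort(params, n_patients = n,
                         schedule = biopsy_protocol(protocol$name,
                                                    years = sched_years),
                         max_followup = horizon,
                         p_missing_biopsy = p_miss_bio,
                         p_missing_psa = p_miss_psa,
                         seed = seed + s - 1)
    r <- biopsy_positive_rates(g$cohort)
    sim_rates[s, ] <- r$rate[match(rounds, r$round)]
  }
  sim_mean <- colMeans(sim_rates, na.rm = TRUE)
  lower <- apply(sim_rates, 2, quantile, 0.025, na.rm = TRUE)
  upper <- apply(sim_rates, 2, quantile, 0.975, na.rm = TRUE)
  data.frame(round = rounds, n_biopsied = obs_rates$n_biopsied,
             observed = obs_rates$rate, simulated_mean = sim_mean,
             lower = lower, upper = upper,
             outside = obs_rates$rate < lower | obs_rates$rate > upper)
}

#' Observed versus fitted log-PSA densities by risk state
#'
#' Groups observed log-PSA values by hidden state — using the ground truth
#' of a synthetic cohort when supplied, otherwise soft-assigning each
#' observation by its smoothed posterior probability of the non-favorable
#' state — and compares a weighted histogram density against the fitted
#' per-state mixture. The distance reported per state is the total
#' variation distance between the binned empirical and fitted
#' probabilities (0 = identical, 1 = disjoint).
#'
#' @param cohort An [as_cohort()] object.
#' @param params [hmm_params()] with the fitted mixtures.
#' @param truth Optional ground-truth `data.frame` (`patient_id`, `year`,
#'   `state`) as returned by [generate_cohort()].
#' @param breaks Number of histogram bins.
#' @return A list of class `psa_density_compare`: per state a `data.frame`
#'   (`mid`, `empirical`, `fitted` densities) plus `distance` (named
#'   numeric, total variation per state) and `weights` (per-observation
#'   state weights, each row summing to 1).
#' @export
psa_density_compare <- function(cohort, params, truth = NULL, breaks = 40) {
  validate_cohort(cohort)
  validate_hmm_params(params)
  obs <- cohort$observations
  keep <- !is.na(obs$log_psa)
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0) stop("cohort contains no PSA observations")
  if (!is.null(truth)) {
    key <- paste(truth$patient_id, truth$year)
    st <- setNames(truth$state, key)[paste(obs$patient_id, obs$year)]
    w_nfr <- as.numeric(st == "NFR")
  } else {
    fb <- forward_backward(params, cohort)
    post <- do.call(rbind, lapply(names(fb), function(id) {
      p <- fb[[id]]$posterior
      data.frame(key = paste(id, p$year), p_nfr = p$p_nfr)
    }))
    w_nfr <- setNames(post$p_nfr, post$key)[paste(obs$patient_id, obs$year)]
  }
  x <- obs$log_psa
  br <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = breaks + 1)
  mid <- (br[-1] + br[-length(br)]) / 2
  wd <- diff(br)
  one_state <- function(w, mix) {
    tot <- sum(w)
    emp <- vapply(seq_len(breaks), function(b)
      sum(w[x >= br[b] & x < br[b + 1]]), 0)
    p_emp <- if (tot > 0) emp / tot else rep(NA_real_, breaks)
    p_fit <- mix$weight * diff(pnorm(br, mix$mu1, mix$sigma1)) +
      (1 - mix$weight) * diff(pnorm(br, mix$mu2, mix$sigma2))
    p_fit <- p_fit / sum(p_fit)
    list(tab = data.frame(mid = mid, empirical = p_emp / wd,
                          fitted = p_fit / wd),
         tv = 0.5 * sum(abs(p_emp - p_fit)))
  }
  fr <- one_state(1 - w_nfr, params$psa_fr)
  nfr <- one_state(w_nfr, params$psa_nfr)
  structure(list(FR = fr$tab, NFR = nfr$tab,
                 distance = c(FR = fr$tv, NFR = nfr$tv),
                 weights = data.frame(patient_id = obs$patient_id,
                                      year = obs$year,
                                      w_fr = 1 - w_nfr, w_nfr = w_nfr)),
            class = "psa_density_compare")
}

#' @export
print.psa_density_compare <- function(x, ...) {
  cat("Observed vs fitted log-PSA densities\n")
  cat(sprintf("  total variation distance: FR %.3f, NFR %.3f\n",
              x$distance["FR"], x$distance["NFR"]))
  invisible(x)
}

#' @export
plot.psa_density_compare <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (s in c("FR", "NFR")) {
    tab <- x[[s]]
    plot(tab$mid, tab$empirical, type = "h", lwd = 3, col = "grey70",
         xlab = "log PSA", ylab = "density", main = s, ...)
    lines(tab$mid, tab$fitted, lwd = 2)
  }
  invisible(x)
}
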