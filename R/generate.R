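#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Forward-samples the active-surveillance HMM to produce a cohort with the
#' same structure as real surveillance extracts: annual observation slots,
#' state-dependent log-PSA and biopsy emissions with non-informative
#' missingness, three absorbing exit types, and administrative censoring at
#' the end of follow-up. The hidden state paths are returned alongside the
#' observable cohort, providing ground truth for estimation and validation
#' tests.
#'
#' Sampling follows the likelihood convention exactly: for each year the
#' transition (including possible exit) is drawn first; an exit replaces
#' that year's observation slot; a surviving patient emits a biopsy result
#' in scheduled years (offered biopsies are skipped with probability
#' `p_missing_biopsy`) and a log-PSA value (missing with probability
#' `p_missing_psa`). Patients still transient after `max_followup` years are
#' censored.
#'
#' @param params An [hmm_params()] object (the generator truth).
#' @param n_patients Number of patients.
#' @param schedule A [biopsy_protocol()] giving the years in which a biopsy
#'   is offered; default annual.
#' @param max_followup Administrative censoring horizon in years.
#' @param p_missing_biopsy,p_missing_psa Probabilities that an offered
#'   biopsy / a PSA measurement is missing (state-independent).
#' @param seed Integer seed.
#' @param name Cohort label.
#' @return A list of class `as_cohort_sim` with `cohort` (an [as_cohort()];
#'   `baseline_grade_group` is 1 throughout) and `truth` (`data.frame` of
#'   `patient_id`, `year` (0 = diagnosis), `state`).
#' @export
#' @examples
#' g <- generate_cohort(cohort_params("jh"), n_patients = 50, seed = 1)
#' g$cohort
#' head(g$truth)
generate_cohort <- function(params, n_patients,
                            schedule = biopsy_protocol("jh"),
                            max_followup = 10,
                            p_missing_biopsy = 0.2, p_missing_psa = 0.1,
                            seed = 1, name = "synthetic") {
  validate_hmm_params(params)
  stopifnot(inherits(schedule, "biopsy_protocol"), n_patients >= 1,
            p_missing_biopsy >= 0, p_missing_biopsy <= 1,
            p_missing_psa >= 0, p_missing_psa <= 1, max_followup >= 1)
  set.seed(seed)
  n <- as.integer(n_patients)
  ids <- sprintf("P%05d", seq_len(n))

  # state codes: 1 FR, 2 NFR, 3 RP_FAVORABLE, 4 RP_NONFAVORABLE, 5 NO_RP
  state <- ifelse(runif(n) < params$pi_nfr, 2L, 1L)
  truth_state <- matrix(NA_integer_, n, max_followup + 1)
  truth_state[, 1] <- state
  exit_kind <- rep(NA_character_, n)
  exit_year <- rep(NA_integer_, n)
  obs <- vector("list", max_followup)

  draw_mix <- function(mix, m) {
    comp1 <- runif(m) < mix$weight
    ifelse(comp1, rnorm(m, mix$mu1, mix$sigma1), rnorm(m, mix$mu2, mix$sigma2))
  }

  for (t in seq_len(max_followup)) {
    active <- state <= 2L
    if (!any(active)) break
    u <- runif(n)
    fr <- active & state == 1L
    nfr <- active & state == 2L
    new_state <- state
    # favorable row: [stay, progress, RP fav, no RP]
    p1 <- params$apr; p2 <- p1 + params$exit_fr_rp; p3 <- p2 + params$exit_fr_norp
    new_state[fr & u < p1] <- 2L
    new_state[fr & u >= p1 & u < p2] <- 3L
    new_state[fr & u >= p2 & u < p3] <- 5L
    # non-favorable row: [stay, RP non-fav, no RP]
    q1 <- params$exit_nfr_rp; q2 <- q1 + params$exit_nfr_norp
    new_state[nfr & u < q1] <- 4L
    new_state[nfr & u >= q1 & u < q2] <- 5L
    state <- new_state
    truth_state[, t + 1][active] <- state[active]

    exited <- active & state > 2L
    exit_year[exited] <- t
    exit_kind[exited] <- c("RP_FAVORABLE", "RP_NONFAVORABLE",
                           "NO_RP")[state[exited] - 2L]

    alive <- state <= 2L
    m <- sum(alive)
    if (m == 0) next
    biopsy <- rep(NA_character_, m)
    if (t %in% schedule$years) {
      done <- runif(m) >= p_missing_biopsy
      st <- state[alive]
      p_pos <- ifelse(st == 2L, params$sens, 1 - params$spec)
      pos <- runif(m) < p_pos
      biopsy[done] <- ifelse(pos[done], "GS7_PLUS", "GS6_OR_LESS")
    }
    lpsa <- ifelse(state[alive] == 2L, draw_mix(params$psa_nfr, m),
                   draw_mix(params$psa_fr, m))
    lpsa[runif(m) < p_missing_psa] <- NA_real_
    obs[[t]] <- data.frame(patient_id = ids[alive], year = t,
                           log_psa = lpsa, biopsy = biopsy,
                           stringsAsFactors = FALSE)
  }
  cens <- state <= 2L
  exit_kind[cens] <- "CENSORED"
  exit_year[cens] <- max_followup

  observations <- do.call(rbind, obs[!vapply(obs, is.null, TRUE)])
  patients <- data.frame(patient_id = ids, baseline_grade_group = 1L,
                         exit_kind = exit_kind, exit_year = exit_year,
                         stringsAsFactors = FALSE)
  cohort <- as_cohort(observations, patients, name = name)

  keep <- !is.na(truth_state)
  truth <- data.frame(patient_id = ids[row(truth_state)[keep]],
                      year = col(truth_state)[keep] - 1L,
                      state = c("FR", "NFR", "RP_FAVORABLE",
                                "RP_NONFAVORABLE", "NO_RP")[truth_state[keep]],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$patient_id, truth$year), ]
  rownames(truth) <- NULL
  structure(list(cohort = cohort, truth = truth,
                 params = params, seed = seed),
            class = "as_cohort_sim")
}

#' @export
print.as_cohort_sim <- function(x, ...) {
  cat("Synthetic cohort with ground truth\n")
  print(x$cohort)
  invisible(x)
}

#' Empirical frequencies of a synthetic cohort against its generator
#'
#' Tallies the observable and hidden-state frequencies of a generated
#' cohort: initial non-favorable fraction, one-year FR to NFR progression
#' frequency, per-source exit frequencies, biopsy positive rates given the
#' true state, and the first two moments of observed log PSA by true state.
#' Used to check that the generator honors its configured parameters.
#'
#' @param sim An `as_cohort_sim` from [generate_cohort()], or a list with
#'   `cohort` and `truth` in the same format.
#' @return A `data.frame` with columns `statistic`, `value` and `n` (the
#'   number of Bernoulli trials or values behind each frequency).
#' @export
empirical_summaries <- function(sim) {
  cohort <- sim$cohort; truth <- sim$truth
  validate_cohort(cohort)
  key <- function(id, yr) paste(id, yr, sep = "\r")
  st <- setNames(truth$state, key(truth$patient_id, truth$year))
  prev <- st[key(truth$patient_id, truth$year - 1L)]
  from_fr <- !is.na(prev) & prev == "FR"
  from_nfr <- !is.na(prev) & prev == "NFR"
  obs <- cohort$observations
  obs_state <- st[key(obs$patient_id, obs$year)]
  bio <- !is.na(obs$biopsy)
  psa <- !is.na(obs$log_psa)
  row <- function(statistic, num, den) {
    data.frame(statistic = statistic,
               value = if (den > 0) num / den else NA_real_, n = den)
  }
  out <- rbind(
    row("initial_nfr", sum(truth$state[truth$year == 0] == "NFR"),
        sum(truth$year == 0)),
    row("fr_to_nfr", sum(from_fr & st == "NFR"), sum(from_fr)),
    row("fr_exit_rp", sum(from_fr & st == "RP_FAVORABLE"), sum(from_fr)),
    row("fr_exit_norp", sum(from_fr & st == "NO_RP"), sum(from_fr)),
    row("nfr_exit_rp", sum(from_nfr & st == "RP_NONFAVORABLE"), sum(from_nfr)),
    row("nfr_exit_norp", sum(from_nfr & st == "NO_RP"), sum(from_nfr)),
    row("biopsy_pos_given_nfr",
        sum(bio & obs_state == "NFR" & obs$biopsy == "GS7_PLUS"),
        sum(bio & obs_state == "NFR")),
    row("biopsy_neg_given_fr",
        sum(bio & obs_state == "FR" & obs$biopsy == "GS6_OR_LESS"),
        sum(bio & obs_state == "FR")),
    row("mean_log_psa_fr", sum(obs$log_psa[psa & obs_state == "FR"]),
        sum(psa & obs_state == "FR")),
    row("mean_log_psa_nfr", sum(obs$log_psa[psa & obs_state == "NFR"]),
        sum(psa & obs_state == "NFR")))
  rownames(out) <- NULL
  out
}
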