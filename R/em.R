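#' Control settings for Baum-Welch estimation
#'
#' @param n_restarts Number of independent EM runs from randomized starting
#'   points (local-maximum insurance). Default 20.
#' @param max_iter Maximum EM iterations per run. Default 500.
#' @param rel_tol Stopping rule: relative change in the cohort log-likelihood
#'   below this value ends a run. Default `1e-6`.
#' @param seed Integer seed; restart `r` draws its starting point from
#'   `seed + r`, so results are reproducible and independent of patient
#'   order.
#' @param short_iter Iteration budget of the exploratory phase: every restart
#'   first runs `short_iter` EM iterations, then only the best of the
#'   restarts is iterated to convergence. Set `short_iter = max_iter` to run
#'   every restart to convergence.
#' @param var_floor Lower bound on mixture component variances (degeneracy
#'   guard). Default `1e-4`.
#' @param start_box Ranges for the random starting points, a list with
#'   elements `rate` (initial/progression/exit probabilities), `sens` and
#'   `spec`.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_restarts = 20, max_iter = 500, rel_tol = 1e-6,
                        seed = 1, short_iter = 40, var_floor = 1e-4,
                        start_box = list(rate = c(0.005, 0.3),
                                         sens = c(0.5, 0.95),
                                         spec = c(0.9, 0.999))) {
  stopifnot(n_restarts >= 1, max_iter >= 1, rel_tol > 0, short_iter >= 1)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed), short_iter = as.integer(short_iter),
                 var_floor = var_floor, start_box = start_box),
            class = "fit_control")
}

# Random valid starting point. Probabilities are drawn uniformly on the
# configured boxes; both mixtures are initialized from the cohort's log-PSA
# quartiles with jitter, leaving the state assignment to the EM iterations.
random_start <- function(cohort_psa, box) {
  rate <- function() runif(1, box$rate[1], box$rate[2])
  q <- if (length(cohort_psa) >= 4) {
    quantile(cohort_psa, c(0.25, 0.75), names = FALSE)
  } else c(1.2, 2.0)
  s0 <- if (length(cohort_psa) >= 4) max(sd(cohort_psa) / 2, 0.05) else 0.4
  mixture <- function() {
    psa_mixture(runif(1, 0.35, 0.65),
                q[1] + rnorm(1, 0, 0.1), q[2] + rnorm(1, 0, 0.1),
                s0 * exp(rnorm(1, 0, 0.2)), s0 * exp(rnorm(1, 0, 0.2)))
  }
  hmm_params(pi_nfr = rate(), apr = rate(),
             exit_fr_rp = rate() / 3, exit_fr_norp = rate() / 3,
             exit_nfr_rp = rate() / 3, exit_nfr_norp = rate() / 3,
             sens = runif(1, box$sens[1], box$sens[2]),
             spec = runif(1, box$spec[1], box$spec[2]),
             psa_fr = mixture(), psa_nfr = mixture())
}

#' Expectation step of Baum-Welch
#'
#' Runs the forward-backward recursions at the current parameters and
#' returns the expected sufficient statistics of the complete-data
#' log-likelihood: expected initial-state occupancy, expected transient
#' transition counts (FR-FR, FR-NFR, NFR-NFR), expected transitions into
#' each leaving state by source state, expected biopsy-outcome counts by
#' state, and per-observation mixture-component responsibilities for the
#' observed PSA values. Null observations contribute no emission counts.
#'
#' @param params An [hmm_params()] object.
#' @param cohort An [as_cohort()] object.
#' @return A list of class `em_stats` with elements `loglik`, `n_patients`,
#'   `counts` (8 expected transition/occupancy counts), `biopsy` (4 expected
#'   outcome counts), `psa` (aggregated responsibility moments used by
#'   [m_step()]) and `responsibilities` (per observed PSA value: patient,
#'   year, and the four state-component responsibilities, which sum to 1).
#' @export
e_step <- function(params, cohort) {
  validate_hmm_params(params)
  a <- cohort_arrays(cohort)
  fb <- cpp_fb(a$nobs, a$exit_code, a$biopsy, a$psa, param_vector(params))
  has_psa <- !is.na(a$psa)
  x <- a$psa[has_psa]
  g_nfr <- fb$gamma[has_psa]
  comp_d <- function(mix, x) cbind(mix$weight * dnorm(x, mix$mu1, mix$sigma1),
                                   (1 - mix$weight) * dnorm(x, mix$mu2, mix$sigma2))
  df <- comp_d(params$psa_fr, x)
  dn <- comp_d(params$psa_nfr, x)
  rf <- (1 - g_nfr) * df / pmax(rowSums(df), .Machine$double.xmin)
  rn <- g_nfr * dn / pmax(rowSums(dn), .Machine$double.xmin)
  resp <- data.frame(patient_id = a$obs_patient[has_psa],
                     year = a$obs_year[has_psa], log_psa = x,
                     fr.1 = rf[, 1], fr.2 = rf[, 2],
                     nfr.1 = rn[, 1], nfr.2 = rn[, 2])
  structure(list(loglik = fb$loglik, n_patients = length(a$nobs),
                 counts = fb$counts, biopsy = fb$biopsy, psa = fb$psa,
                 responsibilities = resp),
            class = "em_stats")
}

#' Maximization step of Baum-Welch
#'
#' Closed-form updates from expected counts: ratio estimates for the initial
#' distribution, progression and exit probabilities and biopsy
#' sensitivity/specificity, and responsibility-weighted means/variances for
#' the per-state PSA mixtures (variances floored at `var_floor`). A state
#' with (numerically) zero expected occupancy keeps its previous emission
#' parameters, with a warning.
#'
#' @param stats An `em_stats` object from [e_step()].
#' @param prev_params The parameters the statistics were computed at (used as
#'   fall-back for unidentified components).
#' @param var_floor Variance floor; default `1e-4`.
#' @return An [hmm_params()] object.
#' @export
m_step <- function(stats, prev_params, var_floor = 1e-4) {
  stopifnot(inherits(stats, "em_stats"))
  validate_hmm_params(prev_params)
  up <- cpp_m_step(stats[c("counts", "biopsy", "psa", "n_patients")],
                   param_vector(prev_params), var_floor)
  if (isTRUE(up$held))
    warning("a state had zero expected occupancy; emission parameters held")
  params_from_vector(up$par)
}

#' Fit the active-surveillance HMM by Baum-Welch
#'
#' Maximum-likelihood estimation of the full parameter set
#' (misclassification at diagnosis, annual progression rate, exit
#' probabilities, biopsy sensitivity/specificity, per-state log-PSA
#' mixtures) from a longitudinal cohort, by the Baum-Welch EM algorithm with
#' random multi-restart: each restart runs a short exploratory EM phase from
#' a randomized valid starting point, and the restart with the best
#' log-likelihood is then iterated to convergence. The run with the largest
#' final log-likelihood is returned. Mixture components are reported in the
#' `mu1 <= mu2` order.
#'
#' The cohort should normally have passed [filter_baseline_favorable()]
#' first, so that the initial distribution estimates misclassification among
#' patients enrolled as favorable risk.
#'
#' @param cohort An [as_cohort()] object.
#' @param control A [fit_control()] list.
#' @param start Optional [hmm_params()] used as an additional (warm)
#'   starting point, e.g. the point estimate when refitting bootstrap
#'   resamples.
#' @return An object of class `as_hmm` with components `params`
#'   ([hmm_params()]), `log_likelihood`, `loglik_trace` (of the winning
#'   run), `restart_logliks`, `converged`, `n_patients`, `n_obs` and
#'   `control`. Methods: [print()], [summary()], [coef()], [logLik()],
#'   [predict()] (posterior state probabilities), [simulate()] (synthetic
#'   cohorts from the fitted parameters) and [plot()].
#' @seealso [bootstrap_hmm()], [generate_cohort()]
#' @export
#' @examples
#' truth <- cohort_params("jh")
#' sim <- generate_cohort(truth, n_patients = 300, seed = 7)
#' f <- fit_hmm(sim$cohort, fit_control(n_restarts = 3, seed = 1))
#' coef(f)[c("pi_nfr", "apr", "sens", "spec")]
fit_hmm <- function(cohort, control = fit_control(), start = NULL) {
  stopifnot(inherits(control, "fit_control"))
  a <- cohort_arrays(cohort)
  psa_obs <- a$psa[!is.na(a$psa)]
  run_em <- function(par0, iters) {
    cpp_em(a$nobs, a$exit_code, a$biopsy, a$psa, par0,
           as.integer(iters), control$rel_tol, control$var_floor)
  }
  starts <- vector("list", control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    set.seed(control$seed + r)
    starts[[r]] <- random_start(psa_obs, control$start_box)
  }
  if (!is.null(start)) {
    validate_hmm_params(start)
    starts <- c(list(start), starts)
  }
  short <- lapply(starts, function(s) {
    tryCatch(run_em(param_vector(s), min(control$short_iter, control$max_iter)),
             error = function(e) NULL)
  })
  lls <- vapply(short, function(z) if (is.null(z)) -Inf else z$loglik, 0)
  if (all(!is.finite(lls)))
    stop("all EM restarts failed with non-finite likelihood; ",
         "check the cohort for degenerate sequences")
  best <- which.max(lls)
  fin <- run_em(short[[best]]$par, control$max_iter)
  trace <- c(short[[best]]$trace,
             if (fin$iterations > 1) fin$trace[-1] else NULL)
  restart_logliks <- lls
  restart_logliks[best] <- fin$loglik
  structure(list(params = params_from_vector(fin$par),
                 log_likelihood = fin$loglik,
                 loglik_trace = trace,
                 restart_logliks = restart_logliks,
                 converged = isTRUE(fin$converged),
                 emission_held = isTRUE(fin$emission_held),
                 n_patients = length(a$nobs),
                 n_obs = length(a$biopsy),
                 cohort_name = cohort$name,
                 control = control,
                 call = match.call()),
            class = "as_hmm")
}
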