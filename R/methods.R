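#' @export
print.as_hmm <- function(x, ...) {
  cat("Active-surveillance HMM fit (Baum-Welch)\n")
  cat(sprintf("  cohort: %s (%d patients, %d patient-years)\n",
              x$cohort_name, x$n_patients, x$n_obs))
  cat(sprintf("  log-likelihood: %.3f (%d restarts, converged: %s)\n",
              x$log_likelihood, length(x$restart_logliks), x$converged))
  p <- x$params
  cat(sprintf("  misclassification at diagnosis: %5.2f%%\n", 100 * p$pi_nfr))
  cat(sprintf("  annual progression rate:        %5.2f%%\n", 100 * p$apr))
  cat(sprintf("  biopsy sensitivity:             %5.2f%%\n", 100 * p$sens))
  cat(sprintf("  biopsy specificity:             %5.2f%%\n", 100 * p$spec))
  invisible(x)
}

#' @export
summary.as_hmm <- function(object, boot = NULL, ...) {
  est <- param_vector(object$params)
  tab <- data.frame(estimate = est)
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "hmm_boot"))
    tab$se <- boot$se[rownames(tab)]
    tab$ci_lo <- boot$ci95[1, rownames(tab)]
    tab$ci_hi <- boot$ci95[2, rownames(tab)]
  }
  out <- list(coefficients = tab, log_likelihood = object$log_likelihood,
              n_patients = object$n_patients, n_obs = object$n_obs,
              converged = object$converged,
              restart_logliks = object$restart_logliks,
              cohort_name = object$cohort_name)
  class(out) <- "summary.as_hmm"
  out
}

#' @export
print.summary.as_hmm <- function(x, digits = 4, ...) {
  cat(sprintf("Active-surveillance HMM fit: cohort %s, %d patients\n",
              x$cohort_name, x$n_patients))
  cat(sprintf("log-likelihood %.3f; best of %d restarts (spread %.3f); converged: %s\n\n",
              x$log_likelihood, length(x$restart_logliks),
              diff(range(x$restart_logliks[is.finite(x$restart_logliks)])),
              x$converged))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.as_hmm <- function(object, ...) param_vector(object$params)

#' @export
logLik.as_hmm <- function(object, ...) {
  structure(object$log_likelihood, df = 18L, nobs = object$n_patients,
            class = "logLik")
}

#' Posterior state probabilities for a cohort
#'
#' @param object A fitted `as_hmm` model.
#' @param cohort The cohort to smooth; by default posteriors are computed
#'   with the fitted parameters, so pass the fitting cohort for in-sample
#'   smoothing.
#' @param ... Unused.
#' @return See [forward_backward()].
#' @export
predict.as_hmm <- function(object, cohort, ...) {
  forward_backward(object$params, cohort)
}

#' Simulate synthetic cohorts from a fitted model
#'
#' @param object A fitted `as_hmm` model.
#' @param nsim Number of cohorts.
#' @param seed Integer seed; cohort `i` uses `seed + i - 1`.
#' @param n_patients Patients per cohort; defaults to the fitted cohort
#'   size.
#' @param ... Passed to [generate_cohort()] (e.g. `schedule`,
#'   `max_followup`, missingness probabilities).
#' @return A list of [generate_cohort()] results (cohort plus ground truth);
#'   a single result if `nsim = 1`.
#' @export
simulate.as_hmm <- function(object, nsim = 1, seed = 1,
                            n_patients = object$n_patients, ...) {
  out <- lapply(seq_len(nsim), function(i)
    generate_cohort(object$params, n_patients = n_patients,
                    seed = seed + i - 1, ...))
  if (nsim == 1) out[[1]] else out
}

#' Plot the EM log-likelihood trace of a fit
#'
#' Left panel: per-iteration cohort log-likelihood of the winning run (EM
#' guarantees a non-decreasing trace). Right panel: final log-likelihoods of
#' all restarts, a visual check for local maxima.
#'
#' @param x A fitted `as_hmm` model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.as_hmm <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "l",
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "winning run", ...)
  ll <- x$restart_logliks[is.finite(x$restart_logliks)]
  plot(seq_along(ll), sort(ll), pch = 19, xlab = "restart (sorted)",
       ylab = "final log-likelihood", main = "restarts")
  abline(h = x$log_likelihood, lty = 2)
  invisible(x)
}
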