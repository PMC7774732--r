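# Patient-level resample of a cohort (with replacement). Re-sampled
# patients get fresh ids so the result is again a valid cohort.
resample_cohort <- function(cohort, idx) {
  pat <- cohort$patients[idx, , drop = FALSE]
  obs_rows <- split(seq_len(nrow(cohort$observations)),
                    factor(cohort$observations$patient_id,
                           levels = cohort$patients$patient_id))
  take <- obs_rows[idx]
  obs <- cohort$observations[unlist(take, use.names = FALSE), , drop = FALSE]
  new_id <- sprintf("B%06d", seq_along(idx))
  pat$patient_id <- new_id
  obs$patient_id <- rep(new_id, lengths(take))
  as_cohort(obs, pat, name = paste0(cohort$name, "_boot"))
}

#' Nonparametric bootstrap for the fitted HMM
#'
#' Patient-level bootstrap: `B` resamples of the cohort (patients drawn with
#' replacement, resample size equal to the cohort size) are each refitted,
#' giving empirical standard errors and 2.5/97.5 percentile confidence
#' intervals for every model parameter. Replicate `b` is seeded
#' deterministically from `seed + b`, so enlarging `B` with the same seed
#' leaves earlier replicates unchanged.
#'
#' To keep 100 refits tractable, each replicate fit uses the point estimate
#' as a warm start plus `restarts - 1` random restarts (the point estimate
#' of the full cohort is an excellent starting neighborhood for its
#' resamples); raise `restarts` for a more conservative search.
#'
#' @param cohort An [as_cohort()] object (after the baseline filter).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param control [fit_control()] for the point-estimate fit.
#' @param point Optional precomputed point estimate (`as_hmm` or
#'   [hmm_params()]); fitted internally when missing.
#' @param restarts Starting points per replicate fit (1 warm + the rest
#'   random).
#' @param max_fail Maximum tolerated fraction of failed replicate fits
#'   before erroring.
#' @return An object of class `hmm_boot`: `point` (params), `replicates`
#'   (`B x 18` matrix, failed rows `NA`), `se`, `ci95` (2 x 18), `B`,
#'   `n_failed`.
#' @seealso [bootstrap_t_test()]
#' @export
bootstrap_hmm <- function(cohort, B = 100, seed = 1,
                          control = fit_control(), point = NULL,
                          restarts = 3, max_fail = 0.1) {
  validate_cohort(cohort)
  stopifnot(B >= 1, restarts >= 1)
  if (is.null(point)) point <- fit_hmm(cohort, control)
  point_params <- if (inherits(point, "as_hmm")) point$params else point
  validate_hmm_params(point_params)
  n <- n_patients(cohort)
  rep_control <- fit_control(n_restarts = max(restarts - 1, 1),
                             max_iter = control$max_iter,
                             rel_tol = control$rel_tol,
                             short_iter = control$short_iter,
                             var_floor = control$var_floor,
                             start_box = control$start_box,
                             seed = control$seed)
  reps <- matrix(NA_real_, B, 18, dimnames = list(NULL, .param_names))
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    bc <- resample_cohort(cohort, idx)
    rep_control$seed <- seed + b
    fit <- tryCatch(fit_hmm(bc, rep_control, start = point_params),
                    error = function(e) NULL)
    if (!is.null(fit)) reps[b, ] <- param_vector(fit$params)
  }
  failed <- rowSums(is.na(reps)) > 0
  if (mean(failed) > max_fail)
    stop(sprintf("%d of %d bootstrap replicate fits failed", sum(failed), B))
  ok <- reps[!failed, , drop = FALSE]
  structure(list(point = point_params,
                 replicates = reps,
                 se = apply(ok, 2, sd),
                 ci95 = apply(ok, 2, quantile, probs = c(0.025, 0.975)),
                 B = B, n_failed = sum(failed), seed = seed),
            class = "hmm_boot")
}

#' @export
print.hmm_boot <- function(x, ...) {
  cat(sprintf("Patient-level bootstrap, B = %d (%d failed)\n", x$B, x$n_failed))
  key <- c("pi_nfr", "apr", "sens", "spec")
  tab <- data.frame(estimate = param_vector(x$point)[key],
                    se = x$se[key], ci_lo = x$ci95[1, key],
                    ci_hi = x$ci95[2, key])
  print(round(tab, 4))
  cat("(all 18 parameters available in $se / $ci95 / $replicates)\n")
  invisible(x)
}

#' Bootstrap-t positivity test for one parameter
#'
#' Tests the null hypothesis that a parameter equals zero against the
#' one-sided alternative that it is positive, using the studentized
#' statistic `point / se` against a bootstrap-t reference distribution
#' `(theta*_b - theta_hat) / se`. Used to establish that misclassification
#' at diagnosis, the annual progression rate and the biopsy false-negative
#' rate are strictly positive.
#'
#' @param boot An `hmm_boot` from [bootstrap_hmm()].
#' @param parameter Parameter name (see [param_vector()] for names), or one
#'   of the derived quantities `"1-sens"` / `"1-spec"`.
#' @param alpha Type-I error level.
#' @return A list of class `hmm_boot_t`: `parameter`, `estimate`, `se`,
#'   `statistic`, `critical`, `p_value`, `reject`, `alpha`. When `se == 0`
#'   the report is degenerate (`reject = NA`) and no test is performed.
#' @export
bootstrap_t_test <- function(boot, parameter, alpha = 0.05) {
  stopifnot(inherits(boot, "hmm_boot"))
  pv <- param_vector(boot$point)
  get <- function(v) {
    switch(parameter,
           "1-sens" = 1 - v["sens"],
           "1-spec" = 1 - v["spec"],
           { if (!parameter %in% names(v)) stop("unknown parameter: ", parameter)
             v[parameter] })
  }
  est <- unname(get(pv))
  ok <- !apply(is.na(boot$replicates), 1, any)
  reps <- apply(boot$replicates[ok, , drop = FALSE], 1, get)
  se <- sd(reps)
  out <- list(parameter = parameter, estimate = est, se = se, alpha = alpha)
  if (!is.finite(se) || se <= 0) {
    out$statistic <- NA_real_; out$critical <- NA_real_
    out$p_value <- NA_real_; out$reject <- NA
  } else {
    tstat <- est / se
    ref <- (reps - est) / se
    out$statistic <- tstat
    out$critical <- unname(quantile(ref, 1 - alpha))
    out$p_value <- mean(ref >= tstat)
    out$reject <- tstat > out$critical
  }
  class(out) <- "hmm_boot_t"
  out
}

#' @export
print.hmm_boot_t <- function(x, ...) {
  cat(sprintf("bootstrap-t positivity test: %s\n", x$parameter))
  if (is.na(x$reject)) {
    cat(sprintf("  estimate %.4f, se = 0: degenerate, no test performed\n",
                x$estimate))
  } else {
    cat(sprintf("  estimate %.4f (se %.4f), t = %.2f, critical %.2f, p = %.3f\n",
                x$estimate, x$se, x$statistic, x$critical, x$p_value))
    cat(sprintf("  %s H0: parameter = 0 at alpha = %.2f\n",
                if (x$reject) "REJECT" else "retain", x$alpha))
  }
  invisible(x)
}
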