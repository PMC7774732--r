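# Pack a cohort into the flat arrays consumed by the compiled recursions.
# Observation rows are patient-major and year-ordered; biopsy codes are
# 0 = none, 1 = GS<=6, 2 = GS>=7; exit codes 0 = censored, 1 = RP favorable,
# 2 = RP non-favorable, 3 = no RP.
cohort_arrays <- function(cohort) {
  validate_cohort(cohort)
  pat <- cohort$patients
  obs <- cohort$observations
  ord <- order(match(obs$patient_id, pat$patient_id), obs$year)
  obs <- obs[ord, , drop = FALSE]
  nobs <- as.integer(table(factor(obs$patient_id, levels = pat$patient_id)))
  exit_code <- match(pat$exit_kind, .exit_kinds)
  exit_code[pat$exit_kind == "CENSORED"] <- 4L
  exit_code <- exit_code %% 4L  # CENSORED -> 0, others keep 1..3
  biopsy <- ifelse(is.na(obs$biopsy), 0L,
                   ifelse(obs$biopsy == "GS7_PLUS", 2L, 1L))
  list(nobs = nobs, exit_code = as.integer(exit_code),
       biopsy = as.integer(biopsy), psa = as.numeric(obs$log_psa),
       patient_id = pat$patient_id,
       obs_patient = obs$patient_id, obs_year = obs$year)
}

#' Log-likelihood of one annual observation given the hidden state
#'
#' The emission term of one observation year: the log mixture density of the
#' observed log PSA plus the log probability of the observed biopsy result,
#' both conditional on the hidden state. A missing PSA or missing biopsy is a
#' null observation and contributes `log(1) = 0` (missingness is assumed
#' non-informative).
#'
#' @param params An [hmm_params()] object.
#' @param state `"FR"` or `"NFR"`.
#' @param log_psa Log PSA value, or `NA` if not measured. Vectorized.
#' @param biopsy `"GS6_OR_LESS"`, `"GS7_PLUS"` or `NA`. Vectorized.
#' @return Numeric vector of log emission likelihoods.
#' @export
#' @examples
#' p <- cohort_params("jh")
#' emission_loglik(p, "NFR", log(6.2), "GS7_PLUS")
#' emission_loglik(p, "FR", NA, NA)  # null observation: exactly 0
emission_loglik <- function(params, state, log_psa = NA_real_,
                            biopsy = NA_character_) {
  validate_hmm_params(params)
  state <- match.arg(state, .states)
  n <- max(length(log_psa), length(biopsy))
  log_psa <- rep_len(as.numeric(log_psa), n)
  biopsy <- rep_len(as.character(biopsy), n)
  if (any(!is.na(log_psa) & !is.finite(log_psa)))
    stop("non-finite log_psa")
  bad <- !is.na(biopsy) & !biopsy %in% c("GS6_OR_LESS", "GS7_PLUS")
  if (any(bad)) stop("invalid biopsy codes")
  p_pos <- if (state == "NFR") params$sens else 1 - params$spec
  lb <- ifelse(is.na(biopsy), 0,
               ifelse(biopsy == "GS7_PLUS", log(p_pos), log(1 - p_pos)))
  mix <- if (state == "NFR") params$psa_nfr else params$psa_fr
  lp <- ifelse(is.na(log_psa), 0, dpsa_mixture(ifelse(is.na(log_psa), 0, log_psa),
                                               mix, log = TRUE))
  lb + lp
}

#' Per-patient sequence log-likelihood
#'
#' Forward recursion over each patient's annual sequence under the model:
#' the initial distribution puts mass `pi_nfr` on the non-favorable state at
#' diagnosis (year 0); each observation year multiplies the transient
#' transition and emission terms; a non-censored exit multiplies the
#' transition probability into the observed leaving state; a censored series
#' ends with the remaining transient mass and no leaving-state factor.
#' Computed with per-year scaling, stable for sequences of 50+ years.
#'
#' @param params An [hmm_params()] object.
#' @param cohort An [as_cohort()] object.
#' @return Named numeric vector of per-patient log-likelihoods (sum it for
#'   the cohort log-likelihood).
#' @export
sequence_loglik <- function(params, cohort) {
  validate_hmm_params(params)
  a <- cohort_arrays(cohort)
  fb <- cpp_fb(a$nobs, a$exit_code, a$biopsy, a$psa, param_vector(params))
  setNames(fb$loglik_patient, a$patient_id)
}

#' Smoothed posterior state probabilities
#'
#' Forward-backward recursions returning, for every patient, the posterior
#' probability of the non-favorable state at diagnosis (year 0) and at each
#' observation year, given the whole sequence, plus the sequence
#' log-likelihood.
#'
#' @inheritParams sequence_loglik
#' @return A list with one element per patient, each a list with `posterior`
#'   (`data.frame` of `year` and `p_nfr`, year 0 first) and `log_likelihood`.
#'   The total log-likelihood is attached as attribute `"log_likelihood"`.
#' @export
forward_backward <- function(params, cohort) {
  validate_hmm_params(params)
  a <- cohort_arrays(cohort)
  fb <- cpp_fb(a$nobs, a$exit_code, a$biopsy, a$psa, param_vector(params))
  idx <- rep(seq_along(a$nobs), a$nobs)
  out <- lapply(seq_along(a$nobs), function(i) {
    g <- fb$gamma[idx == i]
    list(posterior = data.frame(year = 0:a$nobs[i],
                                p_nfr = c(fb$gamma0[i], g)),
         log_likelihood = fb$loglik_patient[i])
  })
  names(out) <- a$patient_id
  attr(out, "log_likelihood") <- fb$loglik
  out
}
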