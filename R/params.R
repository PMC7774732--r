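#' Two-component Gaussian mixture for log PSA
#'
#' Emission distribution of the natural-log PSA value (PSA in ng/mL) in one
#' hidden risk state. Components are kept in the identifiability order
#' `mu1 <= mu2`; a constructor call violating the order has its components
#' swapped (and the weight complemented) silently.
#'
#' @param weight Mixing weight of the first (lower-mean) component, in
#'   `[0, 1]`.
#' @param mu1,mu2 Component means of log PSA.
#' @param sigma1,sigma2 Component standard deviations, strictly positive.
#' @return An object of class `psa_mixture`.
#' @seealso [dpsa_mixture()], [hmm_params()]
#' @export
#' @examples
#' mix <- psa_mixture(0.6, 1.3, 2.0, 0.4, 0.5)
#' dpsa_mixture(log(5), mix)
psa_mixture <- function(weight, mu1, mu2, sigma1, sigma2) {
  stopifnot(is.finite(weight), weight >= 0, weight <= 1,
            is.finite(mu1), is.finite(mu2),
            is.finite(sigma1), sigma1 > 0,
            is.finite(sigma2), sigma2 > 0)
  if (mu1 > mu2) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    tmp <- sigma1; sigma1 <- sigma2; sigma2 <- tmp
    weight <- 1 - weight
  }
  structure(list(weight = weight, mu1 = mu1, mu2 = mu2,
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "psa_mixture")
}

#' Mixture density of log PSA
#'
#' @param x Numeric vector of log PSA values.
#' @param mix A [psa_mixture()].
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @export
dpsa_mixture <- function(x, mix, log = FALSE) {
  stopifnot(inherits(mix, "psa_mixture"))
  d <- mix$weight * dnorm(x, mix$mu1, mix$sigma1) +
    (1 - mix$weight) * dnorm(x, mix$mu2, mix$sigma2)
  if (log) base::log(d) else d
}

#' @export
print.psa_mixture <- function(x, ...) {
  cat(sprintf("log-PSA mixture: %.3f * N(%.3f, %.3f^2) + %.3f * N(%.3f, %.3f^2)\n",
              x$weight, x$mu1, x$sigma1, 1 - x$weight, x$mu2, x$sigma2))
  invisible(x)
}

#' Parameters of the active-surveillance HMM
#'
#' The full parameter set of the two-hidden-state model of prostate cancer
#' under active surveillance: misclassification at diagnosis (initial
#' probability of the non-favorable state), the annual progression rate,
#' per-state annual probabilities of entering each absorbing leaving state,
#' biopsy sensitivity and specificity, and one log-PSA mixture per hidden
#' state.
#'
#' Structural constraints: progression is irreversible (no NFR to FR
#' transition); leaving with favorable prostatectomy pathology is reachable
#' only from the favorable state, and leaving with non-favorable pathology
#' only from the non-favorable state, because prostatectomy pathology reveals
#' the true grade. Each transient row of the implied transition matrix must
#' have non-negative self-loop mass.
#'
#' @param pi_nfr Probability of being in the non-favorable state at diagnosis
#'   (misclassification at diagnosis).
#' @param apr Annual probability of progressing from the favorable to the
#'   non-favorable state.
#' @param exit_fr_rp,exit_fr_norp Annual probabilities of leaving active
#'   surveillance from the favorable state, with radical prostatectomy
#'   (favorable pathology) and without prostatectomy.
#' @param exit_nfr_rp,exit_nfr_norp The same from the non-favorable state
#'   (prostatectomy then shows non-favorable pathology).
#' @param sens Biopsy sensitivity: probability of a Gleason >= 7 biopsy result
#'   while in the non-favorable state.
#' @param spec Biopsy specificity: probability of a Gleason <= 6 result while
#'   in the favorable state.
#' @param psa_fr,psa_nfr [psa_mixture()] of log PSA in each state.
#' @return An object of class `hmm_params`.
#' @seealso [transition_matrix()], [cohort_params()], [fit_hmm()]
#' @export
hmm_params <- function(pi_nfr, apr,
                       exit_fr_rp = 0, exit_fr_norp = 0,
                       exit_nfr_rp = 0, exit_nfr_norp = 0,
                       sens, spec,
                       psa_fr = psa_mixture(0.65, 1.3, 1.9, 0.45, 0.5),
                       psa_nfr = psa_mixture(0.55, 1.7, 2.3, 0.45, 0.55)) {
  p <- structure(list(pi_nfr = pi_nfr, apr = apr,
                      exit_fr_rp = exit_fr_rp, exit_fr_norp = exit_fr_norp,
                      exit_nfr_rp = exit_nfr_rp, exit_nfr_norp = exit_nfr_norp,
                      sens = sens, spec = spec,
                      psa_fr = psa_fr, psa_nfr = psa_nfr),
                 class = "hmm_params")
  validate_hmm_params(p)
  p
}

validate_hmm_params <- function(p) {
  probs <- c(pi_nfr = p$pi_nfr, apr = p$apr,
             exit_fr_rp = p$exit_fr_rp, exit_fr_norp = p$exit_fr_norp,
             exit_nfr_rp = p$exit_nfr_rp, exit_nfr_norp = p$exit_nfr_norp,
             sens = p$sens, spec = p$spec)
  bad <- !is.finite(probs) | probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0, 1]: ", paste(names(probs)[bad], collapse = ", "))
  if (p$apr + p$exit_fr_rp + p$exit_fr_norp > 1 + 1e-12)
    stop("favorable-state row exceeds 1: apr + exit_fr_rp + exit_fr_norp > 1")
  if (p$exit_nfr_rp + p$exit_nfr_norp > 1 + 1e-12)
    stop("non-favorable-state row exceeds 1: exit_nfr_rp + exit_nfr_norp > 1")
  stopifnot(inherits(p$psa_fr, "psa_mixture"), inherits(p$psa_nfr, "psa_mixture"))
  invisible(p)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Active-surveillance HMM parameters\n")
  cat(sprintf("  misclassification at diagnosis : %6.2f%%\n", 100 * x$pi_nfr))
  cat(sprintf("  annual progression rate        : %6.2f%%\n", 100 * x$apr))
  cat(sprintf("  biopsy sensitivity             : %6.2f%%\n", 100 * x$sens))
  cat(sprintf("  biopsy specificity             : %6.2f%%\n", 100 * x$spec))
  cat(sprintf("  annual exits  FR : RP %.3f, no-RP %.3f\n",
              x$exit_fr_rp, x$exit_fr_norp))
  cat(sprintf("  annual exits  NFR: RP %.3f, no-RP %.3f\n",
              x$exit_nfr_rp, x$exit_nfr_norp))
  cat("  log-PSA mixture (FR) : "); print(x$psa_fr)
  cat("  log-PSA mixture (NFR): "); print(x$psa_nfr)
  invisible(x)
}

#' Annual transition matrix of the model
#'
#' Row-stochastic 5 x 5 matrix over the two transient states (`FR`, `NFR`)
#' and the three absorbing leaving states. Progression is one-directional and
#' leaving states are absorbing.
#'
#' @param params An [hmm_params()] object.
#' @return A 5 x 5 matrix with dimnames
#'   `c("FR","NFR","RP_FAVORABLE","RP_NONFAVORABLE","NO_RP")`.
#' @export
#' @examples
#' transition_matrix(hmm_params(0.06, 0.07, sens = 0.72, spec = 0.997))
transition_matrix <- function(params) {
  validate_hmm_params(params)
  st <- c(.states, "RP_FAVORABLE", "RP_NONFAVORABLE", "NO_RP")
  m <- diag(5)
  dimnames(m) <- list(st, st)
  m["FR", ] <- c(1 - params$apr - params$exit_fr_rp - params$exit_fr_norp,
                 params$apr, params$exit_fr_rp, 0, params$exit_fr_norp)
  m["NFR", ] <- c(0, 1 - params$exit_nfr_rp - params$exit_nfr_norp,
                  0, params$exit_nfr_rp, params$exit_nfr_norp)
  m
}

# Flat numeric layout used by the EM core, the bootstrap and coef methods.
.param_names <- c("pi_nfr", "apr", "exit_fr_rp", "exit_fr_norp",
                  "exit_nfr_rp", "exit_nfr_norp", "sens", "spec",
                  "psa_fr.weight", "psa_fr.mu1", "psa_fr.mu2",
                  "psa_fr.sigma1", "psa_fr.sigma2",
                  "psa_nfr.weight", "psa_nfr.mu1", "psa_nfr.mu2",
                  "psa_nfr.sigma1", "psa_nfr.sigma2")

#' Flatten model parameters to a named vector
#'
#' @param params An [hmm_params()] object.
#' @return Named numeric vector of length 18.
#' @export
param_vector <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  setNames(c(params$pi_nfr, params$apr, params$exit_fr_rp, params$exit_fr_norp,
             params$exit_nfr_rp, params$exit_nfr_norp, params$sens, params$spec,
             unlist(params$psa_fr, use.names = FALSE),
             unlist(params$psa_nfr, use.names = FALSE)),
           .param_names)
}

#' Rebuild model parameters from a flat vector
#'
#' Inverse of [param_vector()]; mixture components are re-ordered to the
#' `mu1 <= mu2` convention.
#'
#' @param x Named or positional numeric vector of length 18 in
#'   [param_vector()] order.
#' @return An [hmm_params()] object.
#' @export
params_from_vector <- function(x) {
  stopifnot(length(x) == 18)
  x <- unname(x)
  hmm_params(pi_nfr = x[1], apr = x[2],
             exit_fr_rp = x[3], exit_fr_norp = x[4],
             exit_nfr_rp = x[5], exit_nfr_norp = x[6],
             sens = x[7], spec = x[8],
             psa_fr = psa_mixture(x[9], x[10], x[11], x[12], x[13]),
             psa_nfr = psa_mixture(x[14], x[15], x[16], x[17], x[18]))
}

#' Read or write model parameters as YAML
#'
#' The file is a flat document with the fields of [hmm_params()];
#' `psa_fr`/`psa_nfr` are nested maps with `weight`, `mu1`, `mu2`, `sigma1`,
#' `sigma2`.
#'
#' @param path File path.
#' @return `read_hmm_params()` returns an [hmm_params()] object;
#'   `write_hmm_params()` returns `path` invisibly.
#' @export
read_hmm_params <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("pi_nfr", "apr", "sens", "spec")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("parameter file missing fields: ", paste(miss, collapse = ", "))
  mk <- function(m) do.call(psa_mixture, m[c("weight", "mu1", "mu2", "sigma1", "sigma2")])
  hmm_params(pi_nfr = y$pi_nfr, apr = y$apr,
             exit_fr_rp = y$exit_fr_rp %||% 0,
             exit_fr_norp = y$exit_fr_norp %||% 0,
             exit_nfr_rp = y$exit_nfr_rp %||% 0,
             exit_nfr_norp = y$exit_nfr_norp %||% 0,
             sens = y$sens, spec = y$spec,
             psa_fr = mk(y$psa_fr), psa_nfr = mk(y$psa_nfr))
}

#' @rdname read_hmm_params
#' @param params An [hmm_params()] object.
#' @export
write_hmm_params <- function(params, path) {
  validate_hmm_params(params)
  y <- unclass(params)
  y$psa_fr <- unclass(y$psa_fr)
  y$psa_nfr <- unclass(y$psa_nfr)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published per-cohort model parameters
#'
#' Loads the packaged parameter files for the four active-surveillance
#' cohorts (Johns Hopkins, UCSF, University of Toronto, PRIAS). The
#' probability parameters (misclassification at diagnosis, annual progression
#' rate, biopsy sensitivity and specificity) are the published estimates for
#' each cohort; the per-state log-PSA mixtures in these files are synthetic
#' illustrative values (the fitted mixtures were not published) and do not
#' affect the biopsy-schedule comparison.
#'
#' @param cohort One of `"jh"`, `"ucsf"`, `"uoft"`, `"prias"`.
#' @return An [hmm_params()] object; `cohort_params_all()` returns a named
#'   list with all four.
#' @export
#' @examples
#' cohort_params("jh")
cohort_params <- function(cohort = c("jh", "ucsf", "uoft", "prias")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", paste0(cohort, ".yaml"), package = "ashmm",
                      mustWork = TRUE)
  read_hmm_params(path)
}

#' @rdname cohort_params
#' @export
cohort_params_all <- function() {
  nm <- c("jh", "ucsf", "uoft", "prias")
  setNames(lapply(nm, cohort_params), nm)
}
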