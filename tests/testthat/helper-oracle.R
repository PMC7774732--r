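# Brute-force path-enumeration oracle for short sequences.
#
# Enumerates all hidden-state paths s_0..s_k over {FR, NFR}, computing each
# path's joint probability with the observations directly from the model
# definition (scalar arithmetic, no recursions). Independent of the
# package's forward-backward implementation; feasible for k <= 8.

oracle_emission <- function(params, state, log_psa, biopsy) {
  e <- 1
  if (!is.na(biopsy)) {
    p_pos <- if (state == 2) params$sens else 1 - params$spec
    e <- if (biopsy == "GS7_PLUS") p_pos else 1 - p_pos
  }
  if (!is.na(log_psa)) {
    mix <- if (state == 2) params$psa_nfr else params$psa_fr
    e <- e * (mix$weight * dnorm(log_psa, mix$mu1, mix$sigma1) +
                (1 - mix$weight) * dnorm(log_psa, mix$mu2, mix$sigma2))
  }
  e
}

# states coded 1 = FR, 2 = NFR
oracle_patient <- function(params, log_psa, biopsy, exit_kind) {
  k <- length(log_psa)
  stopifnot(length(biopsy) == k)
  tmat <- matrix(c(1 - params$apr - params$exit_fr_rp - params$exit_fr_norp,
                   params$apr,
                   0, 1 - params$exit_nfr_rp - params$exit_nfr_norp),
                 2, 2, byrow = TRUE)
  exit_prob <- function(s) switch(exit_kind,
    CENSORED = 1,
    RP_FAVORABLE = if (s == 1) params$exit_fr_rp else 0,
    RP_NONFAVORABLE = if (s == 2) params$exit_nfr_rp else 0,
    NO_RP = if (s == 1) params$exit_fr_norp else params$exit_nfr_norp)
  paths <- as.matrix(expand.grid(rep(list(1:2), k + 1)))
  probs <- apply(paths, 1, function(s) {
    p <- if (s[1] == 2) params$pi_nfr else 1 - params$pi_nfr
    for (t in seq_len(k)) {
      p <- p * tmat[s[t], s[t + 1]] *
        oracle_emission(params, s[t + 1], log_psa[t], biopsy[t])
    }
    p * exit_prob(s[k + 1])
  })
  lik <- sum(probs)
  post_nfr <- vapply(seq_len(k + 1), function(j)
    sum(probs[paths[, j] == 2]) / lik, 0)
  # expected counts over the path posterior
  w <- probs / lik
  cnt <- c(init_nfr = 0, fr_fr = 0, fr_nfr = 0, nfr_nfr = 0,
           fr_rpfav = 0, fr_norp = 0, nfr_rpnonfav = 0, nfr_norp = 0)
  bio <- c(pos_fr = 0, neg_fr = 0, pos_nfr = 0, neg_nfr = 0)
  for (i in seq_along(probs)) {
    s <- paths[i, ]
    cnt["init_nfr"] <- cnt["init_nfr"] + w[i] * (s[1] == 2)
    for (t in seq_len(k)) {
      key <- paste0(c("fr", "nfr")[s[t]], "_", c("fr", "nfr")[s[t + 1]])
      if (key != "nfr_fr") cnt[key] <- cnt[key] + w[i]
      if (!is.na(biopsy[t])) {
        b <- if (biopsy[t] == "GS7_PLUS") "pos" else "neg"
        bio[paste0(b, "_", c("fr", "nfr")[s[t + 1]])] <-
          bio[paste0(b, "_", c("fr", "nfr")[s[t + 1]])] + w[i]
      }
    }
    sk <- s[k + 1]
    key <- switch(exit_kind, CENSORED = NULL,
                  RP_FAVORABLE = "fr_rpfav",
                  RP_NONFAVORABLE = "nfr_rpnonfav",
                  NO_RP = if (sk == 1) "fr_norp" else "nfr_norp")
    if (!is.null(key)) cnt[key] <- cnt[key] + w[i]
  }
  list(loglik = log(lik), post_nfr = post_nfr, counts = cnt, biopsy = bio)
}

# single-patient cohort builder; observation years 1..length(log_psa)
make_patient <- function(log_psa, biopsy, exit_kind, id = "PT1",
                         grade = 1L, name = "fixture") {
  k <- length(log_psa)
  obs <- data.frame(patient_id = character(0), year = integer(0),
                    log_psa = numeric(0), biopsy = character(0))
  if (k > 0)
    obs <- data.frame(patient_id = id, year = seq_len(k),
                      log_psa = log_psa, biopsy = biopsy,
                      stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = id, baseline_grade_group = grade,
                    exit_kind = exit_kind,
                    exit_year = if (exit_kind == "CENSORED") k else k + 1L,
                    stringsAsFactors = FALSE)
  as_cohort(obs, pat, name = name)
}

# combine single-patient cohorts into one cohort (fresh unique ids)
bind_cohorts <- function(..., name = "fixture") {
  parts <- list(...)
  obs <- list(); pats <- list()
  for (i in seq_along(parts)) {
    ci <- parts[[i]]
    id_map <- setNames(sprintf("C%02d_%s", i, ci$patients$patient_id),
                       ci$patients$patient_id)
    o <- ci$observations; o$patient_id <- unname(id_map[o$patient_id])
    p <- ci$patients; p$patient_id <- unname(id_map[p$patient_id])
    obs[[i]] <- o; pats[[i]] <- p
  }
  as_cohort(do.call(rbind, obs), do.call(rbind, pats), name = name)
}

# random valid parameter set for property tests
random_params <- function() {
  hmm_params(pi_nfr = runif(1, 0.02, 0.3), apr = runif(1, 0.02, 0.3),
             exit_fr_rp = runif(1, 0.01, 0.1),
             exit_fr_norp = runif(1, 0.01, 0.1),
             exit_nfr_rp = runif(1, 0.01, 0.15),
             exit_nfr_norp = runif(1, 0.01, 0.1),
             sens = runif(1, 0.55, 0.95), spec = runif(1, 0.92, 0.999),
             psa_fr = psa_mixture(runif(1, 0.3, 0.9), rnorm(1, 1.2, 0.2),
                                  rnorm(1, 2.0, 0.2), runif(1, 0.3, 0.6),
                                  runif(1, 0.3, 0.6)),
             psa_nfr = psa_mixture(runif(1, 0.3, 0.9), rnorm(1, 1.6, 0.2),
                                   rnorm(1, 2.4, 0.2), runif(1, 0.3, 0.6),
                                   runif(1, 0.3, 0.6)))
}

# random short observation sequence for oracle comparisons
random_series <- function(k, exit_kind) {
  log_psa <- ifelse(runif(k) < 0.3, NA_real_, rnorm(k, 1.7, 0.6))
  biopsy <- ifelse(runif(k) < 0.4, NA_character_,
                   ifelse(runif(k) < 0.25, "GS7_PLUS", "GS6_OR_LESS"))
  make_patient(log_psa, biopsy, exit_kind)
}
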