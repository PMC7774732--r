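test_that("forward likelihood and posteriors equal path enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    p <- random_params()
    k <- sample(0:8, 1)
    exit_kind <- if (k == 0) sample(c("RP_FAVORABLE", "RP_NONFAVORABLE",
                                      "NO_RP"), 1)
                 else sample(c("CENSORED", "RP_FAVORABLE", "RP_NONFAVORABLE",
                               "NO_RP"), 1)
    co <- random_series(max(k, ifelse(exit_kind == "CENSORED", 1, 0)),
                        exit_kind)
    k <- nrow(co$observations)
    orc <- oracle_patient(p, co$observations$log_psa, co$observations$biopsy,
                          exit_kind)
    expect_equal(unname(sequence_loglik(p, co)), orc$loglik,
                 tolerance = 1e-10)
    fb <- forward_backward(p, co)
    expect_equal(fb[[1]]$log_likelihood, orc$loglik, tolerance = 1e-10)
    expect_equal(fb[[1]]$posterior$p_nfr, orc$post_nfr, tolerance = 1e-10)
  }
})

test_that("single-factor and all-null sequences have closed-form likelihoods", {
  p <- hmm_params(pi_nfr = 0, apr = 0.08, exit_fr_rp = 0.02,
                  exit_fr_norp = 0.05, exit_nfr_rp = 0.06,
                  exit_nfr_norp = 0.03, sens = 0.7, spec = 0.99)
  # immediate exit without observations: one transition factor
  co <- make_patient(numeric(0), character(0), "NO_RP")
  expect_equal(unname(sequence_loglik(p, co)), log(0.05))
  # all-null censored series: total transient mass after T steps
  T <- 7
  co <- make_patient(rep(NA_real_, T), rep(NA_character_, T), "CENSORED")
  m <- transition_matrix(p)[1:2, 1:2]
  mp <- diag(2); for (i in 1:T) mp <- mp %*% m
  expect_equal(unname(sequence_loglik(p, co)), log(sum(c(1, 0) %*% mp)),
               tolerance = 1e-12)
})

test_that("posteriors honor unreachable states and pathology ground truth", {
  p0 <- hmm_params(pi_nfr = 0, apr = 0, exit_fr_rp = 0.02,
                   exit_fr_norp = 0.05, exit_nfr_rp = 0.06,
                   exit_nfr_norp = 0.03, sens = 0.7, spec = 0.99)
  co <- make_patient(c(1.4, NA, 1.8), c("GS6_OR_LESS", NA, NA), "CENSORED")
  fb <- forward_backward(p0, co)
  expect_equal(fb[[1]]$posterior$p_nfr, rep(0, 4))

  p <- hmm_params(pi_nfr = 0.1, apr = 0.1, exit_fr_rp = 0.02,
                  exit_fr_norp = 0.05, exit_nfr_rp = 0.06,
                  exit_nfr_norp = 0.03, sens = 0.7, spec = 0.99)
  co <- make_patient(c(NA, NA), c(NA, NA), "RP_NONFAVORABLE")
  fb <- forward_backward(p, co)
  k <- nrow(co$observations)
  expect_equal(fb[[1]]$posterior$p_nfr[k + 1], 1)  # state before RP is NFR
})

test_that("cohort log-likelihood is invariant to patient order", {
  set.seed(55)
  p <- random_params()
  g <- generate_cohort(p, n_patients = 80, seed = 3, max_followup = 6)
  co <- g$cohort
  perm <- sample(n_patients(co))
  shuffled <- as_cohort(co$observations,
                        co$patients[perm, , drop = FALSE], name = co$name)
  expect_equal(sum(sequence_loglik(p, shuffled)),
               sum(sequence_loglik(p, co)), tolerance = 1e-12)
})

test_that("likelihood increases in sensitivity when positives are NFR-consistent", {
  co <- make_patient(c(NA, NA), c("GS7_PLUS", "GS7_PLUS"),
                     "RP_NONFAVORABLE")
  ll <- vapply(c(0.5, 0.7, 0.9), function(s)
    sum(sequence_loglik(hmm_params(pi_nfr = 0.3, apr = 0.2,
                                   exit_nfr_rp = 0.1, sens = s, spec = 0.99),
                        co)), 0)
  expect_true(all(diff(ll) > 0))
})

test_that("transition-matrix powers match the protocol simulator's state law", {
  # with no exits the transient block is the simulator's state process
  p <- hmm_params(pi_nfr = 0.1, apr = 0.12, sens = 0, spec = 1)
  n <- 50000
  tr <- simulate_trajectories(p, biopsy_protocol("jh"), n_patients = n,
                              seed = 77, horizon = 12)
  m <- transition_matrix(p)
  mp <- diag(5)
  for (t in 1:12) {
    mp <- mp %*% m
    p_nfr <- c(1 - p$pi_nfr, p$pi_nfr, 0, 0, 0) %*% mp[, "NFR"]
    frac <- mean(!is.na(tr$first_nfr_year) & tr$first_nfr_year <= t)
    se <- sqrt(p_nfr * (1 - p_nfr) / n)
    expect_lt(abs(frac - p_nfr), 3 * se + 1e-9)
  }
})
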