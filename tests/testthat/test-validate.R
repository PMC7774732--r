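test_that("per-round positive rates match a hand tally", {
  pts <- list(
    make_patient(c(NA, NA), c("GS6_OR_LESS", "GS7_PLUS"), "RP_NONFAVORABLE"),
    make_patient(c(NA, NA), c("GS6_OR_LESS", "GS7_PLUS"), "NO_RP"),
    make_patient(c(NA, NA, NA), c("GS6_OR_LESS", NA, "GS6_OR_LESS"),
                 "CENSORED"),
    make_patient(c(NA), c("GS7_PLUS"), "RP_NONFAVORABLE"),
    make_patient(c(NA, NA), c(NA, NA), "CENSORED"))
  co <- do.call(bind_cohorts, pts)
  r <- biopsy_positive_rates(co)
  # round 1: patients 1-4 biopsied once each, one positive (patient 4)
  # round 2: patients 1-3 biopsied a second time, two positive
  expect_equal(r$round, c(1L, 2L))
  expect_equal(r$n_biopsied, c(4L, 3L))
  expect_equal(r$n_positive, c(1L, 2L))
  expect_equal(r$rate, c(0.25, 2 / 3))

  # invariant under patient order
  perm <- as_cohort(co$observations, co$patients[c(3, 1, 5, 2, 4), ])
  expect_equal(biopsy_positive_rates(perm), r)

  # all first biopsies negative, all second positive
  pts2 <- replicate(3, make_patient(c(NA, NA),
                                    c("GS6_OR_LESS", "GS7_PLUS"), "NO_RP"),
                    simplify = FALSE)
  r2 <- biopsy_positive_rates(do.call(bind_cohorts, pts2))
  expect_equal(r2$rate, c(0, 1))
})

test_that("self-generated cohorts stay inside the simulated rate bands", {
  p <- cohort_params("ucsf")
  inside <- 0; total <- 0
  for (rep in 1:10) {
    g <- generate_cohort(p, n_patients = 600, seed = 400 + rep,
                         max_followup = 8, schedule = biopsy_protocol("jh"))
    cmp <- compare_observed_simulated(g$cohort, p,
                                      protocol = biopsy_protocol("jh"),
                                      n_sim = 100, seed = 4000 + rep)
    inside <- inside + sum(!cmp$outside)
    total <- total + nrow(cmp)
  }
  expect_gte(inside / total, 0.9)
  # deterministic under a fixed seed
  g <- generate_cohort(p, 300, seed = 1, max_followup = 6)
  c1 <- compare_observed_simulated(g$cohort, p, n_sim = 30, seed = 9)
  c2 <- compare_observed_simulated(g$cohort, p, n_sim = 30, seed = 9)
  expect_identical(c1, c2)
})

test_that("with zero sensitivity the positive rate is the false-positive rate", {
  p <- hmm_params(pi_nfr = 0.3, apr = 0.2, sens = 0, spec = 0.9,
                  exit_fr_rp = 0.01, exit_fr_norp = 0.01,
                  exit_nfr_rp = 0.01, exit_nfr_norp = 0.01)
  g <- generate_cohort(p, n_patients = 20000, seed = 5, max_followup = 4,
                       p_missing_biopsy = 0)
  truth_key <- setNames(g$truth$state, paste(g$truth$patient_id, g$truth$year))
  obs <- g$cohort$observations
  st <- truth_key[paste(obs$patient_id, obs$year)]
  fr_rounds <- !is.na(obs$biopsy) & st == "FR"
  rate_fr <- mean(obs$biopsy[fr_rounds] == "GS7_PLUS")
  expect_lt(abs(rate_fr - (1 - p$spec)),
            3 * sqrt(0.1 * 0.9 / sum(fr_rounds)))
  # and NFR rounds never test positive
  nfr_rounds <- !is.na(obs$biopsy) & st == "NFR"
  expect_true(all(obs$biopsy[nfr_rounds] == "GS6_OR_LESS"))
})

test_that("PSA density comparison is calibrated at the generating truth", {
  p <- cohort_params("jh")
  g <- generate_cohort(p, n_patients = 10000, seed = 17, max_followup = 8)
  d <- psa_density_compare(g$cohort, p, truth = g$truth)
  # soft-assignment weights sum to one per observation
  expect_equal(d$weights$w_fr + d$weights$w_nfr,
               rep(1, nrow(d$weights)))
  # calibration: replicate cohorts from the same truth set the scale
  ref <- vapply(1:5, function(r) {
    gr <- generate_cohort(p, n_patients = 10000, seed = 600 + r,
                          max_followup = 8)
    max(psa_density_compare(gr$cohort, p, truth = gr$truth)$distance)
  }, 0)
  expect_lt(max(d$distance), 2 * max(ref))
  expect_lt(max(d$distance), 0.1)
})

test_that("a single-component mixture compares against its lone Gaussian", {
  p <- hmm_params(pi_nfr = 0.1, apr = 0.1, sens = 0.7, spec = 0.99,
                  psa_fr = psa_mixture(1, 1.5, 2.5, 0.4, 0.4),
                  psa_nfr = psa_mixture(1, 2.0, 3.0, 0.5, 0.5))
  g <- generate_cohort(p, 2000, seed = 3, max_followup = 5)
  d <- psa_density_compare(g$cohort, p, truth = g$truth, breaks = 30)
  tab <- d$FR
  width <- diff(tab$mid[1:2])
  br <- c(tab$mid - width / 2, tab$mid[length(tab$mid)] + width / 2)
  p_fit <- diff(pnorm(br, 1.5, 0.4))
  expect_equal(tab$fitted * width, p_fit / sum(p_fit), tolerance = 1e-10)
})

test_that("posterior-weighted grouping works when no truth is supplied", {
  p <- cohort_params("uoft")
  g <- generate_cohort(p, 400, seed = 21, max_followup = 6)
  d <- psa_density_compare(g$cohort, p)
  expect_equal(d$weights$w_fr + d$weights$w_nfr, rep(1, nrow(d$weights)))
  expect_true(all(d$distance >= 0 & d$distance <= 1))
})
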