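test_that("expected sufficient statistics match path-enumeration expectations", {
  set.seed(202)
  for (rep in 1:6) {
    p <- random_params()
    kinds <- sample(c("CENSORED", "RP_FAVORABLE", "RP_NONFAVORABLE", "NO_RP"),
                    3, replace = TRUE)
    parts <- lapply(kinds, function(kind)
      random_series(sample(1:6, 1), kind))
    co <- bind_cohorts(parts[[1]], parts[[2]], parts[[3]])
    st <- e_step(p, co)
    orc <- lapply(seq_along(parts), function(i) {
      o <- parts[[i]]$observations
      oracle_patient(p, o$log_psa, o$biopsy, kinds[i])
    })
    expect_equal(st$loglik, sum(vapply(orc, `[[`, 0, "loglik")),
                 tolerance = 1e-8)
    cnt <- Reduce(`+`, lapply(orc, `[[`, "counts"))
    bio <- Reduce(`+`, lapply(orc, `[[`, "biopsy"))
    expect_equal(st$counts[names(cnt)], cnt, tolerance = 1e-8)
    expect_equal(st$biopsy[names(bio)], bio, tolerance = 1e-8)
  }
})

test_that("sufficient statistics are additive over patients", {
  set.seed(33)
  p <- random_params()
  g <- generate_cohort(p, n_patients = 40, seed = 5, max_followup = 5)
  co <- g$cohort
  twice <- bind_cohorts(co, co)  # ids disambiguated per part
  expect_equal(n_patients(twice), 2 * n_patients(co))
  st1 <- e_step(p, co)
  st2 <- e_step(p, twice)
  expect_equal(st2$loglik, 2 * st1$loglik)
  expect_equal(st2$counts, 2 * st1$counts, tolerance = 1e-10)
  expect_equal(st2$biopsy, 2 * st1$biopsy, tolerance = 1e-10)
  expect_equal(st2$psa, 2 * st1$psa, tolerance = 1e-10)
  # responsibilities are a soft assignment: each observed PSA row sums to 1
  r <- st1$responsibilities
  expect_equal(rowSums(r[, c("fr.1", "fr.2", "nfr.1", "nfr.2")]),
               rep(1, nrow(r)), tolerance = 1e-10)
})

test_that("the M-step recovers empirical frequencies from known counts", {
  prev <- hmm_params(0.5, 0.1, 0.02, 0.02, 0.02, 0.02, sens = 0.6,
                     spec = 0.95)
  # psa moments for component means 1.5 / 2.4 / 1.3 / 1.8 and variances
  # 0.25 / 0.16 / 0.09 / 0.04 at responsibility masses 200 / 100 / 80 / 40
  ps <- rbind(c(200, 200 * 1.5, 200 * (0.25 + 1.5^2)),
              c(100, 100 * 2.4, 100 * (0.16 + 2.4^2)),
              c(80, 80 * 1.3, 80 * (0.09 + 1.3^2)),
              c(40, 40 * 1.8, 40 * (0.04 + 1.8^2)))
  dimnames(ps) <- list(c("fr.1", "fr.2", "nfr.1", "nfr.2"),
                       c("r", "rx", "rx2"))
  stats <- structure(list(
    loglik = 0, n_patients = 100,
    counts = c(init_nfr = 12, fr_fr = 300, fr_nfr = 30, nfr_nfr = 120,
               fr_rpfav = 6, fr_norp = 24, nfr_rpnonfav = 10, nfr_norp = 14),
    biopsy = c(pos_fr = 1, neg_fr = 199, pos_nfr = 70, neg_nfr = 30),
    psa = ps),
    class = "em_stats")
  up <- m_step(stats, prev)
  d_fr <- 300 + 30 + 6 + 24
  expect_equal(up$pi_nfr, 0.12)
  expect_equal(up$apr, 30 / d_fr, tolerance = 1e-12)
  expect_equal(up$exit_fr_rp, 6 / d_fr, tolerance = 1e-12)
  expect_equal(up$exit_fr_norp, 24 / d_fr, tolerance = 1e-12)
  expect_equal(up$exit_nfr_rp, 10 / 144, tolerance = 1e-12)
  expect_equal(up$exit_nfr_norp, 14 / 144, tolerance = 1e-12)
  expect_equal(up$sens, 0.7)
  expect_equal(up$spec, 0.995)
  expect_equal(up$psa_fr$weight, 200 / 300, tolerance = 1e-12)
  expect_equal(up$psa_fr$mu1, 1.5, tolerance = 1e-12)
  expect_equal(up$psa_fr$sigma1, 0.5, tolerance = 1e-10)
  expect_equal(up$psa_nfr$mu2, 1.8, tolerance = 1e-12)
  expect_equal(up$psa_nfr$sigma2, 0.2, tolerance = 1e-10)
})

test_that("responsibilities concentrated on one component hold the other", {
  prev <- hmm_params(0.1, 0.1, sens = 0.7, spec = 0.99,
                     psa_fr = psa_mixture(0.5, 1.0, 2.0, 0.3, 0.3),
                     psa_nfr = psa_mixture(0.5, 1.3, 2.3, 0.3, 0.3))
  ps <- rbind(c(50, 50 * 1.1, 50 * (0.09 + 1.1^2)),
              c(0, 0, 0),
              c(30, 30 * 1.9, 30 * (0.04 + 1.9^2)),
              c(0, 0, 0))
  dimnames(ps) <- list(c("fr.1", "fr.2", "nfr.1", "nfr.2"),
                       c("r", "rx", "rx2"))
  stats <- structure(list(loglik = 0, n_patients = 10,
                          counts = c(init_nfr = 1, fr_fr = 10, fr_nfr = 2,
                                     nfr_nfr = 5, fr_rpfav = 0, fr_norp = 1,
                                     nfr_rpnonfav = 1, nfr_norp = 1),
                          biopsy = c(pos_fr = 0, neg_fr = 10, pos_nfr = 7,
                                     neg_nfr = 3),
                          psa = ps),
                     class = "em_stats")
  up <- m_step(stats, prev)
  expect_equal(up$psa_fr$weight, 1)
  expect_equal(up$psa_fr$mu1, 1.1, tolerance = 1e-12)
  expect_equal(up$psa_fr$mu2, 2.0)   # held at previous value
  expect_equal(up$psa_nfr$mu1, 1.9, tolerance = 1e-12)
})

test_that("one compiled EM iteration equals e_step followed by m_step", {
  set.seed(61)
  p <- random_params()
  g <- generate_cohort(p, n_patients = 120, seed = 8, max_followup = 7)
  one <- fit_hmm(g$cohort,
                 fit_control(n_restarts = 1, max_iter = 2, short_iter = 2,
                             seed = 3))
  # reproduce by hand from the same starting point
  set.seed(3 + 1)
  a <- ashmm:::cohort_arrays(g$cohort)
  start <- ashmm:::random_start(a$psa[!is.na(a$psa)],
                                fit_control()$start_box)
  st <- e_step(start, g$cohort)
  up <- m_step(st, start)
  st2 <- e_step(up, g$cohort)
  expect_equal(one$loglik_trace[1], st$loglik, tolerance = 1e-10)
  expect_equal(one$loglik_trace[2], st2$loglik, tolerance = 1e-10)
})

test_that("EM log-likelihood traces never decrease", {
  set.seed(404)
  for (rep in 1:25) {
    p <- random_params()
    g <- generate_cohort(p, n_patients = 60, seed = 1000 + rep,
                         max_followup = 6,
                         schedule = biopsy_protocol("jh"))
    f <- fit_hmm(g$cohort, fit_control(n_restarts = 1, max_iter = 80,
                                       short_iter = 80, seed = rep))
    expect_true(all(diff(f$loglik_trace) >= -1e-8))
    expect_equal(f$log_likelihood, max(f$restart_logliks))
  }
})

test_that("fitting recovers generator parameters on a moderate cohort", {
  truth <- cohort_params("jh")
  g <- generate_cohort(truth, n_patients = 1500, seed = 42, max_followup = 10)
  f <- fit_hmm(g$cohort, fit_control(n_restarts = 8, seed = 2))
  expect_true(f$converged)
  expect_lt(abs(coef(f)["apr"] - truth$apr), 0.02)
  expect_lt(abs(coef(f)["sens"] - truth$sens), 0.05)
  expect_lt(abs(coef(f)["pi_nfr"] - truth$pi_nfr), 0.03)
  expect_lt(abs(coef(f)["spec"] - truth$spec), 0.01)
  # mixture identifiability convention on return
  expect_lte(f$params$psa_fr$mu1, f$params$psa_fr$mu2)
  expect_lte(f$params$psa_nfr$mu1, f$params$psa_nfr$mu2)
})

test_that("all-null censored cohorts leave emissions unidentified but fit", {
  parts <- lapply(1:20, function(i)
    make_patient(rep(NA_real_, 4), rep(NA_character_, 4), "CENSORED"))
  co <- do.call(bind_cohorts, parts)
  f <- fit_hmm(co, fit_control(n_restarts = 2, max_iter = 50, seed = 1))
  expect_true(f$emission_held)
  expect_true(is.finite(f$log_likelihood))
})

test_that("patient order does not change the fitted likelihood", {
  set.seed(7)
  g <- generate_cohort(cohort_params("uoft"), n_patients = 200, seed = 12,
                       max_followup = 8)
  co <- g$cohort
  perm <- sample(n_patients(co))
  shuffled <- as_cohort(co$observations, co$patients[perm, , drop = FALSE])
  ctrl <- fit_control(n_restarts = 3, seed = 5)
  f1 <- fit_hmm(co, ctrl)
  f2 <- fit_hmm(shuffled, ctrl)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
})
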