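test_that("reading a longitudinal table maps rows, missingness and exits", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,year,psa_ng_ml,biopsy_grade_group,exit_kind,exit_year,baseline_grade_group",
    "A,1,5.2,1,NO_RP,4,1",
    "A,2,NA,,NO_RP,4,1",
    "A,3,6.0,2,NO_RP,4,1"), path)
  co <- read_cohort(path)
  expect_s3_class(co, "as_cohort")
  expect_equal(n_patients(co), 1)
  expect_equal(nrow(co$observations), 3)
  expect_equal(co$observations$log_psa[1], log(5.2))
  expect_true(is.na(co$observations$log_psa[2]))
  expect_true(is.na(co$observations$biopsy[2]))
  expect_equal(co$observations$biopsy, c("GS6_OR_LESS", NA, "GS7_PLUS"))
  expect_equal(co$patients$exit_kind, "NO_RP")
})

test_that("unparseable and non-positive PSA become missing with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,year,psa_ng_ml,biopsy_grade_group,exit_kind,exit_year,baseline_grade_group",
    "A,1,oops,1,CENSORED,2,1",
    "A,2,-3,,CENSORED,2,1"), path)
  expect_warning(expect_warning(co <- read_cohort(path), "unparseable"),
                 "negative")
  expect_true(all(is.na(co$observations$log_psa)))
})

test_that("malformed tables are rejected with the offending patient named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,year,psa_ng_ml,biopsy_grade_group,exit_kind,exit_year,baseline_grade_group",
    "A,1,5,1,CENSORED,3,1",
    "A,3,5,1,CENSORED,3,1"), path)
  expect_error(read_cohort(path), "A")

  writeLines(c(
    "patient_id,year,psa_ng_ml,biopsy_grade_group,exit_kind,exit_year,baseline_grade_group",
    "B,1,5,1,CENSORED,2,1",
    "B,1,6,1,CENSORED,2,1"), path)
  expect_error(read_cohort(path), "duplicate.*B")
})

test_that("a dialect can remap column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,year,psa,biopsy_grade_group,exit_kind,exit_year,baseline_grade_group",
               "A,1,4.4,1,CENSORED,1,1"), path)
  co <- read_cohort(path, dialect = c(patient_id = "id", psa_ng_ml = "psa"))
  expect_equal(co$patients$patient_id, "A")
  expect_equal(co$observations$log_psa, log(4.4))
})

test_that("write/read round trip is the identity, including edge cohorts", {
  # generated cohort, exercised at a few thousand patients
  g <- generate_cohort(cohort_params("ucsf"), n_patients = 3000, seed = 11,
                       schedule = biopsy_protocol("ucsf"), name = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- read_cohort(path, name = "rt")
  expect_equal(back$patients, g$cohort$patients)
  expect_equal(back$observations$patient_id, g$cohort$observations$patient_id)
  expect_equal(back$observations$year, g$cohort$observations$year)
  expect_equal(back$observations$biopsy, g$cohort$observations$biopsy)
  expect_equal(back$observations$log_psa, g$cohort$observations$log_psa,
               tolerance = 1e-12)

  # zero-observation patient (exit replaces the year-1 slot)
  one <- make_patient(numeric(0), character(0), "NO_RP", id = "Z")
  write_cohort(one, path)
  back <- read_cohort(path)
  expect_equal(back$patients$exit_year, 1L)
  expect_equal(nrow(back$observations), 0)

  # empty cohort writes a header-only file
  empty <- as_cohort(data.frame(patient_id = character(0), year = integer(0),
                                log_psa = numeric(0), biopsy = character(0)),
                     data.frame(patient_id = character(0),
                                baseline_grade_group = integer(0),
                                exit_kind = character(0),
                                exit_year = integer(0)))
  write_cohort(empty, path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(n_patients(read_cohort(path)), 0)
})

test_that("cohort invariants are enforced", {
  obs <- data.frame(patient_id = "A", year = 1:2, log_psa = NA_real_,
                    biopsy = NA_character_)
  pat <- data.frame(patient_id = "A", baseline_grade_group = 1L,
                    exit_kind = "NO_RP", exit_year = 2L)
  expect_error(as_cohort(obs, pat), "exit")
  pat$exit_year <- 3L
  expect_s3_class(as_cohort(obs, pat), "as_cohort")
  pat2 <- rbind(pat, pat)
  expect_error(as_cohort(rbind(obs, obs), pat2), "duplicated patient_id")
})

test_that("baseline filter keeps grade group 1 and missing, drops >= 2", {
  grades <- c(1L, 1L, 2L, NA, 3L, 1L)
  parts <- lapply(grades, function(g)
    make_patient(NA_real_, NA_character_, "CENSORED", grade = g))
  co <- bind_cohorts(parts[[1]], parts[[2]], parts[[3]], parts[[4]],
                     parts[[5]], parts[[6]])
  f <- filter_baseline_favorable(co)
  expect_equal(n_patients(f), 4)
  expect_true(all(is.na(f$patients$baseline_grade_group) |
                    f$patients$baseline_grade_group == 1))
  # idempotent, and the identity when nothing is excludable
  expect_equal(filter_baseline_favorable(f), f)
  # never increases the count
  expect_lte(n_patients(f), n_patients(co))
})
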