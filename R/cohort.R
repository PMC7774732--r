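#' Longitudinal active-surveillance cohort
#'
#' Container for one cohort of patients under active surveillance. Each
#' patient contributes an annual observation sequence (years since diagnosis
#' 1, 2, ...; the diagnosis year itself is year 0 and carries no observation
#' row) and one exit record. A non-censored exit in year `t` replaces that
#' year's observation slot: the leaving state is itself the observation, so
#' observation years run `1 .. t - 1`. A censored patient is still on
#' surveillance when follow-up ends, and the exit year equals the last
#' observation year.
#'
#' @param observations `data.frame` with columns `patient_id` (character),
#'   `year` (integer >= 1), `log_psa` (numeric, `NA` for a missing PSA) and
#'   `biopsy` (`"GS6_OR_LESS"`, `"GS7_PLUS"` or `NA` for no biopsy that
#'   year).
#' @param patients `data.frame` with columns `patient_id`,
#'   `baseline_grade_group` (integer 1-5 or `NA`), `exit_kind` (one of
#'   `"RP_FAVORABLE"`, `"RP_NONFAVORABLE"`, `"NO_RP"`, `"CENSORED"`) and
#'   `exit_year` (integer >= 1).
#' @param name Cohort label.
#' @return An object of class `as_cohort`.
#' @seealso [read_cohort()], [filter_baseline_favorable()], [generate_cohort()]
#' @export
as_cohort <- function(observations, patients, name = "cohort") {
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  need_obs <- c("patient_id", "year", "log_psa", "biopsy")
  need_pat <- c("patient_id", "baseline_grade_group", "exit_kind", "exit_year")
  stopifnot(all(need_obs %in% names(observations)),
            all(need_pat %in% names(patients)))
  observations$patient_id <- as.character(observations$patient_id)
  observations$year <- as.integer(observations$year)
  observations$biopsy <- as.character(observations$biopsy)
  patients$patient_id <- as.character(patients$patient_id)
  patients$exit_year <- as.integer(patients$exit_year)
  observations <- observations[order(observations$patient_id, observations$year),
                               need_obs, drop = FALSE]
  rownames(observations) <- NULL
  rownames(patients) <- NULL
  x <- structure(list(name = name,
                      patients = patients[, need_pat, drop = FALSE],
                      observations = observations),
                 class = "as_cohort")
  validate_cohort(x)
}

#' Check cohort invariants
#'
#' Verifies unique patient ids, valid exit kinds, contiguous observation
#' years starting at 1, the exit-year convention, and valid biopsy codes.
#' Called by [as_cohort()]; exported because generated and hand-built
#' cohorts go through the same checks in tests.
#'
#' @param x An `as_cohort` object.
#' @return `x`, invisibly, or an error naming the offending patient.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "as_cohort"))
  pat <- x$patients; obs <- x$observations
  if (anyDuplicated(pat$patient_id))
    stop("duplicated patient_id: ",
         paste(unique(pat$patient_id[duplicated(pat$patient_id)]), collapse = ", "))
  if (!all(pat$exit_kind %in% .exit_kinds))
    stop("invalid exit_kind values")
  if (any(!is.na(obs$biopsy) & !obs$biopsy %in% c("GS6_OR_LESS", "GS7_PLUS")))
    stop("invalid biopsy codes; use GS6_OR_LESS / GS7_PLUS / NA")
  if (nrow(obs) && !all(obs$patient_id %in% pat$patient_id))
    stop("observations for unknown patients")
  if (any(!is.na(obs$log_psa) & !is.finite(obs$log_psa)))
    stop("non-finite log_psa")
  yrs_by <- split(obs$year, factor(obs$patient_id, levels = pat$patient_id))
  k <- lengths(yrs_by)
  contiguous <- vapply(yrs_by, function(y) length(y) == 0L ||
                         identical(sort(y), seq_along(y)), logical(1))
  if (!all(contiguous)) {
    id <- pat$patient_id[which(!contiguous)[1]]
    y <- sort(yrs_by[[which(!contiguous)[1]]])
    if (anyDuplicated(y))
      stop("duplicate (patient, year) rows for patient ", id)
    stop("non-contiguous observation years for patient ", id,
         " (expected 1..", length(y), ")")
  }
  ey <- pat$exit_year
  if (any(is.na(ey) | ey < 1))
    stop("invalid exit_year for patient ",
         pat$patient_id[which(is.na(ey) | ey < 1)[1]])
  cens <- pat$exit_kind == "CENSORED"
  bad_c <- cens & (k == 0L | ey != k)
  if (any(bad_c))
    stop("censored patient ", pat$patient_id[which(bad_c)[1]],
         " must have exit_year equal to the last observation year")
  bad_e <- !cens & ey != k + 1L
  if (any(bad_e)) {
    i <- which(bad_e)[1]
    stop("patient ", pat$patient_id[i], " exits in year ", ey[i],
         " but has observation years 1..", k[i],
         " (exit must replace the year-", k[i] + 1L, " slot)")
  }
  invisible(x)
}

#' @export
print.as_cohort <- function(x, ...) {
  tab <- table(factor(x$patients$exit_kind, levels = .exit_kinds))
  cat(sprintf("<as_cohort '%s': %d patients, %d patient-year observations>\n",
              x$name, nrow(x$patients), nrow(x$observations)))
  cat("  exits:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nb <- sum(!is.na(x$observations$biopsy))
  np <- sum(!is.na(x$observations$log_psa))
  cat(sprintf("  observed biopsies: %d, observed PSA values: %d\n", nb, np))
  invisible(x)
}

.cohort_columns <- c("patient_id", "year", "psa_ng_ml", "biopsy_grade_group",
                     "exit_kind", "exit_year", "baseline_grade_group")

#' Read a cohort from a delimited longitudinal table
#'
#' One row per patient-year, plus per-patient exit columns repeated on each
#' row; a patient whose exit replaces year 1 (no observation years) appears
#' as a single row with an empty `year`. Expected columns (remappable via
#' `dialect`): `patient_id`, `year`, `psa_ng_ml`, `biopsy_grade_group`
#' (empty = no biopsy, 1 = Gleason <= 6, >= 2 = Gleason >= 7), `exit_kind`,
#' `exit_year`, `baseline_grade_group`.
#'
#' PSA is stored and modelled on the natural-log scale; raw ng/mL values are
#' logged at read time. Unparseable, zero or negative PSA values become
#' missing with a warning.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector or list mapping the
#'   canonical column names to the file's column names, e.g.
#'   `c(psa_ng_ml = "psa")`.
#' @param name Cohort label; defaults to the file name.
#' @return An [as_cohort()] object.
#' @export
read_cohort <- function(path, dialect = NULL, name = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  cols <- setNames(.cohort_columns, .cohort_columns)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    bad <- setdiff(names(dialect), .cohort_columns)
    if (length(bad)) stop("unknown dialect keys: ", paste(bad, collapse = ", "))
    cols[names(dialect)] <- dialect
  }
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  d <- setNames(raw[, unname(cols), drop = FALSE], names(cols))
  d$patient_id <- as.character(d$patient_id)

  psa_chr <- trimws(as.character(d$psa_ng_ml))
  psa <- suppressWarnings(as.numeric(psa_chr))
  bad_parse <- !is.na(psa_chr) & nzchar(psa_chr) &
    !(psa_chr %in% c("NA", "NaN")) & is.na(psa)
  if (any(bad_parse))
    warning(sum(bad_parse), " unparseable PSA value(s) treated as missing")
  nonpos <- !is.na(psa) & psa <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " zero/negative PSA value(s) treated as missing")
    psa[nonpos] <- NA_real_
  }

  gg <- suppressWarnings(as.integer(d$biopsy_grade_group))
  biopsy <- ifelse(is.na(gg), NA_character_,
                   ifelse(gg >= 2, "GS7_PLUS", "GS6_OR_LESS"))

  has_year <- !is.na(suppressWarnings(as.integer(d$year)))
  obs <- data.frame(patient_id = d$patient_id[has_year],
                    year = as.integer(d$year[has_year]),
                    log_psa = log(psa)[has_year],
                    biopsy = biopsy[has_year],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(obs[, c("patient_id", "year")])) {
    dup <- obs[duplicated(obs[, c("patient_id", "year")]), ]
    stop("duplicate (patient, year) rows, e.g. patient ", dup$patient_id[1],
         " year ", dup$year[1])
  }
  first <- !duplicated(d$patient_id)
  pats <- data.frame(patient_id = d$patient_id[first],
                     baseline_grade_group =
                       suppressWarnings(as.integer(d$baseline_grade_group[first])),
                     exit_kind = as.character(d$exit_kind[first]),
                     exit_year = as.integer(d$exit_year[first]),
                     stringsAsFactors = FALSE)
  as_cohort(obs, pats, name = name %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Write a cohort to a delimited longitudinal table
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, path))`
#' reproduces `x` (PSA round-trips through ng/mL at full double precision).
#' An empty cohort writes a header-only file.
#'
#' @param cohort An [as_cohort()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  obs <- cohort$observations
  pat <- cohort$patients
  rows <- merge(pat, obs, by = "patient_id", all.x = TRUE, sort = FALSE)
  rows <- rows[order(rows$patient_id, rows$year), ]
  out <- data.frame(patient_id = rows$patient_id,
                    year = rows$year,
                    psa_ng_ml = sprintf0(exp(rows$log_psa)),
                    biopsy_grade_group = ifelse(is.na(rows$biopsy), "",
                                                ifelse(rows$biopsy == "GS7_PLUS", "2", "1")),
                    exit_kind = rows$exit_kind,
                    exit_year = rows$exit_year,
                    baseline_grade_group = rows$baseline_grade_group,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# full-precision decimal formatting; "" for NA
sprintf0 <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))

#' Baseline eligibility filter
#'
#' Drops patients whose diagnostic biopsy already showed medium/high-grade
#' cancer (ISUP grade group >= 2): these patients do not meet any cohort's
#' favorable-risk inclusion criteria and are excluded before model fitting.
#' Patients with grade group 1 or an unknown baseline grade are retained.
#' Idempotent; never increases the patient count.
#'
#' @param cohort An [as_cohort()] object with `baseline_grade_group`
#'   populated (`NA` allowed).
#' @return The filtered [as_cohort()].
#' @export
filter_baseline_favorable <- function(cohort) {
  validate_cohort(cohort)
  keep <- is.na(cohort$patients$baseline_grade_group) |
    cohort$patients$baseline_grade_group == 1
  ids <- cohort$patients$patient_id[keep]
  as_cohort(cohort$observations[cohort$observations$patient_id %in% ids, ,
                                drop = FALSE],
            cohort$patients[keep, , drop = FALSE],
            name = cohort$name)
}

#' Number of patients in a cohort
#' @param cohort An [as_cohort()] object.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)
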