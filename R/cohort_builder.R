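# Turning a raw HMO extract (demographics, visits, diagnoses, labs,
# procedures) into the analytic cohort: condition phenotyping, qualifying
# primary-care visits, eGFR categorization, demographic encoding, and
# eligibility filtering with an attrition log.

AGE_LEVELS <- c("40-49", "50-59", "60-69", "70-79", "80-89", "90+")
SEX_LEVELS <- c("Female", "Male")
ETHNIC_LEVELS <- c("General", "Arab", "Ultra-Orthodox")
REGION_LEVELS <- c("Central", "North", "Jerusalem", "South")
SES_LEVELS <- c("Highest", "Higher", "Lower", "Lowest")
EGFR_LEVELS <- c("60+", "45-59", "30-44", "<30")
INDEX_CONDITIONS <- c("heart_failure", "chronic_lung_disease", "diabetes")

#' Age band from birth year
#'
#' Age is computed as `age_ref_year - birth_year` (patient-level variables
#' are anchored to 2015, the year before the study period, so birth years
#' 1966-1975 map to the 40-49 band).
#' @param birth_year integer vector
#' @param age_ref_year reference year (default 2015)
#' @return character vector of age bands; `NA` for ages below 40
#' @export
age_group <- function(birth_year, age_ref_year = 2015L) {
  age <- age_ref_year - as.integer(birth_year)
  cut(age, breaks = c(40, 50, 60, 70, 80, 90, Inf), right = FALSE,
      labels = AGE_LEVELS) |> as.character()
}

#' Socioeconomic-status group from an area SES decile
#'
#' Deciles run from 1 (poorest) to 10 (wealthiest) and are grouped 1-3
#' (Lowest), 4-5 (Lower), 6-7 (Higher), 8-10 (Highest).
#' @param ses_decile integer vector in 1..10
#' @return character vector of SES groups
#' @export
ses_group <- function(ses_decile) {
  d <- as.integer(ses_decile)
  if (any(is.na(d) | d < 1L | d > 10L)) {
    stop("SES deciles must be integers in 1..10", call. = FALSE)
  }
  c("Lowest", "Lowest", "Lowest", "Lower", "Lower",
    "Higher", "Higher", "Highest", "Highest", "Highest")[d]
}

#' Qualifying primary-care visit dates for one patient
#'
#' A visit qualifies when it is delivered by a family physician, lasts at
#' least `min_minutes` (chart-open time), and falls inside the study window;
#' any modality (in person, video, phone, text) counts. Multiple qualifying
#' visits on one calendar day collapse to a single date, since a zero-day
#' interval would make the regularity statistic ill-behaved.
#'
#' @param visits data.frame with columns `provider_role`, `date`,
#'   `duration_minutes`
#' @param window closed date window (default 2018-01-01 .. 2019-12-31)
#' @param min_minutes minimum duration in minutes (default 5)
#' @return sorted `Date` vector of distinct qualifying dates
#' @export
qualify_visits <- function(visits,
                           window = as.Date(c("2018-01-01", "2019-12-31")),
                           min_minutes = 5) {
  window <- as_window(window)
  if (is.null(visits) || nrow(visits) == 0L) return(as.Date(character()))
  d <- as.Date(visits$date)
  keep <- visits$provider_role == "family_physician" &
    visits$duration_minutes >= min_minutes &
    in_window(d, window)
  sort(unique(d[keep]))
}

# vectorized multi-patient version used by build_cohort
qualify_visits_all <- function(visits, window, min_minutes) {
  v <- as.data.table(visits)
  v <- v[provider_role == "family_physician" & duration_minutes >= min_minutes]
  v[, date := as.Date(date)]
  v <- v[in_window(date, window), .(patient_id, date)]
  unique(v)[order(patient_id, date)]
}

#' Kidney-function category from laboratory eGFR records
#'
#' The category is taken from the lowest eGFR recorded during the primary
#' years (2018-2019). When no value exists there, the lowest value from the
#' fallback years (2016-2017) is used; when no value exists at all, the mode
#' ("60+", intact kidney function) is imputed.
#'
#' @param labs data.frame with columns `egfr`, `date` for one patient (may
#'   be empty or `NULL`)
#' @param primary_years,fallback_years integer year vectors
#' @return one of `"60+"`, `"45-59"`, `"30-44"`, `"<30"`
#' @export
categorize_egfr <- function(labs, primary_years = 2018:2019,
                            fallback_years = 2016:2017) {
  if (is.null(labs) || nrow(labs) == 0L) return("60+")
  v <- as.numeric(labs$egfr)
  if (any(is.na(v) | v < 0)) {
    stop("negative or missing eGFR value", call. = FALSE)
  }
  yr <- as.integer(format(as.Date(labs$date), "%Y"))
  pick <- v[yr %in% primary_years]
  if (length(pick) == 0L) pick <- v[yr %in% fallback_years]
  if (length(pick) == 0L) return("60+")
  egfr_band(min(pick))
}

egfr_band <- function(x) {
  ifelse(x >= 60, "60+", ifelse(x >= 45, "45-59", ifelse(x >= 30, "30-44", "<30")))
}

#' Build the analytic cohort from extract tables
#'
#' Applies, in order, the eligibility filters: age >= 40 at the reference
#' year; at least one index condition (heart failure, chronic lung disease,
#' diabetes) phenotyped from diagnosis codes over `condition_period`; at
#' least `min_visits` qualifying primary-care visit dates in `visit_window`;
#' and no hemodialysis procedure (even one excludes) during
#' `dialysis_window`. Emits an attrition log with the count removed by each
#' filter. The retained set is order-invariant; only the log depends on the
#' filter order.
#'
#' @param bundle list of extract tables: `demographics`, `visits`,
#'   `diagnoses`, `labs`, `procedures` (see the package vignette for
#'   schemas)
#' @param code_lists named list of [code_list()] objects
#'   (default [default_code_lists()])
#' @param visit_window qualifying-visit window (default 2018-2019)
#' @param condition_period diagnosis lookback (default 2016-2019)
#' @param dialysis_window hemodialysis exclusion window (default 2015-2019)
#' @param min_visits minimum qualifying visit dates (default 3)
#' @param min_minutes minimum visit duration (default 5)
#' @param min_age minimum age (default 40)
#' @param age_ref_year year ages are anchored to (default 2015)
#' @return list with `patients` (one row per retained patient, with
#'   demographic encodings, condition flags `cond_*`, `egfr_category`,
#'   `n_visits`), `visits` (long table of qualifying dates for retained
#'   patients), and `attrition` (per-filter removal counts)
#' @export
build_cohort <- function(bundle,
                         code_lists = default_code_lists(),
                         visit_window = as.Date(c("2018-01-01", "2019-12-31")),
                         condition_period = as.Date(c("2016-01-01", "2019-12-31")),
                         dialysis_window = as.Date(c("2015-01-01", "2019-12-31")),
                         min_visits = 3L, min_minutes = 5,
                         min_age = 40L, age_ref_year = 2015L) {
  visit_window <- as_window(visit_window)
  condition_period <- as_window(condition_period)
  dialysis_window <- as_window(dialysis_window)

  demo <- as.data.table(bundle$demographics)
  req <- c("patient_id", "birth_year", "sex", "ethnic_group", "region",
           "ses_decile", "current_smoker", "clinic_id")
  miss <- setdiff(req, names(demo))
  if (length(miss)) {
    stop("demographics table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(demo$patient_id)) {
    stop("duplicate patient_id in demographics", call. = FALSE)
  }
  if (any(is.na(demo$clinic_id))) stop("missing clinic_id", call. = FALSE)
  for (tb in c("visits", "diagnoses", "labs", "procedures")) {
    ids <- bundle[[tb]]$patient_id
    if (length(ids) && !all(ids %in% demo$patient_id)) {
      stop(sprintf("%s table references unknown patient_id", tb), call. = FALSE)
    }
  }

  # condition flags: match the (few) unique codes once, then join back
  diag <- copy(as.data.table(bundle$diagnoses))
  diag[, date := as.Date(date)]
  diag <- diag[in_window(date, condition_period)]
  flags <- data.table(patient_id = demo$patient_id)
  uc <- unique(diag[, .(code, code_system)])
  for (nm in names(code_lists)) {
    cl <- code_lists[[nm]]
    hit_codes <- uc[code_system == cl$code_system][matches_code_list(code, cl)]
    hit_pat <- unique(diag[hit_codes, on = c("code", "code_system")]$patient_id)
    flags[, (paste0("cond_", nm)) := patient_id %in% hit_pat]
  }

  # qualifying visits
  qv <- qualify_visits_all(bundle$visits, visit_window, min_minutes)
  nv <- qv[, .(n_visits = .N), by = patient_id]

  # hemodialysis exposure
  proc <- copy(as.data.table(bundle$procedures))
  hd_ids <- character()
  if (nrow(proc)) {
    proc[, date := as.Date(date)]
    if ("procedure" %in% names(proc)) proc <- proc[procedure == "hemodialysis"]
    hd_ids <- unique(proc[in_window(date, dialysis_window)]$patient_id)
  }

  # eGFR categories (vectorized over the labs table)
  labs <- copy(as.data.table(bundle$labs))
  egfr_cat <- data.table(patient_id = demo$patient_id, egfr_category = "60+")
  if (nrow(labs)) {
    if (any(is.na(labs$egfr) | labs$egfr < 0)) {
      stop("negative or missing eGFR value", call. = FALSE)
    }
    labs[, yr := as.integer(format(as.Date(date), "%Y"))]
    # the Inf guard keeps data.table's empty-group prototype evaluation quiet
    prim <- labs[yr %in% 2018:2019, .(v = min(egfr, Inf)), by = patient_id]
    fall <- labs[yr %in% 2016:2017, .(v = min(egfr, Inf)), by = patient_id]
    fall <- fall[!prim, on = "patient_id"]
    low <- rbind(prim, fall)
    egfr_cat[low, egfr_category := egfr_band(i.v), on = "patient_id"]
  }

  pat <- copy(demo)
  pat[, age := age_ref_year - as.integer(birth_year)]
  pat[, age_group := age_group(birth_year, age_ref_year)]
  pat[, ses_group := ses_group(ses_decile)]
  pat <- flags[pat, on = "patient_id"]
  pat <- egfr_cat[pat, on = "patient_id"]
  pat <- nv[pat, on = "patient_id"]
  pat[is.na(n_visits), n_visits := 0L]

  index_cols <- paste0("cond_", intersect(INDEX_CONDITIONS, names(code_lists)))
  pat[, has_index := Reduce(`|`, .SD), .SDcols = index_cols]

  # eligibility filters, applied in the documented order
  steps <- list(
    age_under_40 = function(p) p$age >= min_age,
    no_index_condition = function(p) p$has_index,
    fewer_than_min_visits = function(p) p$n_visits >= min_visits,
    hemodialysis = function(p) !(p$patient_id %in% hd_ids)
  )
  attrition <- data.table(filter = character(), n_before = integer(),
                          n_removed = integer(), n_after = integer())
  for (nm in names(steps)) {
    keep <- steps[[nm]](pat)
    attrition <- rbind(attrition, data.table(
      filter = nm, n_before = nrow(pat),
      n_removed = sum(!keep), n_after = sum(keep)
    ))
    pat <- pat[keep]
  }

  pat[, c("age", "has_index") := NULL]
  setcolorder(pat, c("patient_id", "clinic_id", "age_group", "sex",
                     "ethnic_group", "region", "ses_group", "egfr_category",
                     "current_smoker", "n_visits"))
  validate_analytic_patients(pat, min_visits = min_visits)
  qv <- qv[patient_id %in% pat$patient_id]
  list(patients = pat[], visits = qv[], attrition = attrition[])
}

# Type invariants of the analytic patient table, asserted on construction.
validate_analytic_patients <- function(pat, min_visits = 3L) {
  stopifnot(
    all(pat$age_group %in% AGE_LEVELS),
    all(pat$sex %in% SEX_LEVELS),
    all(pat$ethnic_group %in% ETHNIC_LEVELS),
    all(pat$region %in% REGION_LEVELS),
    all(pat$ses_group %in% SES_LEVELS),
    all(pat$egfr_category %in% EGFR_LEVELS),
    is.logical(pat$current_smoker),
    all(pat$n_visits >= min_visits)
  )
  invisible(pat)
}
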