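# Delimited-text readers and writers for the five extract tables
# (comma-separated, header row, ISO-8601 dates, UTF-8) plus the generator's
# ground-truth sidecars, and YAML (de)serialization of configurations.

EXTRACT_TABLES <- c("demographics", "visits", "diagnoses", "labs", "procedures")
SIDE_TABLES <- c("ground_truth", "clinic_effects")

EXTRACT_SCHEMAS <- list(
  demographics = c(patient_id = "character", birth_year = "integer",
                   sex = "character", ethnic_group = "character",
                   region = "character", ses_decile = "integer",
                   current_smoker = "logical", clinic_id = "character"),
  visits = c(patient_id = "character", clinic_id = "character",
             provider_role = "character", date = "Date",
             duration_minutes = "numeric", modality = "character"),
  diagnoses = c(patient_id = "character", code = "character",
                code_system = "character", date = "Date"),
  labs = c(patient_id = "character", egfr = "numeric", date = "Date"),
  procedures = c(patient_id = "character", procedure = "character",
                 date = "Date")
)

#' Write a cohort bundle as delimited text
#'
#' One CSV per table (ISO-8601 dates), the ground-truth sidecars when
#' present, and the generator configuration as YAML.
#'
#' @param bundle a `cohort_bundle` (or any list holding the extract tables)
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_extract <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c(EXTRACT_TABLES, SIDE_TABLES)) {
    if (!is.null(bundle[[tb]])) {
      fwrite(as.data.table(bundle[[tb]]), file.path(dir, paste0(tb, ".csv")),
             dateTimeAs = "ISO")
    }
  }
  if (!is.null(bundle$config)) {
    write_generator_config(bundle$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory of delimited tables
#'
#' Schema-validated with explicit types; the five extract tables are
#' required, sidecars are read when present.
#'
#' @param dir directory written by [write_extract()] (or assembled by hand)
#' @return a `cohort_bundle`
#' @export
read_extract <- function(dir) {
  out <- list()
  for (tb in EXTRACT_TABLES) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      stop("missing extract table: ", path, call. = FALSE)
    }
    sch <- EXTRACT_SCHEMAS[[tb]]
    dt <- fread(path, colClasses = sch, na.strings = "")
    miss <- setdiff(names(sch), names(dt))
    if (length(miss)) {
      stop(sprintf("table %s is missing columns: %s", tb,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (cn in names(sch)[sch == "Date"]) dt[, (cn) := as.Date(get(cn))]
    out[[tb]] <- dt[]
  }
  for (tb in SIDE_TABLES) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(path)) out[[tb]] <- fread(path)
  }
  cfg <- file.path(dir, "config.yaml")
  if (file.exists(cfg)) out$config <- read_generator_config(cfg)
  structure(out, class = "cohort_bundle")
}

#' Serialize a generator configuration to YAML
#' @param config a [generator_config()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$study_window <- format(x$study_window)
  x$prevalences <- as.list(x$prevalences)
  x$true_log_odds <- as.list(x$true_log_odds)
  x$egfr_distribution <- as.list(x$egfr_distribution)
  x$egfr_missing <- as.list(x$egfr_missing)
  x$ineligible_fractions <- as.list(x$ineligible_fractions)
  # maximum precision so doubles round-trip exactly
  yaml::write_yaml(x, path, precision = 22L)
  invisible(path)
}

#' Read a generator configuration from YAML
#' @param path file written by [write_generator_config()]
#' @return a validated [generator_config()]
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(
    n_patients = x$n_patients, n_clinics = x$n_clinics,
    clinic_size_concentration = x$clinic_size_concentration,
    study_window = as.Date(unlist(x$study_window)),
    prevalences = unlist(x$prevalences),
    true_log_odds = unlist(x$true_log_odds),
    clinic_effect_sd = x$clinic_effect_sd,
    baseline_flag_rate = x$baseline_flag_rate,
    flag_threshold = x$flag_threshold,
    mean_visits_per_2y = x$mean_visits_per_2y,
    visit_duration_lognormal_params = unlist(x$visit_duration_lognormal_params),
    smoking_rate = x$smoking_rate,
    egfr_distribution = unlist(x$egfr_distribution),
    egfr_missing = unlist(x$egfr_missing),
    ineligible_fractions = unlist(x$ineligible_fractions),
    seed = x$seed
  )
}
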