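# Fixtures are built in code: a tiny hand-written extract with known
# eligibility outcomes, plus a small generator configuration for fast runs.

quick_config <- function(...) {
  args <- utils::modifyList(list(n_patients = 400L, n_clinics = 6L, seed = 99L),
                            list(...))
  do.call(generator_config, args)
}

# Six patients exercising every eligibility filter:
#   P1 eligible diabetic, five 60-day-spaced qualifying visits, eGFR 52
#   P2 born 1977 (age 38 in 2015) -> excluded by age
#   P3 eligible but only two qualifying visits -> excluded
#   P4 eligible but hemodialysis in 2016 -> excluded
#   P5 hypertension only (no index condition) -> excluded
#   P6 eligible heart-failure patient, four qualifying visits among noise
tiny_bundle <- function() {
  demographics <- data.frame(
    patient_id = paste0("P", 1:6),
    birth_year = c(1950L, 1977L, 1950L, 1950L, 1950L, 1940L),
    sex = c("Female", "Male", "Male", "Female", "Male", "Male"),
    ethnic_group = c("General", "Arab", "General", "Ultra-Orthodox",
                     "General", "General"),
    region = c("Central", "North", "South", "Jerusalem", "Central", "South"),
    ses_decile = c(9L, 2L, 5L, 7L, 4L, 1L),
    current_smoker = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    clinic_id = c("C1", "C1", "C2", "C2", "C1", "C2")
  )
  p1_dates <- as.Date("2018-02-01") + 60 * (0:4)
  p3_dates <- as.Date("2018-03-01") + c(0, 90)
  p4_dates <- as.Date("2018-04-01") + 45 * (0:3)
  p6_dates <- as.Date("2018-01-15") + c(0, 100, 250, 500)
  visits <- rbind(
    data.frame(patient_id = "P1", clinic_id = "C1",
               provider_role = "family_physician", date = p1_dates,
               duration_minutes = 12, modality = "in_person"),
    data.frame(patient_id = "P2", clinic_id = "C1",
               provider_role = "family_physician",
               date = as.Date("2018-06-01") + 30 * (0:5),
               duration_minutes = 10, modality = "in_person"),
    data.frame(patient_id = "P3", clinic_id = "C2",
               provider_role = "family_physician", date = p3_dates,
               duration_minutes = 8, modality = "phone"),
    data.frame(patient_id = "P4", clinic_id = "C2",
               provider_role = "family_physician", date = p4_dates,
               duration_minutes = 9, modality = "in_person"),
    data.frame(patient_id = "P5", clinic_id = "C1",
               provider_role = "family_physician",
               date = as.Date("2018-05-01") + 50 * (0:4),
               duration_minutes = 15, modality = "video"),
    data.frame(patient_id = "P6", clinic_id = "C2",
               provider_role = "family_physician", date = p6_dates,
               duration_minutes = 7, modality = "in_person"),
    # noise around P6: too short, wrong provider, outside window
    data.frame(patient_id = "P6", clinic_id = "C2",
               provider_role = "family_physician",
               date = as.Date("2018-02-20"), duration_minutes = 3,
               modality = "text"),
    data.frame(patient_id = "P6", clinic_id = "C2",
               provider_role = "other", date = as.Date("2018-03-20"),
               duration_minutes = 30, modality = "in_person"),
    data.frame(patient_id = "P6", clinic_id = "C2",
               provider_role = "family_physician",
               date = as.Date("2017-06-15"), duration_minutes = 20,
               modality = "in_person")
  )
  diagnoses <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P6"),
    code = c("250.01", "250.0", "250.1", "250.9", "401.1", "428.0", "F32.1"),
    code_system = c(rep("ICD9", 6), "ICD10"),
    date = as.Date(c("2017-03-01", "2018-01-01", "2016-07-01", "2019-02-01",
                     "2018-08-01", "2016-05-01", "2018-09-01"))
  )
  labs <- data.frame(
    patient_id = c("P1", "P6", "P6"),
    egfr = c(52, 72, 41),
    date = as.Date(c("2018-06-01", "2018-03-01", "2019-05-01"))
  )
  procedures <- data.frame(
    patient_id = "P4", procedure = "hemodialysis",
    date = as.Date("2016-09-15")
  )
  list(demographics = demographics, visits = visits, diagnoses = diagnoses,
       labs = labs, procedures = procedures)
}

# all-pairs concordance oracle (events vs non-events, ties count one half)
brute_force_concordance <- function(p, y) {
  pe <- p[y == 1]
  pn <- p[y == 0]
  tot <- 0
  for (a in pe) {
    tot <- tot + sum(a > pn) + 0.5 * sum(a == pn)
  }
  tot / (length(pe) * length(pn))
}

# regex/enumeration-based oracle for a single code pattern, independent of
# the package's compiled matchers
oracle_pattern_match <- function(pattern, codes) {
  p <- toupper(gsub("–|—", "-", trimws(pattern)))
  root_of <- function(x) vapply(strsplit(x, ".", fixed = TRUE), `[`, "", 1L)
  if (grepl("-", p, fixed = TRUE)) {
    ends <- strsplit(p, "-", fixed = TRUE)[[1L]]
    lo_x <- sub("X$", "", ends[1L]); hi_x <- sub("X$", "", ends[2L])
    hi_had_x <- grepl("X$", ends[2L])
    if (!grepl("\\.", lo_x) && !grepl("\\.", hi_x)) {
      letter <- gsub("[0-9.]", "", lo_x)
      lo <- as.integer(gsub("[^0-9]", "", lo_x))
      hi <- as.integer(gsub("[^0-9]", "", hi_x))
      wanted <- paste0(letter, sprintf("%03d", lo:hi))
      root_of(codes) %in% wanted
    } else {
      lo <- as.numeric(gsub("[A-Z]", "", lo_x))
      hi <- as.numeric(gsub("[A-Z]", "", hi_x))
      letter <- gsub("[0-9.]", "", lo_x)
      v <- suppressWarnings(as.numeric(gsub("[A-Z]", "", codes)))
      ok <- !is.na(v) & gsub("[0-9.]", "", root_of(codes)) == letter & v >= lo
      up <- !is.na(v) & (v <= hi)
      if (hi_had_x) up <- up | grepl(paste0("^", gsub("\\.", "\\\\.", hi_x)), codes)
      ok & up
    }
  } else if (grepl("X$", p)) {
    stem <- sub("\\.?X$", "", p)
    if (grepl("\\.", stem)) {
      grepl(paste0("^", gsub("\\.", "\\\\.", stem)), codes)
    } else {
      grepl(paste0("^", stem, "($|\\.)"), codes)
    }
  } else if (grepl("^[A-Z]?[0-9]{1,3}$", p)) {
    root_of(codes) == p
  } else {
    codes == p
  }
}

oracle_list_match <- function(cl, codes) {
  inc <- Reduce(`|`, lapply(cl$include_patterns, oracle_pattern_match, codes = codes))
  if (length(cl$exclude_patterns)) {
    exc <- Reduce(`|`, lapply(cl$exclude_patterns, oracle_pattern_match, codes = codes))
    inc & !exc
  } else {
    inc
  }
}

# every syntactically plausible 3-digit-root code with 0-2 decimal digits
icd9_universe <- function(roots = 100:999) {
  r <- sprintf("%03d", roots)
  c(r,
    paste0(rep(r, each = 10), ".", 0:9),
    paste0(rep(r, each = 100), ".", sprintf("%02d", 0:99)))
}

icd10_f_universe <- function() {
  r <- sprintf("F%02d", 0:99)
  c(r,
    paste0(rep(r, each = 10), ".", 0:9),
    paste0(rep(r, each = 100), ".", sprintf("%02d", 0:99)))
}
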