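# Synthetic HMO extract generator. Produces demographics, visits, diagnoses,
# labs and procedures tables with known ground-truth regularity effects:
# each patient's inter-visit gaps follow a gamma renewal process whose
# target COV is chosen (via a Monte-Carlo calibration of the sample-COV
# distribution) so that the probability of crossing the least-regular
# threshold follows a logistic model in the patient's linear predictor plus
# a clinic-level random effect. Condition prevalences default to the
# marginal rates of a 70k-patient chronic-disease cohort; effect sizes
# default to the log adjusted odds ratios of the corresponding risk model.

#' Default condition prevalences (eligible-cohort marginals)
#' @return named probability vector
#' @export
default_prevalences <- function() {
  c(atrial_fibrillation = 0.122, cancer = 0.110, chronic_lung_disease = 0.289,
    cad_angina = 0.289, cad_mi = 0.109, dementia = 0.012, diabetes = 0.783,
    epilepsy = 0.009, headache = 0.067, heart_failure = 0.168,
    hypertension = 0.462, ibd = 0.018, osteoporosis = 0.205, pad = 0.108,
    rheumatoid_arthritis = 0.028, sleep_disorders = 0.050, stroke = 0.047,
    vte = 0.053, alcohol_misuse = 0.003, adhd = 0.018, anxiety = 0.298,
    bipolar = 0.014, depression = 0.282, ptsd = 0.026, schizophrenia = 0.019)
}

#' Default ground-truth log-odds per model term
#'
#' Log adjusted odds ratios used as simulation truth; terms absent from the
#' map contribute zero.
#' @return named numeric vector keyed by [design_terms()] names
#' @export
default_true_log_odds <- function() {
  log(c(
    "age:50-59" = 0.92, "age:60-69" = 0.86, "age:70-79" = 0.83,
    "age:80-89" = 0.86, "age:90+" = 0.90,
    "sex:Male" = 1.19,
    "ethnic:Arab" = 1.19, "ethnic:Ultra-Orthodox" = 1.10,
    "region:North" = 1.04, "region:Jerusalem" = 1.10, "region:South" = 1.00,
    "ses:Higher" = 1.09, "ses:Lower" = 1.07, "ses:Lowest" = 1.06,
    "egfr:45-59" = 0.98, "egfr:30-44" = 1.00, "egfr:<30" = 1.00,
    "cond:atrial_fibrillation" = 1.08, "cond:cancer" = 0.85,
    "cond:chronic_lung_disease" = 0.93, "cond:cad_angina" = 0.90,
    "cond:cad_mi" = 1.07, "cond:dementia" = 1.05, "cond:diabetes" = 0.79,
    "cond:epilepsy" = 0.94, "cond:heart_failure" = 0.98,
    "cond:hypertension" = 0.92, "cond:ibd" = 1.00, "cond:osteoporosis" = 0.85,
    "cond:pad" = 0.92, "cond:rheumatoid_arthritis" = 0.92,
    "cond:stroke" = 0.94, "cond:vte" = 1.09,
    "cond:alcohol_misuse" = 1.28, "cond:adhd" = 0.91, "cond:anxiety" = 0.91,
    "cond:bipolar" = 1.12, "cond:depression" = 0.92, "cond:ptsd" = 0.97,
    "cond:schizophrenia" = 0.80,
    "smoker" = 1.12
  ))
}

AGE_BAND_YEARS <- list(
  "40-49" = c(1966L, 1975L), "50-59" = c(1956L, 1965L),
  "60-69" = c(1946L, 1955L), "70-79" = c(1936L, 1945L),
  "80-89" = c(1926L, 1935L), "90+" = c(1910L, 1925L)
)
AGE_BAND_PROBS <- c(0.1268, 0.2615, 0.3257, 0.1915, 0.0843, 0.0102)
ETHNIC_PROBS <- c(General = 0.7788, Arab = 0.1618, "Ultra-Orthodox" = 0.0594)
REGION_PROBS <- c(Central = 0.3029, North = 0.2601, Jerusalem = 0.1312,
                  South = 0.3057)
SES_GROUP_PROBS <- c(Highest = 0.0993, Higher = 0.1921, Lower = 0.5165,
                     Lowest = 0.1921)
SES_GROUP_DECILES <- list(Highest = 8:10, Higher = 6:7, Lower = 4:5, Lowest = 1:3)
EGFR_PROBS <- c("60+" = 0.7889, "45-59" = 0.1149, "30-44" = 0.0600,
                "<30" = 0.0362)
EGFR_RANGES <- list("60+" = c(60, 105), "45-59" = c(45, 59.9),
                    "30-44" = c(30, 44.9), "<30" = c(8, 29.9))
MODALITY_PROBS <- c(in_person = 0.65, phone = 0.20, text = 0.10, video = 0.05)

#' Synthetic-cohort generator configuration
#'
#' @param n_patients,n_clinics positive integers
#' @param clinic_size_concentration gamma shape controlling clinic-size skew
#'   (smaller = more skewed)
#' @param study_window two dates, the qualifying-visit window
#' @param prevalences named condition probabilities (eligible-cohort
#'   marginals); see [default_prevalences()]
#' @param true_log_odds named ground-truth log-odds; names must be design
#'   terms of [design_spec()]
#' @param clinic_effect_sd SD of clinic-level log-odds offsets
#' @param baseline_flag_rate flag probability of the all-reference patient
#' @param flag_threshold COV threshold the generator calibrates against
#' @param mean_visits_per_2y mean qualifying visits per eligible patient over
#'   the study window (truncated-Poisson, minimum 3)
#' @param visit_duration_lognormal_params `c(meanlog, sdlog)` of the visit
#'   duration distribution (median 5 minutes by default, so the 5-minute
#'   qualifying filter bites)
#' @param smoking_rate current-smoker probability
#' @param egfr_distribution named probabilities over the four eGFR bands
#' @param egfr_missing `c(fallback_only, none)`: fractions with labs only in
#'   2016-2017, and with no labs at all
#' @param ineligible_fractions named probabilities for planned filter
#'   failures: `under_40`, `no_index_condition`, `hemodialysis`,
#'   `under_3_visits`
#' @param seed integer master seed; it expands into independent per-table
#'   substreams
#' @return a `generator_config` object
#' @export
generator_config <- function(n_patients = 2000L,
                             n_clinics = 30L,
                             clinic_size_concentration = 1.5,
                             study_window = as.Date(c("2018-01-01", "2019-12-31")),
                             prevalences = default_prevalences(),
                             true_log_odds = default_true_log_odds(),
                             clinic_effect_sd = 0.25,
                             baseline_flag_rate = 0.20,
                             flag_threshold = 1.2,
                             mean_visits_per_2y = 12,
                             visit_duration_lognormal_params = c(log(5), 0.6),
                             smoking_rate = 0.195,
                             egfr_distribution = EGFR_PROBS,
                             egfr_missing = c(fallback_only = 0.029, none = 0.011),
                             ineligible_fractions = c(under_40 = 0.04,
                                                      no_index_condition = 0.04,
                                                      hemodialysis = 0.02,
                                                      under_3_visits = 0.05),
                             seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_clinics <- as.integer(n_clinics)
  if (is.na(n_patients) || n_patients < 1L) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  if (is.na(n_clinics) || n_clinics < 1L) {
    stop("n_clinics must be a positive integer", call. = FALSE)
  }
  study_window <- as_window(study_window)
  if (!is_probability(prevalences) || is.null(names(prevalences))) {
    stop("prevalences must be a named vector of probabilities", call. = FALSE)
  }
  if (!is_probability(baseline_flag_rate) || baseline_flag_rate <= 0 ||
      baseline_flag_rate >= 1) {
    stop("baseline_flag_rate must lie strictly inside (0, 1)", call. = FALSE)
  }
  need <- c("under_40", "no_index_condition", "hemodialysis", "under_3_visits")
  if (!all(need %in% names(ineligible_fractions)) ||
      !is_probability(ineligible_fractions[need])) {
    stop("ineligible_fractions must name probabilities for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is_probability(egfr_distribution) ||
      abs(sum(egfr_distribution) - 1) > 1e-6) {
    stop("egfr_distribution must be probabilities summing to 1", call. = FALSE)
  }
  if (!is.numeric(clinic_effect_sd) || clinic_effect_sd < 0) {
    stop("clinic_effect_sd must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(mean_visits_per_2y) || mean_visits_per_2y <= 0) {
    stop("mean_visits_per_2y must be positive", call. = FALSE)
  }
  unknown <- setdiff(names(true_log_odds), design_terms(design_spec()))
  if (length(unknown)) {
    stop("true_log_odds names are not design terms: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, n_clinics = n_clinics,
         clinic_size_concentration = clinic_size_concentration,
         study_window = study_window, prevalences = prevalences,
         true_log_odds = true_log_odds, clinic_effect_sd = clinic_effect_sd,
         baseline_flag_rate = baseline_flag_rate,
         flag_threshold = flag_threshold,
         mean_visits_per_2y = mean_visits_per_2y,
         visit_duration_lognormal_params = visit_duration_lognormal_params,
         smoking_rate = smoking_rate,
         egfr_distribution = egfr_distribution,
         egfr_missing = egfr_missing,
         ineligible_fractions = ineligible_fractions[need],
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d patients, %d clinics, window %s..%s, seed %d\n",
    x$n_patients, x$n_clinics, format(x$study_window[1]),
    format(x$study_window[2]), x$seed))
  invisible(x)
}

in_substream <- function(seed, k, expr) {
  with_preserved_rng({
    set.seed(substream_seed(seed, k))
    expr
  })
}

# zero/one/two-truncated Poisson: visit counts for eligible patients
rztpois3 <- function(n, lambda) {
  u <- runif(n, ppois(2, lambda), 1)
  pmax(3L, qpois(u, lambda))
}

# Vectorized gamma-renewal gap simulator. For series i with target COV c_i
# and n_i visits, n_i - 1 gaps are drawn gamma(shape 1/c_i^2) (constant when
# c_i = 0), rescaled so the series fits the window after a random start and
# end offset, and rounded to whole days (minimum 1). The sample COV of the
# gaps is scale-free, so the rescaling leaves the regularity target intact.
sim_gaps <- function(target_cov, n_visits, win_len) {
  m <- length(target_cov)
  n_gaps <- as.integer(n_visits) - 1L
  stopifnot(length(n_gaps) == m, all(n_gaps >= 1L), all(target_cov >= 0))
  u1 <- runif(m, 0, 0.08 * win_len)
  u2 <- runif(m, 0, 0.08 * win_len)
  span <- win_len - u1 - u2 - n_gaps - 1
  id <- rep.int(seq_len(m), n_gaps)
  cv <- target_cov[id]
  raw <- rep(1, length(id))
  pos <- cv > 0
  if (any(pos)) {
    raw[pos] <- rgamma(sum(pos), shape = 1 / cv[pos]^2, rate = 1)
  }
  tot <- as.vector(rowsum(raw, id))
  gaps <- raw * (span[id] / tot[id])
  gaps <- pmax(1L, as.integer(round(gaps)))
  list(id = id, gaps = gaps, start = as.integer(round(u1)), n_gaps = n_gaps)
}

series_sample_cov <- function(s) {
  g <- as.numeric(s$gaps)
  n <- s$n_gaps
  sm <- as.vector(rowsum(g, s$id))
  sq <- as.vector(rowsum(g^2, s$id))
  mu <- sm / n
  v <- pmax(0, (sq - n * mu^2) / (n - 1))
  sqrt(v) / mu
}

#' Sample one visit-date series with a target regularity
#'
#' Inter-visit gaps are drawn from a gamma renewal process with shape
#' `1/target_cov^2` (constant gaps when `target_cov` is 0), rescaled to fit
#' the window and rounded to whole days. The expected sample COV converges
#' to `target_cov` as the series grows.
#'
#' @param target_cov nonnegative target coefficient of variation
#' @param n_visits integer >= 2
#' @param window closed date window the series must fit in
#' @param seed optional seed; when `NULL` the current RNG stream is used
#' @return sorted `Date` vector of length `n_visits`
#' @export
sample_visit_series <- function(target_cov, n_visits,
                                window = as.Date(c("2018-01-01", "2019-12-31")),
                                seed = NULL) {
  window <- as_window(window)
  if (!is.numeric(target_cov) || length(target_cov) != 1L || target_cov < 0) {
    stop("target_cov must be a single nonnegative number", call. = FALSE)
  }
  n_visits <- as.integer(n_visits)
  if (is.na(n_visits) || n_visits < 2L) {
    stop("n_visits must be an integer >= 2", call. = FALSE)
  }
  draw <- function() {
    win_len <- as.integer(diff(window)) + 1L
    s <- sim_gaps(target_cov, n_visits, win_len)
    window[1L] + s$start + c(0L, cumsum(s$gaps))
  }
  dates <- if (is.null(seed)) {
    draw()
  } else {
    with_preserved_rng({
      set.seed(as.integer(seed))
      draw()
    })
  }
  pmin(dates, window[2L])
}

calibration_key <- function(config) {
  paste(config$flag_threshold, config$mean_visits_per_2y,
        as.integer(diff(config$study_window)) + 1L, sep = "|")
}

#' Calibration curve from target COV to flag probability
#'
#' Monte-Carlo estimate of `P(sample COV >= flag_threshold)` over a grid of
#' target COV values, marginal over the configured visit-count distribution
#' and simulated through the exact series path (gamma gaps, window
#' rescaling, whole-day rounding). Isotonic-smoothed, memoised per
#' (threshold, visit rate, window length), and computed under a fixed
#' internal RNG stream so it is a deterministic function of the
#' configuration.
#'
#' @param config a [generator_config()]
#' @param grid target COV grid
#' @param n_rep Monte-Carlo replicates per grid point
#' @return data.table with `target_cov`, `p_flag` (nondecreasing)
#' @export
cov_flag_calibration <- function(config, grid = seq(0.05, 3, by = 0.05),
                                 n_rep = 6000L) {
  key <- calibration_key(config)
  if (is.null(.temporeg_env$calibration)) {
    .temporeg_env$calibration <- list()
  }
  cached <- .temporeg_env$calibration[[key]]
  if (!is.null(cached)) return(copy(cached))
  win_len <- as.integer(diff(config$study_window)) + 1L
  p <- with_preserved_rng({
    set.seed(987654321L)
    vapply(grid, function(cv) {
      nv <- rztpois3(n_rep, config$mean_visits_per_2y)
      s <- sim_gaps(rep(cv, n_rep), nv, win_len)
      mean(series_sample_cov(s) >= config$flag_threshold)
    }, numeric(1))
  })
  p <- isoreg(grid, p)$yf
  cal <- data.table(target_cov = c(0, grid), p_flag = c(0, p))
  .temporeg_env$calibration[[key]] <- copy(cal)
  cal
}

#' Target COV realizing a logistic flag probability
#'
#' Maps a patient's linear predictor (plus clinic effect) to the target COV
#' whose flag probability, under the calibrated sample-COV distribution,
#' equals `logistic(intercept + lp + clinic_effect)`; the intercept is the
#' logit of `baseline_flag_rate`, so the all-reference patient flags at the
#' configured baseline rate. Monotone nondecreasing in `lp + clinic_effect`.
#'
#' @param lp numeric linear predictor(s)
#' @param clinic_effect clinic-level log-odds offset(s)
#' @param config a [generator_config()]
#' @return nonnegative target COV value(s)
#' @export
regularity_from_linear_predictor <- function(lp, clinic_effect = 0, config) {
  stopifnot(is.finite(lp), is.finite(clinic_effect))
  cal <- cov_flag_calibration(config)
  p <- plogis(qlogis(config$baseline_flag_rate) + lp + clinic_effect)
  keep <- rev(!duplicated(rev(cal$p_flag)))
  approx(cal$p_flag[keep], cal$target_cov[keep], xout = p, rule = 2,
         ties = "ordered")$y
}

#' Generate a synthetic HMO extract
#'
#' Draws demographics, condition flags (index-condition marginals are
#' calibrated so eligible-cohort prevalences match the configured values),
#' kidney-function labs, clinic assignments with Dirichlet-multinomial
#' sizes, hemodialysis procedures for planned exclusions, concrete ICD
#' diagnosis codes drawn from the packaged code lists, and visit series
#' whose regularity follows the configured ground-truth effects. Fully
#' deterministic for a fixed configuration (the master seed expands into
#' per-table substreams).
#'
#' @param config a [generator_config()]
#' @return a `cohort_bundle`: `demographics`, `visits`, `diagnoses`, `labs`,
#'   `procedures`, `ground_truth` (per patient), `clinic_effects` (per
#'   clinic), and the `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  win <- config$study_window
  win_len <- as.integer(diff(win)) + 1L
  patient_id <- sprintf("P%07d", seq_len(n))
  clinic_ids <- sprintf("C%04d", seq_len(config$n_clinics))
  frac <- config$ineligible_fractions

  # --- substream 1: demographics, clinic assignment, planned eligibility
  demo <- in_substream(config$seed, 1L, {
    marks <- sapply(names(frac), function(nm) runif(n) < frac[[nm]])
    if (n == 1L) marks <- matrix(marks, nrow = 1L, dimnames = list(NULL, names(frac)))
    band <- sample(names(AGE_BAND_YEARS), n, TRUE, prob = AGE_BAND_PROBS)
    band_lo <- vapply(AGE_BAND_YEARS, `[`, integer(1), 1L)[band]
    band_hi <- vapply(AGE_BAND_YEARS, `[`, integer(1), 2L)[band]
    birth_year <- band_lo + as.integer(floor(runif(n) * (band_hi - band_lo + 1L)))
    birth_year[marks[, "under_40"]] <-
      sample(1976:1985, sum(marks[, "under_40"]), TRUE)
    clinic_w <- rgamma(config$n_clinics, shape = config$clinic_size_concentration)
    clinic_w <- clinic_w / sum(clinic_w)
    data.table(
      patient_id = patient_id,
      birth_year = unname(birth_year),
      sex = sample(SEX_LEVELS, n, TRUE, prob = c(0.4997, 0.5003)),
      ethnic_group = sample(names(ETHNIC_PROBS), n, TRUE, prob = ETHNIC_PROBS),
      region = sample(names(REGION_PROBS), n, TRUE, prob = REGION_PROBS),
      ses_decile = {
        grp <- sample(names(SES_GROUP_PROBS), n, TRUE, prob = SES_GROUP_PROBS)
        d_lo <- vapply(SES_GROUP_DECILES, `[`, integer(1), 1L)[grp]
        d_n <- vapply(SES_GROUP_DECILES, length, integer(1))[grp]
        d_lo + as.integer(floor(runif(n) * d_n))
      },
      current_smoker = runif(n) < config$smoking_rate,
      clinic_id = clinic_ids[sample.int(config$n_clinics, n, TRUE, prob = clinic_w)],
      mark_under_40 = marks[, "under_40"],
      mark_no_index = marks[, "no_index_condition"],
      mark_hemodialysis = marks[, "hemodialysis"],
      mark_under_3_visits = marks[, "under_3_visits"]
    )
  })

  # --- substream 2: condition flags
  prev <- config$prevalences
  index_names <- intersect(INDEX_CONDITIONS, names(prev))
  flags <- in_substream(config$seed, 2L, {
    fl <- data.table(patient_id = patient_id)
    # index conditions: unconditional rates q = p * Z chosen so that the
    # conditional-on-eligibility marginals equal the configured prevalences
    p_idx <- prev[index_names]
    zfun <- function(z) 1 - prod(1 - p_idx * z) - z
    Z <- uniroot(zfun, c(1e-6, 1), tol = 1e-12)$root
    q_idx <- p_idx * Z
    idx_draw <- matrix(runif(n * length(q_idx)), nrow = n) <
      matrix(q_idx, nrow = n, ncol = length(q_idx), byrow = TRUE)
    needs_index <- !demo$mark_no_index
    repeat {
      redo <- which(needs_index & rowSums(idx_draw) == 0L)
      if (length(redo) == 0L) break
      idx_draw[redo, ] <- matrix(runif(length(redo) * length(q_idx)),
                                 nrow = length(redo)) <
        matrix(q_idx, nrow = length(redo), ncol = length(q_idx), byrow = TRUE)
    }
    idx_draw[!needs_index, ] <- FALSE
    colnames(idx_draw) <- index_names
    for (nm in index_names) fl[, (paste0("cond_", nm)) := idx_draw[, nm]]
    for (nm in setdiff(names(prev), index_names)) {
      fl[, (paste0("cond_", nm)) := runif(n) < prev[[nm]]]
    }
    fl
  })

  # --- substream 3: kidney function
  egfr <- in_substream(config$seed, 3L, {
    cat_ <- sample(names(config$egfr_distribution), n, TRUE,
                   prob = config$egfr_distribution)
    miss <- sample(c("present", "fallback_only", "none"), n, TRUE,
                   prob = c(1 - sum(config$egfr_missing),
                            config$egfr_missing[["fallback_only"]],
                            config$egfr_missing[["none"]]))
    data.table(patient_id = patient_id, egfr_true = cat_, egfr_missing = miss,
               # the model-relevant category: imputation target for no-lab patients
               egfr_model = ifelse(miss == "none", "60+", cat_))
  })

  # --- substream 4: clinic effects
  clinic_eff <- in_substream(config$seed, 4L, {
    data.table(clinic_id = clinic_ids,
               effect = rnorm(config$n_clinics, 0, config$clinic_effect_sd))
  })

  # --- ground-truth linear predictor (no RNG)
  ptab <- data.table(
    age_group = age_group(demo$birth_year),
    sex = demo$sex, ethnic_group = demo$ethnic_group, region = demo$region,
    ses_group = ses_group(demo$ses_decile),
    egfr_category = egfr$egfr_model,
    current_smoker = demo$current_smoker
  )
  ptab[is.na(age_group), age_group := "40-49"] # under-40s never reach the model
  for (cn in default_model_conditions()) {
    col <- paste0("cond_", cn)
    ptab[, (col) := if (col %in% names(flags)) flags[[col]] else FALSE]
  }
  enc <- encode_design(ptab, design_spec(), drop_constant = FALSE)
  terms <- setdiff(colnames(enc$x), "(Intercept)")
  beta <- setNames(numeric(length(terms)), terms)
  tlo <- config$true_log_odds
  beta[intersect(names(tlo), terms)] <- tlo[intersect(names(tlo), terms)]
  lp <- drop(enc$x[, terms, drop = FALSE] %*% beta)
  ce <- clinic_eff$effect[match(demo$clinic_id, clinic_eff$clinic_id)]
  eta <- qlogis(config$baseline_flag_rate) + lp + ce
  target_cov <- regularity_from_linear_predictor(lp, ce, config)

  # --- substream 5: visits
  meanlog <- config$visit_duration_lognormal_params[1L]
  sdlog <- config$visit_duration_lognormal_params[2L]
  p5 <- plnorm(5, meanlog, sdlog)
  visits_out <- in_substream(config$seed, 5L, {
    n_vis <- rztpois3(n, config$mean_visits_per_2y)
    few <- demo$mark_under_3_visits
    n_vis[few] <- sample(1:2, sum(few), TRUE)
    multi <- which(n_vis >= 2L)
    s <- sim_gaps(target_cov[multi], n_vis[multi], win_len)
    # qualifying dates: start offset + cumulative gaps, per series
    gap_dt <- data.table(row = s$id, gap = s$gaps)
    gap_dt[, day := cumsum(gap), by = row]
    first <- data.table(row = seq_along(multi), day = 0L)
    qdays <- rbind(first, gap_dt[, .(row, day)])
    qdays[, day := day + s$start[row]]
    qdays[, patient := multi[row]]
    single <- which(n_vis == 1L)
    if (length(single)) {
      qdays <- rbind(qdays,
                     data.table(row = NA_integer_,
                                day = sample.int(win_len, length(single), TRUE) - 1L,
                                patient = single))
    }
    nq <- nrow(qdays)
    qualifying <- data.table(
      patient_id = patient_id[qdays$patient],
      clinic_id = demo$clinic_id[qdays$patient],
      provider_role = "family_physician",
      date = win[1L] + qdays$day,
      # rounding must not cross the 5-minute qualifying threshold
      duration_minutes = pmax(round(qlnorm(runif(nq, p5, 1), meanlog, sdlog), 1), 5),
      modality = sample(names(MODALITY_PROBS), nq, TRUE, prob = MODALITY_PROBS)
    )
    # short family-physician contacts (below the qualifying duration)
    n_short <- rpois(n, 2.5)
    si <- rep.int(seq_len(n), n_short)
    short <- data.table(
      patient_id = patient_id[si],
      clinic_id = demo$clinic_id[si],
      provider_role = "family_physician",
      date = win[1L] + sample.int(win_len, length(si), TRUE) - 1L,
      duration_minutes = pmin(round(qlnorm(runif(length(si), 0, p5), meanlog, sdlog), 1), 4.9),
      modality = sample(names(MODALITY_PROBS), length(si), TRUE, prob = MODALITY_PROBS)
    )
    # non-primary-care providers, any duration
    n_oth <- rpois(n, 2)
    oi <- rep.int(seq_len(n), n_oth)
    other <- data.table(
      patient_id = patient_id[oi],
      clinic_id = demo$clinic_id[oi],
      provider_role = "other",
      date = win[1L] + sample.int(win_len, length(oi), TRUE) - 1L,
      duration_minutes = round(qlnorm(runif(length(oi)), meanlog, sdlog), 1),
      modality = sample(names(MODALITY_PROBS), length(oi), TRUE, prob = MODALITY_PROBS)
    )
    # historical family-physician visits before the study window
    hist_start <- as.Date("2016-01-01")
    hist_len <- as.integer(as.Date("2017-12-31") - hist_start) + 1L
    n_hist <- rpois(n, 1.5)
    hi <- rep.int(seq_len(n), n_hist)
    historical <- data.table(
      patient_id = patient_id[hi],
      clinic_id = demo$clinic_id[hi],
      provider_role = "family_physician",
      date = hist_start + sample.int(hist_len, length(hi), TRUE) - 1L,
      duration_minutes = round(qlnorm(runif(length(hi)), meanlog, sdlog), 1),
      modality = sample(names(MODALITY_PROBS), length(hi), TRUE, prob = MODALITY_PROBS)
    )
    v <- rbind(qualifying, short, other, historical)
    setorder(v, patient_id, date, provider_role, duration_minutes, modality)
    list(visits = v, n_vis = n_vis)
  })
  visits <- visits_out$visits
  n_vis <- visits_out$n_vis

  # --- substream 6: diagnoses with concrete ICD codes
  code_lists <- default_code_lists()
  pools <- condition_code_pools(code_lists)
  diagnoses <- in_substream(config$seed, 6L, {
    period_start <- as.Date("2016-01-01")
    period_len <- as.integer(as.Date("2019-12-31") - period_start) + 1L
    parts <- list()
    for (nm in sort(intersect(names(prev), names(code_lists)))) {
      cl <- code_lists[[nm]]
      has <- which(flags[[paste0("cond_", nm)]])
      if (length(has) == 0L) next
      n_rec <- 1L + rpois(length(has), 0.7)
      ri <- rep.int(has, n_rec)
      pool <- pools[[nm]]
      parts[[nm]] <- data.table(
        patient_id = patient_id[ri],
        code = pool[sample.int(length(pool), length(ri), TRUE)],
        code_system = cl$code_system,
        date = period_start + sample.int(period_len, length(ri), TRUE) - 1L
      )
    }
    # decoy codes that match no list (or only exclusion arms)
    decoy_pool <- data.table(
      code = c("173.2", "173.9", "210.0", "327.35", "780.52", "V70.0",
               "F10.11", "F10.21"),
      code_system = c(rep("ICD9", 6L), "ICD10", "ICD10")
    )
    n_dec <- rpois(n, 0.3)
    di <- rep.int(seq_len(n), n_dec)
    pick <- sample.int(nrow(decoy_pool), length(di), TRUE)
    parts$decoy <- data.table(
      patient_id = patient_id[di],
      code = decoy_pool$code[pick],
      code_system = decoy_pool$code_system[pick],
      date = period_start + sample.int(period_len, length(di), TRUE) - 1L
    )
    dg <- rbindlist(parts, use.names = TRUE)
    setorder(dg, patient_id, date, code_system, code)
    dg
  })

  # --- substream 7: labs
  labs <- in_substream(config$seed, 7L, {
    has_labs <- which(egfr$egfr_missing != "none")
    lo <- vapply(EGFR_RANGES, `[`, numeric(1), 1L)[egfr$egfr_true[has_labs]]
    hi <- vapply(EGFR_RANGES, `[`, numeric(1), 2L)[egfr$egfr_true[has_labs]]
    v1 <- runif(length(has_labs), lo, hi)
    v2 <- v1 + runif(length(has_labs), 0, 20)
    fallback <- egfr$egfr_missing[has_labs] == "fallback_only"
    w_start <- as.Date(ifelse(fallback, "2016-01-01", "2018-01-01"))
    w_len <- ifelse(fallback,
                    as.integer(as.Date("2017-12-31") - as.Date("2016-01-01")) + 1L,
                    as.integer(as.Date("2019-12-31") - as.Date("2018-01-01")) + 1L)
    d1 <- w_start + floor(runif(length(has_labs)) * w_len)
    d2 <- w_start + floor(runif(length(has_labs)) * w_len)
    lb <- data.table(
      patient_id = rep(patient_id[has_labs], 2L),
      egfr = round(c(v1, v2), 1),
      date = c(d1, d2)
    )
    setorder(lb, patient_id, date)
    lb
  })

  # --- substream 8: hemodialysis procedures
  procedures <- in_substream(config$seed, 8L, {
    hd <- which(demo$mark_hemodialysis)
    p_start <- as.Date("2015-01-01")
    p_len <- as.integer(as.Date("2019-12-31") - p_start) + 1L
    n_hd <- if (length(hd)) 1L + rpois(length(hd), 6) else integer(0)
    pi_ <- rep.int(hd, n_hd)
    pr <- data.table(
      patient_id = patient_id[pi_],
      procedure = if (length(pi_)) "hemodialysis" else character(0),
      date = p_start + sample.int(p_len, length(pi_), TRUE) - 1L
    )
    setorder(pr, patient_id, date)
    pr
  })

  ground_truth <- data.table(
    patient_id = patient_id,
    clinic_id = demo$clinic_id,
    lp = lp,
    clinic_effect = ce,
    eta = eta,
    flag_prob = plogis(eta),
    target_cov = target_cov,
    n_visits_planned = n_vis,
    egfr_true = egfr$egfr_true,
    mark_under_40 = demo$mark_under_40,
    mark_no_index = demo$mark_no_index,
    mark_hemodialysis = demo$mark_hemodialysis,
    mark_under_3_visits = demo$mark_under_3_visits,
    planned_eligible = !(demo$mark_under_40 | demo$mark_no_index |
                           demo$mark_hemodialysis | demo$mark_under_3_visits)
  )

  demographics <- demo[, .(patient_id, birth_year, sex, ethnic_group, region,
                           ses_decile, current_smoker, clinic_id)]
  structure(
    list(demographics = demographics[], visits = visits[],
         diagnoses = diagnoses[], labs = labs[], procedures = procedures[],
         ground_truth = ground_truth[], clinic_effects = clinic_eff[],
         config = config),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d patients, %d visits, %d diagnoses, %d labs, %d procedures\n",
    nrow(x$demographics), nrow(x$visits), nrow(x$diagnoses), nrow(x$labs),
    nrow(x$procedures)))
  invisible(x)
}
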