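# The temporal-regularity (TR) statistic: coefficient of variation of the
# intervals between qualifying primary-care visits. Higher COV = less
# temporally regular care; COV 0 = perfectly even spacing.

#' Inter-visit intervals in whole days
#'
#' @param dates sorted, strictly increasing `Date` vector with at least three
#'   distinct dates (same-day visits must be collapsed upstream)
#' @return integer vector of consecutive differences (all positive)
#' @examples
#' inter_visit_intervals(as.Date(c("2018-01-01", "2018-03-02", "2018-05-01")))
#' @export
inter_visit_intervals <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("missing visit dates", call. = FALSE)
  if (length(dates) < 3L) {
    stop("at least three visit dates are required to measure regularity",
         call. = FALSE)
  }
  if (is.unsorted(dates, strictly = FALSE)) {
    stop("visit dates must be sorted ascending", call. = FALSE)
  }
  iv <- as.integer(diff(dates))
  if (any(iv == 0L)) {
    stop("duplicate visit dates: collapse same-day visits upstream",
         call. = FALSE)
  }
  iv
}

#' Coefficient of variation of inter-visit intervals
#'
#' SD of the intervals divided by their mean. The sample SD (n-1 denominator)
#' is the default; the population variant is one flag away since per-patient
#' interval counts are small and either convention is defensible.
#'
#' @param intervals numeric vector of positive intervals, length >= 2
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n)
#' @return nonnegative scalar
#' @examples
#' coefficient_of_variation(c(30, 60, 90)) # 0.5
#' @export
coefficient_of_variation <- function(intervals, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L) {
    stop("need at least two intervals to compute a coefficient of variation",
         call. = FALSE)
  }
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("intervals must be positive and non-missing", call. = FALSE)
  }
  m <- mean(intervals)
  s <- sd(intervals)
  if (sd_type == "population") {
    n <- length(intervals)
    s <- s * sqrt((n - 1) / n)
  }
  s / m
}

#' Per-patient TR scores from a long table of qualifying visit dates
#'
#' @param visit_dates data.frame/data.table with columns `patient_id`, `date`
#'   (qualifying visit dates, same-day visits already collapsed)
#' @param sd_type passed to [coefficient_of_variation()]
#' @return data.table with one row per patient: `patient_id`, `n_visits`,
#'   `mean_interval`, `sd_interval`, `tr`
#' @export
tr_scores <- function(visit_dates, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  dt <- as.data.table(visit_dates)[, .(patient_id, date = as.Date(date))]
  setorder(dt, patient_id, date)
  if (anyDuplicated(dt)) {
    stop("duplicate (patient, date) rows: collapse same-day visits upstream",
         call. = FALSE)
  }
  counts <- dt[, .N, by = patient_id]
  if (nrow(counts) && any(counts$N < 3L)) {
    stop("every patient needs at least three qualifying visit dates",
         call. = FALSE)
  }
  iv <- dt[, .(interval = as.integer(diff(date)), n_visits = .N), by = patient_id]
  out <- iv[, {
    m <- mean(interval)
    s <- sd(interval)
    if (sd_type == "population") s <- s * sqrt((.N - 1) / .N)
    .(n_visits = n_visits[1L], mean_interval = m, sd_interval = s, tr = s / m)
  }, by = patient_id]
  out[]
}

#' Jarque-Bera normality test with Q-Q pairs
#'
#' Moment-based (biased) sample skewness S and kurtosis K; the statistic is
#' `n/6 * (S^2 + (K - 3)^2 / 4)`, asymptotically chi-square with 2 df. Also
#' returns ordered (theoretical, empirical) quantile pairs for a Q-Q plot of
#' the standardized values.
#'
#' @param values numeric vector, n >= 8, non-degenerate
#' @param variable_name label carried in the report
#' @param transform `"none"` or `"log"`; with `"log"` the values are
#'   log-transformed first (zeros/negatives are an error)
#' @return a `normality_report` list: `variable_name`, `n`, `skewness`,
#'   `kurtosis`, `jb_statistic`, `p_value`, `transform`, `qq` (data.table of
#'   theoretical and empirical quantiles)
#' @export
jarque_bera <- function(values, variable_name = "x",
                        transform = c("none", "log")) {
  transform <- match.arg(transform)
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (transform == "log") {
    if (any(values <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    values <- log(values)
  }
  n <- length(values)
  if (n < 8L) stop("need at least 8 observations", call. = FALSE)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    stop("zero variance: normality statistic undefined", call. = FALSE)
  }
  S <- mean(d^3) / m2^1.5
  K <- mean(d^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  p <- pchisq(jb, df = 2, lower.tail = FALSE)
  qq <- data.table(
    theoretical = qnorm(ppoints(n)),
    empirical = sort(d / sqrt(m2))
  )
  structure(
    list(variable_name = variable_name, n = n, skewness = S, kurtosis = K,
         jb_statistic = jb, p_value = p, transform = transform, qq = qq),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf(
    "Jarque-Bera normality check for %s%s (n = %d)\n  skewness %.4f, kurtosis %.4f, JB = %.3f, p = %.3g\n",
    x$variable_name, if (x$transform == "log") " (log scale)" else "",
    x$n, x$skewness, x$kurtosis, x$jb_statistic, x$p_value
  ))
  invisible(x)
}

#' Dichotomize TR into the least-regular group
#'
#' Either flags the least temporally regular quintile (threshold at the
#' empirical 80th percentile, linear-interpolation quantile) or applies a
#' fixed threshold. The flag rule is inclusive: `tr >= threshold`.
#'
#' @param tr named or unnamed numeric vector of TR values
#' @param rule `"empirical_quintile"` or `"fixed_threshold"`
#' @param threshold used by the fixed rule (default 1.2)
#' @return list with `flags` (logical, same order/names as `tr`),
#'   `threshold_used`, `rule`
#' @export
dichotomize <- function(tr, rule = c("empirical_quintile", "fixed_threshold"),
                        threshold = 1.2) {
  rule <- match.arg(rule)
  tr <- as.numeric(tr)
  if (length(tr) == 0L || anyNA(tr)) {
    stop("TR values must be non-empty and non-missing", call. = FALSE)
  }
  if (rule == "empirical_quintile") {
    if (length(unique(tr)) == 1L) {
      stop("degenerate TR distribution: all values identical", call. = FALSE)
    }
    threshold_used <- unname(quantile(tr, 0.8, type = 7))
  } else {
    threshold_used <- threshold
  }
  list(flags = tr >= threshold_used, threshold_used = threshold_used, rule = rule)
}

#' Score a built cohort and flag the least-regular group
#'
#' Convenience wrapper: computes per-patient TR from the cohort's qualifying
#' visit dates, dichotomizes it, and attaches the `flagged` column to the
#' patient table.
#'
#' @param cohort output of [build_cohort()]
#' @param rule,threshold passed to [dichotomize()]
#' @param sd_type passed to [tr_scores()]
#' @return list with `scores` (TR table incl. `flagged`), `patients` (the
#'   cohort's patient table with `tr` and `flagged`), `threshold_used`,
#'   `rule`
#' @export
score_cohort <- function(cohort, rule = c("empirical_quintile", "fixed_threshold"),
                         threshold = 1.2, sd_type = c("sample", "population")) {
  rule <- match.arg(rule)
  sd_type <- match.arg(sd_type)
  scores <- tr_scores(cohort$visits, sd_type = sd_type)
  d <- dichotomize(scores$tr, rule = rule, threshold = threshold)
  scores[, flagged := d$flags]
  patients <- merge(cohort$patients, scores[, .(patient_id, tr, flagged)],
                    by = "patient_id", sort = FALSE)
  list(scores = scores[], patients = patients, threshold_used = d$threshold_used,
       rule = rule)
}
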