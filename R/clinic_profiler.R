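# Case-mix-adjusted clinic profiling: observed vs expected counts of
# least-regular patients per clinic. E is the sum of model-predicted
# probabilities, so when the model is fit by maximum likelihood with an
# intercept on the profiled cohort, total O equals total E exactly (the
# intercept score equation) and the E-weighted mean O/E is 1.

#' Per-clinic observed and expected counts
#'
#' @param clinic_id vector of clinic assignments (one per patient)
#' @param flagged logical vector: least-regular flag
#' @param probability numeric vector of model-predicted probabilities
#' @return data.table: `clinic_id`, `n_patients`, `observed`, `expected`
#' @export
clinic_counts <- function(clinic_id, flagged, probability) {
  if (length(clinic_id) != length(flagged) ||
      length(clinic_id) != length(probability)) {
    stop("clinic_id, flagged and probability must have equal length", call. = FALSE)
  }
  if (anyNA(probability)) {
    stop("every patient needs a predicted probability", call. = FALSE)
  }
  if (anyNA(flagged) || anyNA(clinic_id)) {
    stop("every patient needs a clinic and a flag", call. = FALSE)
  }
  dt <- data.table(clinic_id = clinic_id, flagged = as.logical(flagged),
                   probability = as.numeric(probability))
  out <- dt[, .(n_patients = .N, observed = sum(flagged),
                expected = sum(probability)), by = clinic_id]
  setorder(out, clinic_id)
  out[]
}

#' Clinic O/E scores with a minimum-size rule
#'
#' Clinics with fewer than `min_n` patients are excluded (estimate
#' stability); the exclusion list is returned alongside the scores.
#'
#' @param counts output of [clinic_counts()]
#' @param min_n minimum patients per profiled clinic (default 30)
#' @return list with `scores` (`clinic_id`, `n_patients`, `observed`,
#'   `expected`, `oe`) and `excluded` (the under-sized clinics)
#' @export
oe_scores <- function(counts, min_n = 30L) {
  counts <- as.data.table(counts)
  excluded <- counts[n_patients < min_n]
  scores <- counts[n_patients >= min_n]
  if (nrow(scores) && any(scores$expected <= 0)) {
    stop("degenerate expectation: an included clinic has E = 0", call. = FALSE)
  }
  scores <- copy(scores)[, oe := observed / expected]
  setorder(scores, clinic_id)
  list(scores = scores[], excluded = excluded[])
}

#' Distribution summary of clinic O/E scores
#'
#' @param scores the `scores` table from [oe_scores()]
#' @param band inclusive near-expected band (default 0.90 .. 1.10)
#' @return list: `n_clinics`, `min`, `max`, `median`, `band`, `band_n`,
#'   `band_pct`, `e_weighted_mean` (= total O / total E), and `ranked`
#'   (clinics ordered by O/E, for plotting)
#' @export
profile_summary <- function(scores, band = c(0.90, 1.10)) {
  scores <- as.data.table(scores)
  if (nrow(scores) == 0L) stop("no included clinics", call. = FALSE)
  in_band <- scores$oe >= band[1L] & scores$oe <= band[2L]
  ranked <- copy(scores)
  setorder(ranked, oe)
  ranked[, rank := .I]
  list(
    n_clinics = nrow(scores),
    min = min(scores$oe),
    max = max(scores$oe),
    median = median(scores$oe),
    band = band,
    band_n = sum(in_band),
    band_pct = 100 * mean(in_band),
    e_weighted_mean = sum(scores$observed) / sum(scores$expected),
    ranked = ranked[]
  )
}
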