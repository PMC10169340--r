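# Logistic modelling of least-regular care: bivariate and fully adjusted
# models over the standard predictor set (age band, sex, ethnic/cultural
# group, region, SES group, kidney function, smoking, chronic conditions),
# odds ratios with 95% Wald intervals, and the concordance statistic.

#' Conditions included in the default model
#' @return character vector of condition names
#' @export
default_model_conditions <- function() {
  c("atrial_fibrillation", "cancer", "chronic_lung_disease", "cad_angina",
    "cad_mi", "dementia", "diabetes", "epilepsy", "heart_failure",
    "hypertension", "ibd", "osteoporosis", "pad", "rheumatoid_arthritis",
    "stroke", "vte", "alcohol_misuse", "adhd", "anxiety", "bipolar",
    "depression", "ptsd", "schizophrenia")
}

#' Model design specification
#'
#' Describes which predictors enter the design and the reference level of
#' each categorical predictor (age 40-49, female, General population,
#' Central region, Highest SES, eGFR 60+, absence of each condition).
#'
#' @param age,sex,ethnic,region,ses,egfr,smoker logicals, include the term?
#' @param conditions character vector of condition names (columns `cond_*`
#'   must exist in the patient table)
#' @return a `design_spec` object
#' @export
design_spec <- function(age = TRUE, sex = TRUE, ethnic = TRUE, region = TRUE,
                        ses = TRUE, egfr = TRUE, smoker = TRUE,
                        conditions = default_model_conditions()) {
  factors <- list()
  if (age) factors$age <- list(column = "age_group", prefix = "age", levels = AGE_LEVELS)
  if (sex) factors$sex <- list(column = "sex", prefix = "sex", levels = SEX_LEVELS)
  if (ethnic) factors$ethnic <- list(column = "ethnic_group", prefix = "ethnic", levels = ETHNIC_LEVELS)
  if (region) factors$region <- list(column = "region", prefix = "region", levels = REGION_LEVELS)
  if (ses) factors$ses <- list(column = "ses_group", prefix = "ses", levels = SES_LEVELS)
  if (egfr) factors$egfr <- list(column = "egfr_category", prefix = "egfr", levels = EGFR_LEVELS)
  structure(list(factors = factors, conditions = conditions, smoker = smoker),
            class = "design_spec")
}

#' Column names of a design spec (non-reference indicator terms)
#' @param spec a [design_spec()]
#' @return character vector of term names, e.g. `"age:50-59"`, `"cond:diabetes"`
#' @export
design_terms <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  out <- character()
  for (f in spec$factors) {
    out <- c(out, paste0(f$prefix, ":", f$levels[-1L]))
  }
  out <- c(out, paste0("cond:", spec$conditions))
  if (spec$smoker) out <- c(out, "smoker")
  out
}

#' Encode patients into a design matrix and outcome vector
#'
#' One row per patient; an intercept column plus 0/1 indicators for every
#' non-reference level. Indicator columns that are constant in the data are
#' dropped with a warning (rank preservation).
#'
#' @param patients analytic patient table (see [build_cohort()]); needs a
#'   logical `flagged` column when an outcome is required
#' @param spec a [design_spec()]
#' @param drop_constant drop all-zero/all-one indicator columns? (default
#'   `TRUE`; the synthetic generator disables this to keep truth alignment)
#' @return list with `x` (numeric matrix, first column `(Intercept)`), `y`
#'   (0/1 outcome or `NULL` when no `flagged` column), `dropped` (names of
#'   removed columns)
#' @export
encode_design <- function(patients, spec = design_spec(), drop_constant = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  p <- as.data.frame(patients)
  n <- nrow(p)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  cols <- list("(Intercept)" = rep(1, n))
  for (f in spec$factors) {
    v <- as.character(p[[f$column]])
    bad <- setdiff(unique(v), f$levels)
    if (length(bad)) {
      stop(sprintf("unseen level(s) in %s: %s", f$column,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (lv in f$levels[-1L]) {
      cols[[paste0(f$prefix, ":", lv)]] <- as.numeric(v == lv)
    }
  }
  for (cn in spec$conditions) {
    col <- paste0("cond_", cn)
    if (!col %in% names(p)) {
      stop("missing condition column: ", col, call. = FALSE)
    }
    cols[[paste0("cond:", cn)]] <- as.numeric(p[[col]])
  }
  if (spec$smoker) cols[["smoker"]] <- as.numeric(p[["current_smoker"]])
  x <- do.call(cbind, cols)
  dropped <- character()
  if (drop_constant && ncol(x) > 1L) {
    const <- vapply(seq_len(ncol(x)), function(j) {
      j > 1L && length(unique(x[, j])) == 1L
    }, logical(1))
    if (any(const)) {
      dropped <- colnames(x)[const]
      warning("dropping constant design column(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
      x <- x[, !const, drop = FALSE]
    }
  }
  y <- if ("flagged" %in% names(p)) as.numeric(p$flagged) else NULL
  list(x = x, y = y, dropped = dropped)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit with step-halving (so the deviance never
#' increases), Wald standard errors from the observed information, 95%
#' confidence intervals at z = 1.96, and the concordance statistic of the
#' fitted probabilities. Separation is signalled (not an error): when any
#' coefficient magnitude exceeds `beta_bound` or the iteration cap is hit,
#' `converged` is `FALSE` and partial results are returned with a warning.
#'
#' @param x design matrix including an intercept column
#' @param y 0/1 outcome vector with at least one event and one non-event
#' @param max_iter iteration cap (default 100)
#' @param tol convergence tolerance on the relative deviance change
#' @param beta_bound separation bound on |coefficient| (default 15)
#' @return an object of class `tr_logit`: coefficients, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `converged`, `n_obs`, `c_statistic`,
#'   `fitted`, `deviance_trace`
#' @export
fit_logistic <- function(x, y, max_iter = 100L, tol = 1e-10, beta_bound = 15) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("outcome needs at least one event and one non-event", call. = FALSE)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, ncol(x))
  names(beta) <- colnames(x)
  # deviance via a numerically safe log(1 + exp(eta))
  log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(eta)))
  dev <- function(b) {
    eta <- drop(x %*% b)
    -2 * sum(y * eta - log1pexp(eta))
  }
  d_old <- dev(beta)
  trace <- d_old
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(x, x * w)
    xtwz <- crossprod(x, w * z)
    beta_new <- drop(solve(xtwx, xtwz))
    # step-halving guarantees a non-increasing deviance trace
    step <- beta_new - beta
    d_new <- dev(beta_new)
    halvings <- 0L
    while (d_new > d_old + 1e-12 && halvings < 30L) {
      step <- step / 2
      beta_new <- beta + step
      d_new <- dev(beta_new)
      halvings <- halvings + 1L
    }
    beta <- beta_new
    trace <- c(trace, d_new)
    if (abs(d_old - d_new) < tol * (abs(d_new) + 0.1)) {
      converged <- TRUE
      d_old <- d_new
      break
    }
    d_old <- d_new
  }
  separated <- any(abs(beta) > beta_bound)
  if (separated || !converged) {
    converged <- FALSE
    warning("logistic fit did not converge cleanly",
            if (separated) " (possible separation: coefficient bound exceeded)" else "",
            "; partial results returned", call. = FALSE)
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  cov_beta <- solve(crossprod(x, x * w))
  se <- sqrt(diag(cov_beta))
  names(se) <- colnames(x)
  z_val <- beta / se
  p <- 2 * pnorm(-abs(z_val))
  structure(
    list(
      coefficients = beta,
      se = se,
      or = exp(beta),
      ci_low = exp(beta - 1.96 * se),
      ci_high = exp(beta + 1.96 * se),
      p = p,
      converged = converged,
      n_obs = nrow(x),
      c_statistic = concordance(mu, y),
      fitted = mu,
      deviance = d_old,
      deviance_trace = trace,
      terms = colnames(x)
    ),
    class = "tr_logit"
  )
}

#' Odds-ratio table of a fitted model
#'
#' @param fit a `tr_logit` object
#' @param include_intercept include the intercept row? (default `FALSE`)
#' @return data.table with `term`, `coefficient`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `marker` (`"*"` for p < 0.05, a dagger for p < 0.001)
#' @export
or_table <- function(fit, include_intercept = FALSE) {
  stopifnot(inherits(fit, "tr_logit"))
  dt <- data.table(
    term = fit$terms, coefficient = unname(fit$coefficients),
    se = unname(fit$se), or = unname(fit$or),
    ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
    p = unname(fit$p)
  )
  if (!include_intercept) dt <- dt[term != "(Intercept)"]
  dt[, marker := significance_marker(p)]
  dt[]
}

significance_marker <- function(p) {
  ifelse(p < 0.001, "†", ifelse(p < 0.05, "*", ""))
}

#' @export
print.tr_logit <- function(x, ...) {
  cat(sprintf("<tr_logit> n = %d, converged = %s, c-statistic = %.3f\n",
              x$n_obs, x$converged, x$c_statistic))
  tab <- or_table(x)
  tab[, or := sprintf("%.2f%s", or, marker)]
  tab[, ci := sprintf("%.2f, %.2f", ci_low, ci_high)]
  print(tab[, .(term, or, ci)], nrows = 100L)
  invisible(x)
}

#' Predicted probability of the flagged outcome
#'
#' @param object a fitted `tr_logit`
#' @param newdata design matrix whose columns cover the fit's terms (an
#'   `(Intercept)` column is added when absent)
#' @param allow_unconverged predict from a non-converged fit? (default
#'   `FALSE`)
#' @param ... unused
#' @return vector of probabilities in (0, 1)
#' @export
predict.tr_logit <- function(object, newdata, allow_unconverged = FALSE, ...) {
  if (!object$converged && !allow_unconverged) {
    stop("model did not converge; set allow_unconverged = TRUE to override",
         call. = FALSE)
  }
  x <- as.matrix(newdata)
  if (!"(Intercept)" %in% colnames(x)) {
    x <- cbind("(Intercept)" = 1, x)
  }
  miss <- setdiff(object$terms, colnames(x))
  if (length(miss)) {
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  plogis(drop(x[, object$terms, drop = FALSE] %*% object$coefficients))
}

#' Fully adjusted model of least-regular care
#'
#' Encodes the design and fits the multivariable logistic model; attaches
#' per-patient predicted probabilities (used downstream as expected counts
#' in clinic profiling).
#'
#' @param patients analytic patient table with a logical `flagged` column
#' @param spec a [design_spec()]
#' @param ... passed to [fit_logistic()]
#' @return list with `fit` (a `tr_logit`) and `probabilities` (named by
#'   `patient_id`)
#' @export
adjusted_model <- function(patients, spec = design_spec(), ...) {
  enc <- encode_design(patients, spec)
  if (is.null(enc$y)) stop("patients table has no 'flagged' column", call. = FALSE)
  fit <- fit_logistic(enc$x, enc$y, ...)
  probs <- fit$fitted
  names(probs) <- as.character(patients$patient_id)
  list(fit = fit, probabilities = probs)
}

#' Bivariate (single-predictor) models
#'
#' One logistic model per predictor (all levels of that predictor plus an
#' intercept), mirroring an unadjusted odds-ratio column. A predictor whose
#' fit fails is reported with `NA` estimates rather than aborting the rest.
#'
#' @param patients analytic patient table with `flagged`
#' @param spec a [design_spec()] naming the predictors
#' @param ... passed to [fit_logistic()]
#' @return data.table with one row per non-reference level
#' @export
bivariate_table <- function(patients, spec = design_spec(), ...) {
  stopifnot(inherits(spec, "design_spec"))
  single_specs <- list()
  for (nm in names(spec$factors)) {
    s <- design_spec(age = FALSE, sex = FALSE, ethnic = FALSE, region = FALSE,
                     ses = FALSE, egfr = FALSE, smoker = FALSE,
                     conditions = character())
    s$factors <- spec$factors[nm]
    single_specs[[nm]] <- s
  }
  for (cn in spec$conditions) {
    single_specs[[paste0("cond_", cn)]] <-
      design_spec(age = FALSE, sex = FALSE, ethnic = FALSE, region = FALSE,
                  ses = FALSE, egfr = FALSE, smoker = FALSE, conditions = cn)
  }
  if (spec$smoker) {
    single_specs$smoker <-
      design_spec(age = FALSE, sex = FALSE, ethnic = FALSE, region = FALSE,
                  ses = FALSE, egfr = FALSE, smoker = TRUE,
                  conditions = character())
  }
  rows <- lapply(names(single_specs), function(nm) {
    s <- single_specs[[nm]]
    tryCatch({
      enc <- encode_design(patients, s)
      fit <- fit_logistic(enc$x, enc$y, ...)
      tab <- or_table(fit)
      tab[, predictor := nm]
      tab
    }, error = function(e) {
      message(sprintf("bivariate model for '%s' failed: %s", nm, conditionMessage(e)))
      data.table(term = design_terms(s), coefficient = NA_real_, se = NA_real_,
                 or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, marker = "", predictor = nm)
    })
  })
  rbindlist(rows, use.names = TRUE)
}

#' Concordance statistic (c-statistic / AUC)
#'
#' Probability that a randomly chosen event-patient receives a higher
#' predicted probability than a randomly chosen non-event patient, ties
#' counting one half; computed by the rank method in O(n log n).
#'
#' @param predicted numeric vector of scores/probabilities
#' @param outcome 0/1 vector of the same length with both classes present
#' @return scalar in [0, 1]
#' @export
concordance <- function(predicted, outcome) {
  predicted <- as.numeric(predicted)
  outcome <- as.numeric(outcome)
  stopifnot(length(predicted) == length(outcome), all(outcome %in% c(0, 1)))
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop("degenerate outcome: both classes are required", call. = FALSE)
  }
  r <- rank(predicted) # average ranks make ties count 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
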