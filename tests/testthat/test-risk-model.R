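test_that("intercept-only fit recovers the logit of the event rate", {
  y <- rep(c(1, 0, 0, 0, 0), 40) # prevalence exactly 0.20
  x <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), qlogis(0.2), tolerance = 1e-8)
  # score equation: fitted probabilities sum to the event count
  expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-8)
})

test_that("a saturated binary predictor reproduces the 2x2 cross-product OR", {
  # exposed: 30 events / 70 non-events; unexposed: 10 / 90
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  e <- c(rep(1, 100), rep(0, 100))
  x <- cbind("(Intercept)" = 1, exposed = e)
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$or["exposed"]), (30 * 90) / (70 * 10),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["exposed"]), log(30 * 90 / (70 * 10)),
               tolerance = 1e-8)
  expect_true(fit$ci_low["exposed"] <= fit$or["exposed"])
  expect_true(fit$ci_high["exposed"] >= fit$or["exposed"])
})

test_that("IRLS agrees with the glm oracle on coefficients and Wald SEs", {
  set.seed(404)
  n <- 600
  x <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, 0.3),
             c = runif(n))
  eta <- -1 + 0.8 * x[, "a"] - 0.5 * x[, "b"] + 0.3 * x[, "c"]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(x, y)
  oracle <- glm(y ~ a + b + c, data = as.data.frame(x[, -1]),
                family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-4)
  expect_equal(fit$deviance, deviance(oracle), tolerance = 1e-8)
})

test_that("the deviance trace is non-increasing across IRLS iterations", {
  set.seed(11)
  x <- cbind("(Intercept)" = 1, z = rnorm(300))
  y <- rbinom(300, 1, plogis(2 * x[, "z"]))
  fit <- fit_logistic(x, y)
  expect_true(all(diff(fit$deviance_trace) <= 1e-10))
})

test_that("separation is signalled without aborting", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- cbind("(Intercept)" = 1, s = c(rep(0, 20), rep(1, 20)))
  expect_warning(fit <- fit_logistic(x, y), "separation|converge")
  expect_false(fit$converged)
  expect_error(predict(fit, x), "converge")
  expect_length(predict(fit, x, allow_unconverged = TRUE), 40)
})

test_that("degenerate designs raise informative errors", {
  x <- cbind("(Intercept)" = 1, a = c(0, 1, 0, 1), a2 = c(0, 2, 0, 2))
  expect_error(fit_logistic(x, c(0, 1, 1, 0)), "collinear")
  expect_error(fit_logistic(cbind(1, 0:3), rep(1, 4)), "one event and one non-event")
})

test_that("design encoding uses reference levels and flags unseen categories", {
  pts <- data.frame(
    patient_id = c("A", "B"),
    age_group = c("40-49", "70-79"), sex = c("Female", "Male"),
    ethnic_group = c("General", "Arab"), region = c("Central", "South"),
    ses_group = c("Highest", "Lower"), egfr_category = c("60+", "<30"),
    current_smoker = c(FALSE, TRUE), cond_diabetes = c(FALSE, TRUE),
    flagged = c(FALSE, TRUE)
  )
  spec <- design_spec(conditions = "diabetes")
  enc <- encode_design(pts, spec, drop_constant = FALSE)
  # pure reference patient: all indicators zero
  expect_equal(unname(enc$x[1, -1]), rep(0, ncol(enc$x) - 1))
  expect_equal(unname(enc$x[2, "sex:Male"]), 1)
  expect_equal(unname(enc$x[2, "age:70-79"]), 1)
  expect_equal(unname(enc$x[2, "cond:diabetes"]), 1)
  expect_equal(enc$y, c(0, 1))
  expect_identical(colnames(enc$x)[-1], design_terms(spec))
  pts_bad <- pts
  pts_bad$region[1] <- "Atlantis"
  expect_error(encode_design(pts_bad, spec), "unseen level.*Atlantis")
  # constant indicator columns are dropped with a warning
  pts3 <- rbind(pts, pts)
  pts3$age_group <- "40-49"
  expect_warning(enc3 <- encode_design(pts3, spec), "constant design column")
  expect_false(any(grepl("^age:", colnames(enc3$x))))
})

test_that("concordance matches examples and the all-pairs oracle", {
  expect_equal(concordance(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(concordance(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(concordance(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(909)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n), 2) # rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(concordance(p, y), brute_force_concordance(p, y))
  }
  expect_error(concordance(c(0.1, 0.2), c(1, 1)), "degenerate")
})

test_that("predictions respect the fitted model and average to the event rate", {
  set.seed(21)
  n <- 500
  x <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.7 * x[, "a"]))
  fit <- fit_logistic(x, y)
  expect_equal(mean(predict(fit, x)), mean(y), tolerance = 1e-8)
  ref <- matrix(c(1, 0, 0), 1, dimnames = list(NULL, colnames(x)))
  expect_equal(unname(predict(fit, ref)),
               plogis(unname(fit$coefficients["(Intercept)"])))
  expect_error(predict(fit, x[, 1:2]), "missing feature")
})

test_that("bivariate models isolate single predictors", {
  set.seed(55)
  cfg <- quick_config(n_patients = 1500L)
  sc <- score_cohort(build_cohort(generate_cohort(cfg)))
  spec <- design_spec(conditions = c("diabetes", "osteoporosis"))
  tab <- bivariate_table(sc$patients, spec)
  expect_setequal(tab$term, design_terms(spec))
  # a null predictor on shuffled outcome stays near OR 1
  pts <- sc$patients
  pts$flagged <- sample(pts$flagged)
  tab0 <- bivariate_table(pts, design_spec(
    age = FALSE, sex = TRUE, ethnic = FALSE, region = FALSE, ses = FALSE,
    egfr = FALSE, smoker = FALSE, conditions = character()))
  expect_lt(abs(log(tab0$or)), 0.5)
})
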