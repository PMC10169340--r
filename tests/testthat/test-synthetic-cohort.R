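test_that("generation is byte-identical under a fixed config and seed", {
  cfg <- quick_config()
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
  b3 <- generate_cohort(quick_config(seed = 100L))
  expect_false(identical(b1$visits, b3$visits))
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_patients = 0), "positive integer")
  expect_error(generator_config(study_window = as.Date(c("2019-01-01", "2018-01-01"))),
               "after")
  expect_error(generator_config(prevalences = c(diabetes = 1.2)), "probabilit")
  expect_error(generator_config(baseline_flag_rate = 0), "strictly inside")
  expect_error(generator_config(clinic_effect_sd = -1), "nonnegative")
  expect_error(generator_config(true_log_odds = c(bogus_term = 0.5)),
               "not design terms")
  expect_error(generator_config(ineligible_fractions = c(under_40 = 0.1)),
               "ineligible_fractions")
})

test_that("eligible-cohort condition prevalences match the configuration", {
  cfg <- generator_config(n_patients = 10000L, n_clinics = 25L, seed = 202L)
  co <- build_cohort(generate_cohort(cfg))
  n <- nrow(co$patients)
  for (cond in c("diabetes", "chronic_lung_disease", "heart_failure",
                 "hypertension", "osteoporosis", "anxiety", "cad_mi")) {
    p <- cfg$prevalences[[cond]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$patients[[paste0("cond_", cond)]]) - p), 3 * se,
              label = cond)
  }
})

test_that("a zero-COV target yields perfectly even visit series", {
  for (seed in 1:5) {
    d <- sample_visit_series(0, 6, as.Date(c("2018-01-01", "2018-12-31")),
                             seed = seed)
    expect_length(d, 6)
    expect_equal(length(unique(diff(d))), 1) # identical gaps
    expect_true(all(d >= as.Date("2018-01-01") & d <= as.Date("2018-12-31")))
  }
  expect_error(sample_visit_series(0.5, 1), "n_visits")
  expect_error(sample_visit_series(-0.2, 5), "nonnegative")
})

test_that("the gamma renewal process hits its target sample COV", {
  # closed form: gamma shape k has COV k^(-1/2); with many intervals the
  # sample COV concentrates near the target
  set.seed(606)
  w <- as.Date(c("2015-01-01", "2019-12-31"))
  covs <- replicate(500, {
    d <- sample_visit_series(1.0, 200, w)
    coefficient_of_variation(as.numeric(diff(d)))
  })
  expect_lt(abs(mean(covs) - 1.0), 0.05)
  # monotonicity in the target
  m_low <- mean(replicate(80, {
    d <- sample_visit_series(0.5, 100, w)
    coefficient_of_variation(as.numeric(diff(d)))
  }))
  m_high <- mean(replicate(80, {
    d <- sample_visit_series(1.5, 100, w)
    coefficient_of_variation(as.numeric(diff(d)))
  }))
  expect_lt(m_low, m_high)
})

test_that("the calibrated link reproduces logistic flag probabilities", {
  cfg <- quick_config()
  cal <- cov_flag_calibration(cfg)
  expect_false(is.unsorted(cal$p_flag)) # isotonic by construction
  # monotone link
  lp_grid <- seq(-2, 2, by = 0.5)
  tc <- regularity_from_linear_predictor(lp_grid, 0, cfg)
  expect_true(all(diff(tc) >= 0))
  # Monte-Carlo check at the calibration anchor (lp = 0 -> baseline rate)
  # and one log-odds unit above it
  flag_rate <- function(lp, n_rep = 4000L) {
    tc <- regularity_from_linear_predictor(lp, 0, cfg)
    nv <- temporeg:::rztpois3(n_rep, cfg$mean_visits_per_2y)
    s <- temporeg:::sim_gaps(rep(tc, n_rep), nv, 730L)
    mean(temporeg:::series_sample_cov(s) >= cfg$flag_threshold)
  }
  set.seed(313)
  p0 <- flag_rate(0)
  p1 <- flag_rate(1)
  expect_lt(abs(p0 - cfg$baseline_flag_rate), 0.025)
  expect_lt(abs(plogis(qlogis(p0) + 1) - p1), 0.035)
  # odds ratio between lp = 1 and lp = 0 is approximately e
  or_hat <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_lt(abs(log(or_hat) - 1), 0.25)
})

test_that("planned ineligibility fractions control the attrition", {
  cfg0 <- quick_config(n_patients = 600L,
                       ineligible_fractions = c(under_40 = 0, no_index_condition = 0,
                                                hemodialysis = 0, under_3_visits = 0))
  co0 <- build_cohort(generate_cohort(cfg0))
  expect_equal(nrow(co0$patients), 600L) # no filter can bite
  expect_equal(sum(co0$attrition$n_removed), 0L)
  cfg1 <- quick_config(n_patients = 800L,
                       ineligible_fractions = c(under_40 = 0.15, no_index_condition = 0,
                                                hemodialysis = 0, under_3_visits = 0))
  co1 <- build_cohort(generate_cohort(cfg1))
  removed <- co1$attrition[filter == "age_under_40", n_removed]
  expect_lt(abs(removed / 800 - 0.15), 3 * sqrt(0.15 * 0.85 / 800))
})

test_that("bundle tables are referentially consistent with ground truth", {
  b <- generate_cohort(quick_config())
  ids <- b$demographics$patient_id
  expect_false(anyDuplicated(ids) > 0)
  for (tb in c("visits", "diagnoses", "labs", "procedures")) {
    expect_true(all(b[[tb]]$patient_id %in% ids), label = tb)
  }
  expect_setequal(b$ground_truth$patient_id, ids)
  expect_setequal(unique(b$demographics$clinic_id), b$clinic_effects$clinic_id)
  # every patient has exactly one clinic assignment
  expect_equal(nrow(unique(b$demographics[, c("patient_id", "clinic_id")])),
               length(ids))
  # hemodialysis procedures only for marked patients
  hd <- b$ground_truth$patient_id[b$ground_truth$mark_hemodialysis]
  expect_setequal(unique(b$procedures$patient_id), hd)
})

test_that("builder recovers the generator's planned eligibility and flags", {
  cfg <- quick_config(n_patients = 1200L)
  b <- generate_cohort(cfg)
  co <- build_cohort(b)
  gt <- b$ground_truth
  expect_setequal(co$patients$patient_id, gt$patient_id[gt$planned_eligible])
  # condition flags recovered exactly from the emitted codes
  m <- merge(co$patients, gt, by = "patient_id")
  for (cond in c("diabetes", "heart_failure", "anxiety")) {
    truth <- b$demographics$patient_id %in%
      b$diagnoses$patient_id[matches_code_list(b$diagnoses$code,
                                               default_code_lists()[[cond]]) &
                               b$diagnoses$code_system ==
                               default_code_lists()[[cond]]$code_system]
    names(truth) <- b$demographics$patient_id
    expect_equal(unname(truth[m$patient_id]), m[[paste0("cond_", cond)]],
                 label = cond)
  }
})
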