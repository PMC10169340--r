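test_that("inter-visit intervals are whole-day differences with guards", {
  expect_equal(
    inter_visit_intervals(as.Date(c("2018-01-01", "2018-03-02", "2018-05-01"))),
    c(60L, 60L))
  six <- as.Date("2018-01-01") + 60 * (0:5)
  expect_equal(inter_visit_intervals(six), rep(60L, 5))
  expect_error(inter_visit_intervals(six[1:2]), "at least three")
  expect_error(inter_visit_intervals(rev(six)), "sorted")
  expect_error(inter_visit_intervals(six[c(1, 1, 2)]), "duplicate")
})

test_that("COV matches the hand formula and is scale invariant", {
  expect_identical(coefficient_of_variation(rep(60, 5)), 0)
  expect_equal(coefficient_of_variation(c(30, 60, 90)), 0.5) # sample SD 30 / mean 60
  expect_equal(coefficient_of_variation(c(30, 60, 90), "population"),
               sqrt(2 / 3) * 30 / 60)
  set.seed(31)
  for (i in 1:20) {
    x <- runif(sample(2:12, 1), 1, 200)
    c_scale <- runif(1, 0.1, 50)
    expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
    expect_equal(coefficient_of_variation(c_scale * x),
                 coefficient_of_variation(x))
  }
  expect_error(coefficient_of_variation(60), "at least two")
  expect_error(coefficient_of_variation(c(10, -5, 20)), "positive")
})

test_that("COV is zero iff constant and grows under perturbation", {
  base <- rep(45, 6)
  expect_identical(coefficient_of_variation(base), 0)
  for (delta in c(1, 5, 20)) {
    pert <- base
    pert[3] <- pert[3] + delta
    expect_gt(coefficient_of_variation(pert), 0)
  }
  expect_gt(coefficient_of_variation(c(45, 45, 65, 45)),
            coefficient_of_variation(c(45, 45, 55, 45)))
})

test_that("tr_scores aggregates per patient and enforces the visit minimum", {
  vd <- data.frame(
    patient_id = c(rep("A", 4), rep("B", 3)),
    date = c(as.Date("2018-01-01") + c(0, 30, 60, 120),
             as.Date("2018-02-01") + c(0, 50, 100))
  )
  s <- tr_scores(vd)
  expect_equal(s[patient_id == "A", tr],
               coefficient_of_variation(c(30, 30, 60)))
  expect_equal(s[patient_id == "B", tr], 0)
  expect_equal(s$n_visits, c(4L, 3L))
  expect_error(tr_scores(vd[c(1, 2, 5:7), ]), "at least three")
})

test_that("Jarque-Bera matches its closed-form chi-square tail and moments", {
  set.seed(77)
  x <- rnorm(1000)
  r <- jarque_bera(x)
  # independent oracle: chi-square(2) survival function is exp(-x/2)
  expect_equal(r$p_value, exp(-r$jb_statistic / 2), tolerance = 1e-12)
  # independent moment computation
  S <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  K <- mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  expect_equal(r$jb_statistic, length(x) / 6 * (S^2 + (K - 3)^2 / 4))
  expect_gt(r$p_value, 0.01) # normal draws should not be rejected wildly
  # location/scale invariance
  r2 <- jarque_bera(5 + 3 * x)
  expect_equal(r2$jb_statistic, r$jb_statistic, tolerance = 1e-8)
  # clearly non-normal data are rejected
  y <- rexp(1000)
  expect_lt(jarque_bera(y)$p_value, 0.001)
  expect_lt(jarque_bera(y, transform = "log")$p_value, 0.001)
  # Q-Q pairs are ordered and standardized
  expect_equal(nrow(r$qq), 1000)
  expect_false(is.unsorted(r$qq$empirical))
  expect_error(jarque_bera(rep(1, 20)), "zero variance")
  expect_error(jarque_bera(rnorm(5)), "at least 8")
})

test_that("dichotomization follows the inclusive threshold rule", {
  d <- dichotomize(c(1.19, 1.20, 1.21), rule = "fixed_threshold", threshold = 1.2)
  expect_equal(d$flags, c(FALSE, TRUE, TRUE))
  expect_equal(d$threshold_used, 1.2)
  # 100 distinct values -> exactly 20 in the least-regular quintile
  set.seed(5)
  v <- sort(runif(100))
  q <- dichotomize(v, rule = "empirical_quintile")
  expect_equal(sum(q$flags), 20L)
  expect_equal(q$threshold_used, unname(quantile(v, 0.8)))
  # ties exactly at the computed threshold are all flagged
  vt <- c(rep(1, 80), rep(2, 25))
  qt <- dichotomize(vt, rule = "empirical_quintile")
  expect_true(all(qt$flags[vt >= qt$threshold_used]))
  expect_error(dichotomize(rep(1, 10), rule = "empirical_quintile"),
               "degenerate")
})

test_that("quintile flagging stays near 20% for continuous TR", {
  set.seed(123)
  for (n in c(500, 2000)) {
    v <- rgamma(n, 3)
    q <- dichotomize(v, rule = "empirical_quintile")
    expect_lte(abs(sum(q$flags) - ceiling(0.2 * n)), 1)
  }
})
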