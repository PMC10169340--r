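test_that("qualify_visits applies duration, provider, window and same-day rules", {
  w <- as.Date(c("2018-01-01", "2019-12-31"))
  v <- data.frame(
    provider_role = c("family_physician", "family_physician",
                      "family_physician", "other", "family_physician",
                      "family_physician", "family_physician"),
    date = as.Date(c("2018-02-01", "2018-03-01", "2018-03-01", "2018-04-01",
                     "2017-12-31", "2018-05-01", "2018-06-01")),
    duration_minutes = c(5.0, 10, 10, 30, 10, 4.9, 8)
  )
  q <- qualify_visits(v, w)
  # 5.0 kept, 4.9 dropped, other-provider dropped, pre-window dropped,
  # same-day pair collapses to one date
  expect_equal(q, as.Date(c("2018-02-01", "2018-03-01", "2018-06-01")))
  expect_length(qualify_visits(v[0, ], w), 0)
})

test_that("eGFR categorization uses the lowest value with fallback then imputation", {
  lab <- function(egfr, date) data.frame(egfr = egfr, date = as.Date(date))
  expect_equal(categorize_egfr(lab(52, "2018-06-01")), "45-59")
  expect_equal(categorize_egfr(lab(c(72, 41), c("2018-01-01", "2019-06-01"))),
               "30-44") # lowest wins
  expect_equal(categorize_egfr(lab(29.5, "2016-03-01")), "<30") # fallback years
  # a 2018-2019 value beats any 2016-2017 value
  expect_equal(categorize_egfr(lab(c(25, 80), c("2016-03-01", "2019-06-01"))),
               "60+")
  expect_equal(categorize_egfr(NULL), "60+") # mode imputation
  expect_error(categorize_egfr(lab(-5, "2018-01-01")), "negative")
})

test_that("build_cohort applies every eligibility filter and logs attrition", {
  co <- build_cohort(tiny_bundle())
  expect_setequal(co$patients$patient_id, c("P1", "P6"))
  expect_equal(co$attrition$filter,
               c("age_under_40", "no_index_condition",
                 "fewer_than_min_visits", "hemodialysis"))
  expect_equal(co$attrition$n_removed, c(1L, 1L, 1L, 1L))
  expect_equal(co$attrition$n_after[4], 2L)
  # P1: diabetes flag from a 250.x code, eGFR 45-59, five visits
  p1 <- co$patients[patient_id == "P1"]
  expect_true(p1$cond_diabetes)
  expect_equal(p1$egfr_category, "45-59")
  expect_equal(p1$n_visits, 5L)
  expect_equal(p1$age_group, "60-69")
  expect_equal(p1$ses_group, "Highest")
  # P6: heart failure + depression, lowest eGFR 41 -> 30-44, noise ignored
  p6 <- co$patients[patient_id == "P6"]
  expect_true(p6$cond_heart_failure)
  expect_true(p6$cond_depression)
  expect_equal(p6$egfr_category, "30-44")
  expect_equal(p6$n_visits, 4L)
})

test_that("the retained set is filter-order invariant", {
  b <- tiny_bundle()
  co <- build_cohort(b)
  # brute-force: evaluate each eligibility predicate independently
  demo <- b$demographics
  keep <- vapply(demo$patient_id, function(pid) {
    age_ok <- (2015 - demo$birth_year[demo$patient_id == pid]) >= 40
    dx <- b$diagnoses[b$diagnoses$patient_id == pid, ]
    idx_ok <- any(vapply(
      default_code_lists()[c("heart_failure", "chronic_lung_disease", "diabetes")],
      function(cl) flag_condition(dx, cl), logical(1)))
    visits_ok <- length(qualify_visits(b$visits[b$visits$patient_id == pid, ])) >= 3
    hd_ok <- !pid %in% b$procedures$patient_id
    age_ok && idx_ok && visits_ok && hd_ok
  }, logical(1))
  expect_setequal(co$patients$patient_id, demo$patient_id[keep])
})

test_that("data errors are raised for broken extracts", {
  b <- tiny_bundle()
  b$demographics <- rbind(b$demographics, b$demographics[1, ])
  expect_error(build_cohort(b), "duplicate patient_id")
  b2 <- tiny_bundle()
  b2$visits$patient_id[1] <- "P99"
  expect_error(build_cohort(b2), "unknown patient_id")
})

test_that("extract tables round-trip through delimited text", {
  b <- generate_cohort(quick_config())
  dir <- file.path(tempfile("extract"))
  write_extract(b, dir)
  b2 <- read_extract(dir)
  for (tb in c("demographics", "visits", "diagnoses", "labs", "procedures")) {
    expect_equal(as.data.frame(b[[tb]]), as.data.frame(b2[[tb]]),
                 label = tb, ignore_attr = TRUE)
  }
  expect_equal(b2$config$seed, b$config$seed)
  # builds identically from disk
  expect_equal(build_cohort(b)$patients, build_cohort(b2)$patients)
  unlink(dir, recursive = TRUE)
})
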