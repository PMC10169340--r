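# End-to-end orchestration: simulate -> build -> score -> model -> profile
# -> report, as one reproducible run with a manifest (seed, parameters, row
# counts, output checksums).

PIPELINE_STAGES <- c("simulate", "build", "score", "model", "profile", "report")

#' Pipeline run configuration
#'
#' @param out_dir output directory for all stage artifacts
#' @param seed master seed; overrides the generator config's seed so one
#'   number controls the whole run
#' @param generator a [generator_config()] used by the simulate stage
#' @param input_dir extract directory used by `build` when `simulate` is
#'   disabled
#' @param stages subset of `simulate, build, score, model, profile, report`
#' @param rule,threshold dichotomization rule (see [dichotomize()])
#' @param sd_type COV standard-deviation convention (see
#'   [coefficient_of_variation()])
#' @param min_n minimum clinic size for profiling
#' @return a `run_config` object
#' @export
run_config <- function(out_dir, seed = 1L,
                       generator = generator_config(),
                       input_dir = NULL,
                       stages = PIPELINE_STAGES,
                       rule = "empirical_quintile", threshold = 1.2,
                       sd_type = "sample", min_n = 30L) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (!rule %in% c("empirical_quintile", "fixed_threshold")) {
    stop("unknown dichotomization rule: ", rule, call. = FALSE)
  }
  if (!sd_type %in% c("sample", "population")) {
    stop("unknown sd_type: ", sd_type, call. = FALSE)
  }
  if (min_n < 1L) stop("min_n must be at least 1", call. = FALSE)
  generator$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, input_dir = input_dir,
                 stages = stages, rule = rule, threshold = threshold,
                 sd_type = sd_type, min_n = as.integer(min_n)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writes every stage artifact under
#' `config$out_dir`, and returns (and writes) a run manifest with the seed,
#' resolved parameters, per-stage row counts and MD5 checksums of all
#' outputs. Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()]
#' @return list with `manifest` and the in-memory stage `results`, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  counts <- list()
  completed <- character()

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      results$bundle <- generate_cohort(config$generator)
      write_extract(results$bundle, file.path(config$out_dir, "extract"))
      counts$simulate <- c(patients = nrow(results$bundle$demographics),
                           visits = nrow(results$bundle$visits))
      completed <- c(completed, "simulate")
    })
  }

  if ("build" %in% config$stages) {
    run_stage("build", {
      if (is.null(results$bundle)) {
        if (is.null(config$input_dir) ||
            !file.exists(file.path(config$input_dir, "demographics.csv"))) {
          stop("no extract available: expected tables under '",
               config$input_dir %||% "<unset input_dir>", "'")
        }
        results$bundle <- read_extract(config$input_dir)
      }
      results$cohort <- build_cohort(results$bundle)
      fwrite(results$cohort$patients, file.path(config$out_dir, "cohort.csv"))
      fwrite(results$cohort$visits, file.path(config$out_dir, "qualifying_visits.csv"))
      fwrite(results$cohort$attrition, file.path(config$out_dir, "attrition.csv"))
      counts$build <- c(retained = nrow(results$cohort$patients))
      completed <- c(completed, "build")
    })
  }

  if ("score" %in% config$stages) {
    run_stage("score", {
      if (is.null(results$cohort)) stop("no cohort: enable the build stage")
      results$scored <- score_cohort(results$cohort, rule = config$rule,
                                     threshold = config$threshold,
                                     sd_type = config$sd_type)
      fwrite(results$scored$scores, file.path(config$out_dir, "tr_scores.csv"))
      results$normality <- list(
        raw = jarque_bera(results$scored$scores$tr, "TR"),
        log = jarque_bera(results$scored$scores$tr[results$scored$scores$tr > 0],
                          "TR", transform = "log")
      )
      norm_txt <- lapply(results$normality, function(r) {
        r[c("variable_name", "n", "skewness", "kurtosis", "jb_statistic",
            "p_value", "transform")]
      })
      yaml::write_yaml(norm_txt, file.path(config$out_dir, "normality.yaml"))
      fwrite(results$normality$raw$qq, file.path(config$out_dir, "qq_pairs.csv"))
      counts$score <- c(scored = nrow(results$scored$scores),
                        flagged = sum(results$scored$scores$flagged))
      completed <- c(completed, "score")
    })
  }

  if ("model" %in% config$stages) {
    run_stage("model", {
      if (is.null(results$scored)) stop("no TR scores: enable the score stage")
      results$model <- adjusted_model(results$scored$patients)
      results$bivariate <- bivariate_table(results$scored$patients)
      fwrite(or_table(results$model$fit), file.path(config$out_dir, "adjusted_model.csv"))
      fwrite(results$bivariate, file.path(config$out_dir, "bivariate_models.csv"))
      fwrite(data.table(patient_id = names(results$model$probabilities),
                        probability = unname(results$model$probabilities)),
             file.path(config$out_dir, "predicted_probabilities.csv"))
      counts$model <- c(terms = length(results$model$fit$coefficients),
                        c_statistic = round(results$model$fit$c_statistic, 4))
      completed <- c(completed, "model")
    })
  }

  if ("profile" %in% config$stages) {
    run_stage("profile", {
      if (is.null(results$model)) stop("no fitted model: enable the model stage")
      pts <- results$scored$patients
      cc <- clinic_counts(pts$clinic_id, pts$flagged,
                          results$model$probabilities[as.character(pts$patient_id)])
      results$oe <- oe_scores(cc, min_n = config$min_n)
      fwrite(results$oe$scores, file.path(config$out_dir, "clinic_scores.csv"))
      fwrite(results$oe$excluded, file.path(config$out_dir, "clinics_excluded.csv"))
      if (nrow(results$oe$scores)) {
        results$profile <- profile_summary(results$oe$scores)
        fwrite(results$profile$ranked, file.path(config$out_dir, "oe_ranked.csv"))
      }
      counts$profile <- c(included = nrow(results$oe$scores),
                          excluded = nrow(results$oe$excluded))
      completed <- c(completed, "profile")
    })
  }

  if ("report" %in% config$stages) {
    run_stage("report", {
      report <- render_report(results)
      writeLines(report, file.path(config$out_dir, "report.md"))
      completed <- c(completed, "report")
    })
  }

  files <- sort(list.files(config$out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.yaml"]
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", config$out_dir, "/?"), "", names(checksums))
  manifest <- list(
    package_version = as.character(packageVersion("temporeg")),
    seed = config$seed,
    parameters = list(rule = config$rule, threshold = config$threshold,
                      sd_type = config$sd_type, min_n = config$min_n,
                      n_patients = config$generator$n_patients,
                      n_clinics = config$generator$n_clinics),
    stages_completed = completed,
    row_counts = lapply(counts, as.list),
    checksums = as.list(checksums)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, results = results))
}

fmt_or_row <- function(tab) {
  sprintf("| %s | %.2f%s | %.2f, %.2f |", tab$term, tab$or, tab$marker,
          tab$ci_low, tab$ci_high)
}

#' Render the run report
#'
#' One markdown document with the cohort characteristics table, the TR
#' distribution and normality summary, the bivariate and adjusted
#' odds-ratio tables (significance markers: `*` p < 0.05, dagger
#' p < 0.001), and the clinic O/E summary with ordered plot data.
#'
#' @param results the `results` list from [run_pipeline()]
#' @return character vector of markdown lines
#' @export
render_report <- function(results) {
  out <- c("# Temporal regularity of primary care: run report", "")

  out <- c(out, "## Cohort characteristics", "")
  if (!is.null(results$cohort)) {
    pts <- results$cohort$patients
    out <- c(out, sprintf("Patients retained: %d", nrow(pts)), "",
             "| Variable | Level | n | % |", "|---|---|---|---|")
    for (v in c("age_group", "sex", "ethnic_group", "region", "ses_group",
                "egfr_category")) {
      tb <- sort(table(pts[[v]]), decreasing = TRUE)
      out <- c(out, sprintf("| %s | %s | %d | %.1f |", v, names(tb),
                            as.integer(tb), 100 * as.integer(tb) / nrow(pts)))
    }
    cond_cols <- grep("^cond_", names(pts), value = TRUE)
    for (cc in cond_cols) {
      n1 <- sum(pts[[cc]])
      out <- c(out, sprintf("| condition | %s | %d | %.1f |",
                            sub("^cond_", "", cc), n1, 100 * n1 / nrow(pts)))
    }
    out <- c(out, "", "Attrition:", "",
             knit_simple_table(results$cohort$attrition))
  } else {
    out <- c(out, "_No cohort built._")
  }

  out <- c(out, "", "## Temporal regularity", "")
  if (!is.null(results$scored)) {
    tr <- results$scored$scores$tr
    out <- c(out, sprintf(
      "TR over %d patients: min %.2f, median %.2f, mean %.2f, SD %.2f, max %.2f.",
      length(tr), min(tr), median(tr), mean(tr), sd(tr), max(tr)),
      sprintf("Least-regular rule: %s, threshold %.4f, flagged %d (%.1f%%).",
              results$scored$rule, results$scored$threshold_used,
              sum(results$scored$scores$flagged),
              100 * mean(results$scored$scores$flagged)))
    if (!is.null(results$normality)) {
      for (r in results$normality) {
        out <- c(out, sprintf(
          "Jarque-Bera (%s%s): JB = %.1f, p = %.3g.", r$variable_name,
          if (r$transform == "log") ", log scale" else "",
          r$jb_statistic, r$p_value))
      }
    }
  } else {
    out <- c(out, "_No TR scores computed._")
  }

  out <- c(out, "", "## Patient-level models", "")
  if (!is.null(results$model)) {
    out <- c(out, sprintf("Adjusted model c-statistic: %.3f (n = %d).",
                          results$model$fit$c_statistic,
                          results$model$fit$n_obs), "",
             "Adjusted odds ratios (* p < 0.05, † p < 0.001):", "",
             "| Term | OR | 95% CI |", "|---|---|---|",
             fmt_or_row(or_table(results$model$fit)))
    if (!is.null(results$bivariate)) {
      out <- c(out, "", "Bivariate (unadjusted) odds ratios:", "",
               "| Term | OR | 95% CI |", "|---|---|---|",
               fmt_or_row(results$bivariate))
    }
  } else {
    out <- c(out, "_No models fitted._")
  }

  out <- c(out, "", "## Clinic profiling", "")
  if (!is.null(results$oe) && nrow(results$oe$scores) > 0L) {
    s <- results$profile
    out <- c(out, sprintf(
      "%d clinics profiled (%d excluded below the size threshold).",
      s$n_clinics, nrow(results$oe$excluded)),
      sprintf("O/E range %.2f-%.2f, median %.2f; %d clinics (%.0f%%) within %.2f-%.2f.",
              s$min, s$max, s$median, s$band_n, s$band_pct, s$band[1], s$band[2]),
      sprintf("E-weighted mean O/E: %.6f.", s$e_weighted_mean),
      "", "Ordered O/E scores (plot data):", "",
      knit_simple_table(s$ranked[, .(rank, clinic_id, n_patients, observed,
                                     expected = round(expected, 2),
                                     oe = round(oe, 3))]))
  } else if (!is.null(results$oe)) {
    out <- c(out, "No clinics included: none met the minimum size rule.")
  } else {
    out <- c(out, "_No profiling performed._")
  }
  out
}

knit_simple_table <- function(dt) {
  dt <- as.data.frame(dt)
  header <- paste0("| ", paste(names(dt), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(dt)), collapse = "|"), "|")
  rows <- apply(dt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
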