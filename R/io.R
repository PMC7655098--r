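# File schemas and pipeline orchestration: validated CSV readers/writers and
# a single entry point running score -> outcomes -> fits -> averaging -> LOO
# with a JSON run report. Missing values are encoded as empty CSV cells.

#' Read a trial-level CSV
#'
#' One row per trial with the columns `subject_id`, `event_id`,
#' `first_estimate`, `base_rate`, `second_estimate`, `recalled_rate`,
#' `rt_first`, `rt_second`, `familiarity`, `prior_experience`, `vividness`,
#' `arousal`, `negativity`; missing responses are empty cells. Rows violating
#' the task's ranges (base rates within \[10, 70\], estimates within
#' \[3, 77\], integer likert ratings in 1-6) fail validation with the row and
#' field named.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) ub_validation_error(paste("no such file:", path))
  trials <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    ub_validation_error(paste("trials file is missing columns:",
                              paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trials) == 0L) {
    ub_validation_error(paste("trials file has no rows:", path))
  }
  check_field <- function(col, lo, hi, integer_only = FALSE) {
    x <- trials[[col]]
    bad <- !is.na(x) & (x < lo | x > hi |
                          (integer_only & x != round(x)))
    if (any(bad)) {
      ub_validation_error(sprintf(
        "invalid %s at row(s) %s: values must lie in [%s, %s]%s",
        col, paste(utils::head(which(bad), 5L), collapse = ", "),
        format(lo), format(hi), if (integer_only) " (integers)" else ""))
    }
  }
  check_field("base_rate", 10, 70)
  check_field("first_estimate", 3, 77)
  check_field("second_estimate", 3, 77)
  for (v in RATING_VARS) check_field(v, 1, 6, integer_only = TRUE)
  for (v in c("rt_first", "rt_second")) {
    x <- trials[[v]]
    if (any(!is.na(x) & x < 0)) {
      ub_validation_error(paste("negative reaction times in column", v))
    }
  }
  trials
}

#' Read a subject-level CSV
#'
#' Requires a `subject_id` column; all other columns (relapse month,
#' next-episode label, demographics, medication flags, questionnaires) are
#' passed through as-is.
#'
#' @param path Path to the CSV file.
#' @return Data frame of subjects.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) ub_validation_error(paste("no such file:", path))
  subjects <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"subject_id" %in% names(subjects)) {
    ub_validation_error("cohort file must have a subject_id column")
  }
  if (nrow(subjects) == 0L) {
    ub_validation_error(paste("cohort file has no rows:", path))
  }
  if (anyDuplicated(subjects$subject_id)) {
    ub_validation_error("duplicated subject_id values in cohort file")
  }
  subjects
}

#' Write a table as CSV with empty cells for missing values
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full prognostic pipeline
#'
#' Executes, in order: trial classification and subject scoring, outcome
#' construction (when the subject table still lacks outcome columns), model
#' fits with optional bootstrap intervals, all-subsets BIC averaging, and
#' the leave-one-out ablation comparison. Subjects excluded at any stage are
#' logged in the report, and any stage failure aborts with the stage named.
#'
#' @param trials Trial-level data frame (or path to a trials CSV).
#' @param subjects Subject-level data frame (or path to a cohort CSV).
#' @param models Character vector of model names to fit.
#' @param n_boot Bootstrap replicates per model (0 to skip).
#' @param averaging Model name to average over all predictor subsets, or
#'   `NULL` to skip.
#' @param loo_ablate Predictor whose removal is tested by leave-one-out
#'   comparison (applied to the first fitted model), or `NULL` to skip.
#' @param out_dir Optional directory for stage outputs (`scores.csv`,
#'   `cohort.csv`, `report.json`).
#' @param seed Integer seed recorded in the report and used for every
#'   stochastic stage.
#' @param horizon Censoring horizon in months.
#' @return Run report (list), invisibly written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is given.
#' @export
run_pipeline <- function(trials, subjects, models = "model1", n_boot = 0,
                         averaging = NULL, loo_ablate = NULL, out_dir = NULL,
                         seed = 1, horizon = 60) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.character(trials)) trials <- stage("read_trials", read_trials(trials))
  if (is.character(subjects)) subjects <- stage("read_cohort", read_cohort(subjects))

  classified <- stage("classify", classify_trials(trials))
  warnings_log <- character(0)
  scores <- stage("score", withCallingHandlers(
    score_subjects(classified),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))

  if (!"log_months" %in% names(subjects)) {
    subjects <- stage("outcomes", build_outcomes(subjects, horizon = horizon))
  }
  cohort <- stage("merge", merge(scores, subjects, by = "subject_id"))

  fits <- stage("fit", lapply(models, function(m) {
    fit <- fit_linear_model(m, cohort)
    boot <- if (n_boot > 0) {
      bootstrap_ci(m, cohort, n_boot = n_boot, seed = seed)
    }
    list(fit = fit, bootstrap = boot)
  }))
  names(fits) <- models

  avg <- if (!is.null(averaging)) {
    stage("averaging", model_average(averaging, cohort))
  }
  loo <- if (!is.null(loo_ablate)) {
    stage("loo", compare_models_loo(
      build_model_spec(models[[1]]),
      drop_predictor(models[[1]], loo_ablate), cohort))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("updatebias")),
    seed = seed,
    n_trials = nrow(trials),
    n_subjects_scored = nrow(scores),
    unscorable_subjects = attr(scores, "unscorable"),
    exclusion_warnings = warnings_log,
    models = lapply(fits, function(f) {
      list(name = f$fit$spec$name, n_used = f$fit$n_used,
           r_squared = f$fit$r_squared, sse = f$fit$sse, bic = f$fit$bic,
           coefficients = f$fit$coefficients,
           beta_std = as.list(f$fit$beta_std),
           vif = as.list(f$fit$vif),
           bootstrap_ci = if (!is.null(f$bootstrap)) {
             list(raw = f$bootstrap$ci_raw, standardized = f$bootstrap$ci_std)
           })
    }),
    averaging = if (!is.null(avg)) {
      list(n_models = avg$fits$n_models, table = avg$averaging$table,
           top_k = as.list(avg$top_k))
    },
    loo = if (!is.null(loo)) {
      list(sse_with = loo$with$sse, sse_without = loo$without$sse,
           r_with = loo$with$r, r_without = loo$without$r, n = loo$n)
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(scores, file.path(out_dir, "scores.csv"))
    write_table_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(report)
}
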