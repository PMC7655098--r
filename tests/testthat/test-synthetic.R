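test_that("configuration invariants are enforced before generation", {
  expect_error(synthetic_config(n_events = 2), class = "ub_validation_error")
  expect_error(synthetic_config(base_rate_range = c(70, 10)),
               class = "ub_validation_error")
  expect_error(synthetic_config(update_noise_sd = -1),
               class = "ub_validation_error")
  expect_error(synthetic_config(estimate_bounds = c(20, 60)),
               class = "ub_validation_error")
})

test_that("noiseless integer-mean updating is recovered exactly", {
  # interior base rates and integer per-valence means keep rounding and
  # clipping inert, so the scored bias equals the configured truth exactly
  cfg <- synthetic_config(n_subjects = 10, base_rate_range = c(30, 50),
                          first_estimate_sd_between = 0,
                          first_estimate_sd_within = 5,
                          base_update = 10, bias_mean = 6, bias_sd = 0,
                          update_noise_sd = 0, missing_rate_mean = 0,
                          missing_rate_sd = 0, seed = 61)
  task <- generate_task_data(cfg)
  scores <- score_subjects(classify_trials(task$trials))
  expect_equal(scores$update_bias, rep(6, 10))
  expect_equal(scores$mean_update_good, rep(13, 10))
  expect_equal(scores$mean_update_bad, rep(7, 10))
})

test_that("without missing responses every trial is scorable or excluded", {
  cfg <- synthetic_config(n_subjects = 15, missing_rate_mean = 0,
                          missing_rate_sd = 0, seed = 62)
  scores <- score_subjects(classify_trials(generate_task_data(cfg)$trials))
  expect_true(all(scores$n_missing == 0))
  expect_true(all(scores$n_good + scores$n_bad + scores$n_excluded == 40))
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- synthetic_config(n_subjects = 12, seed = 63)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truth, c2$truth)
})

test_that("scored bias tracks the configured truth within the CLT bound", {
  cfg <- synthetic_config(n_subjects = 200, seed = 64)
  task <- generate_task_data(cfg)
  scores <- suppressWarnings(score_subjects(classify_trials(task$trials)))
  m <- merge(scores, task$truth, by = "subject_id")
  err <- m$update_bias - m$true_bias
  # measurement sd of a per-subject bias: noise * sqrt(1/n_good + 1/n_bad);
  # allow 30% margin for integer rounding and boundary clipping
  pred_sd <- cfg$update_noise_sd * sqrt(mean(1 / m$n_good.x + 1 / m$n_bad.x))
  expect_lt(mean(abs(err)), 1.3 * sqrt(2 / pi) * pred_sd)
  expect_gt(cor(m$update_bias, m$true_bias), 0.8)
})

test_that("generated data reproduce the study's qualitative signatures", {
  cfg <- synthetic_config(n_subjects = 80, seed = 65)
  cohort <- generate_cohort(cfg)
  cls <- classify_trials(cohort$trials)
  # good-news trials are rated more vivid (and so on) by construction
  for (v in c("vividness", "arousal", "familiarity")) {
    res <- compare_good_bad(cls, v)
    expect_gt(res$t, 0)
    expect_lt(res$p.value, 0.05)
  }
  # reaction times carry no valence effect
  expect_gt(compare_good_bad(cls, "rt_first")$p.value, 0.01)
  # right-skewed months, censoring present but minority
  expect_gt(distribution_diagnostics(cohort$subjects$months_euthymia)$skewness, 0.5)
  frac_cens <- mean(cohort$subjects$censored)
  expect_gt(frac_cens, 0.02)
  expect_lt(frac_cens, 0.5)
})

test_that("a null update-bias effect is estimated near zero", {
  hits <- vapply(1:30, function(s) {
    cfg <- synthetic_config(n_subjects = 36, b1_bias = 0, seed = 600 + s)
    tab <- suppressWarnings(assemble_cohort(generate_cohort(cfg)))
    fit <- fit_linear_model("model1", tab)
    row <- fit$coefficients[fit$coefficients$term == "update_bias", ]
    abs(row$estimate) < 2 * row$se
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("stronger bias effects increase the censoring rate monotonically", {
  cfg <- synthetic_config(n_subjects = 300, b1_bias = 0.12, seed = 66)
  cohort <- generate_cohort(cfg)
  m <- merge(cohort$subjects, cohort$truth, by = "subject_id")
  m <- m[is.finite(m$realized_bias), ]   # drop subjects lacking a valence
  tert <- cut(m$realized_bias, quantile(m$realized_bias, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  cens_by_tert <- tapply(m$censored, tert, mean)
  expect_gt(cens_by_tert[3], cens_by_tert[1])
})

test_that("doubling outcome noise increases recovery RMSE", {
  cfg_lo <- synthetic_config(n_subjects = 120, outcome_noise_sd = 0.5)
  cfg_hi <- synthetic_config(n_subjects = 120, outcome_noise_sd = 1.0)
  r_lo <- parameter_recovery_report(cfg_lo, n_reps = 20, seed = 70, n_boot = 0)
  r_hi <- parameter_recovery_report(cfg_hi, n_reps = 20, seed = 70, n_boot = 0)
  expect_gt(r_hi$rmse, r_lo$rmse)
})

test_that("generated trials round-trip through the CSV reader unchanged", {
  cfg <- synthetic_config(n_subjects = 8, seed = 67)
  trials <- generate_task_data(cfg)$trials
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_table_csv(trials, path)
  back <- read_trials(path)
  expect_equal(back, trials)
})
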