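test_that("trial valence follows the good/bad/excluded rule", {
  expect_identical(classify_trial(25, 10), "good")
  expect_identical(classify_trial(10, 25), "bad")
  expect_identical(classify_trial(40, 40), "excluded")
  expect_identical(classify_trial(NA, 30), "excluded")
  expect_identical(classify_trial(c(25, 40, NA), c(10, 40, 30)),
                   c("good", "excluded", "excluded"))
})

test_that("out-of-range inputs fail validation naming the field", {
  expect_error(classify_trial(25, 5), "base_rate", class = "ub_validation_error")
  expect_error(classify_trial(90, 30), "first_estimate", class = "ub_validation_error")
})

test_that("updates are signed toward the presented information", {
  expect_equal(compute_update(40, 30, "good"), 10)
  expect_equal(compute_update(20, 35, "bad"), 15)
  expect_equal(compute_update(40, 45, "good"), -5)
  expect_equal(compute_update(40, 35, "bad"), -5)
  expect_error(compute_update(40, 40, "excluded"), class = "ub_logic_error")
})

test_that("memory error is a symmetric absolute difference that propagates NA", {
  expect_equal(compute_memory_error(30, 42), 12)
  expect_equal(compute_memory_error(42, 30), 12)
  expect_equal(compute_memory_error(50, 50), 0)
  expect_true(is.na(compute_memory_error(30, NA)))
})

test_that("subject scores implement the update-bias and delta arithmetic", {
  scores <- score_subjects(classify_trials(toy_trials()))
  expect_equal(nrow(scores), 1L)
  expect_equal(scores$n_good, 2L)
  expect_equal(scores$n_bad, 2L)
  expect_equal(scores$n_excluded, 1L)
  expect_equal(scores$n_missing, 1L)
  expect_equal(scores$mean_update_good, 15)
  expect_equal(scores$mean_update_bad, 5)
  expect_equal(scores$update_bias, 10)
  expect_equal(scores$delta_n_trials, 0L)
  expect_equal(scores$mean_first_estimate, mean(c(40, 50, 20, 30, 40)))
  # good trials have estimation errors |10-40|=30, |20-50|=30; bad 20, 20
  expect_equal(scores$delta_estimation_error, 30 - 20)
  expect_equal(scores$delta_vividness, mean(c(4, 5)) - mean(c(3, 3)))
})

test_that("update_bias always equals mean_update_good - mean_update_bad", {
  cfg <- synthetic_config(n_subjects = 25, seed = 5)
  scores <- suppressWarnings(score_subjects(classify_trials(generate_task_data(cfg)$trials)))
  expect_equal(scores$update_bias,
               scores$mean_update_good - scores$mean_update_bad)
})

test_that("scores match the generator's independent bookkeeping exactly", {
  cfg <- synthetic_config(n_subjects = 30, seed = 7)
  task <- generate_task_data(cfg)
  scores <- suppressWarnings(score_subjects(classify_trials(task$trials)))
  m <- merge(scores, task$truth, by = "subject_id")
  expect_equal(m$mean_update_good, m$realized_mean_update_good)
  expect_equal(m$mean_update_bad, m$realized_mean_update_bad)
  expect_equal(m$update_bias, m$realized_bias)
  expect_equal(m$n_good.x, m$n_good.y)
  expect_equal(m$n_bad.x, m$n_bad.y)
})

test_that("classification conserves trial counts per subject", {
  cfg <- synthetic_config(n_subjects = 20, seed = 13)
  scores <- suppressWarnings(score_subjects(classify_trials(generate_task_data(cfg)$trials)))
  expect_true(all(scores$n_good + scores$n_bad + scores$n_excluded +
                    scores$n_missing == cfg$n_events))
})

test_that("mirroring the task data swaps valences and negates bias and deltas", {
  # reflecting estimates and base rates around 40 maps [3,77] and [10,70]
  # onto themselves and turns every good-news trial into a bad-news one
  cfg <- synthetic_config(n_subjects = 12, seed = 3, missing_rate_mean = 0,
                          missing_rate_sd = 0)
  trials <- generate_task_data(cfg)$trials
  mirrored <- trials
  for (col in c("first_estimate", "base_rate", "second_estimate",
                "recalled_rate")) {
    mirrored[[col]] <- 80 - mirrored[[col]]
  }
  s1 <- score_subjects(classify_trials(trials))
  s2 <- score_subjects(classify_trials(mirrored))
  expect_equal(s2$update_bias, -s1$update_bias)
  expect_equal(s2$n_good, s1$n_bad)
  expect_equal(s2$delta_n_trials, -s1$delta_n_trials)
  for (d in c("delta_memory_error", "delta_familiarity", "delta_vividness",
              "delta_arousal", "delta_negativity", "delta_rt_first")) {
    expect_equal(s2[[d]], -s1[[d]], tolerance = 1e-12)
  }
})

test_that("subjects lacking a valence are flagged unscorable and dropped", {
  trials <- toy_trials()
  trials$base_rate <- pmin(trials$first_estimate - 1, 70)
  trials$base_rate[is.na(trials$base_rate)] <- 30
  expect_warning(scores <- score_subjects(classify_trials(trials)), "unscorable|cannot be scored")
  expect_equal(nrow(scores), 0L)
  expect_equal(attr(scores, "unscorable"), "S1")
})

test_that("paired good-vs-bad comparison matches the textbook formula", {
  # five hand-written per-subject (good, bad) vividness means
  g <- c(4.2, 3.9, 4.8, 3.5, 4.0)
  b <- c(3.6, 4.1, 4.0, 3.2, 3.3)
  trials <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(subject_id = paste0("S", i), event_id = c("E1", "E2"),
               first_estimate = c(50, 20), base_rate = c(20, 50),
               second_estimate = c(40, 30), recalled_rate = c(20, 50),
               rt_first = 1, rt_second = 1, familiarity = 3L,
               prior_experience = 2L, vividness = c(g[i], b[i]),
               arousal = 3L, negativity = 4L, stringsAsFactors = FALSE)
  }))
  res <- compare_good_bad(classify_trials(trials), "vividness")
  d <- g - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), df = 4), tolerance = 1e-12)
  # equivalence with a one-sample t on the difference vector
  one_sample <- t.test(d)
  expect_equal(res$t, unname(one_sample$statistic))
  expect_equal(res$p.value, one_sample$p.value)
})

test_that("balanced differences give t = 0 and zero variance is degenerate", {
  make_trials <- function(viv_good, viv_bad) {
    do.call(rbind, lapply(seq_along(viv_good), function(i) {
      data.frame(subject_id = paste0("S", i), event_id = c("E1", "E2"),
                 first_estimate = c(50, 20), base_rate = c(20, 50),
                 second_estimate = c(40, 30), recalled_rate = c(20, 50),
                 rt_first = 1, rt_second = 1, familiarity = 3L,
                 prior_experience = 2L, vividness = c(viv_good[i], viv_bad[i]),
                 arousal = 3L, negativity = 4L, stringsAsFactors = FALSE)
    }))
  }
  balanced <- compare_good_bad(
    classify_trials(make_trials(c(1, 2, 3, 4), c(2, 1, 4, 3))), "vividness")
  expect_equal(balanced$t, 0)
  expect_error(
    compare_good_bad(classify_trials(make_trials(c(3, 3, 3), c(3, 3, 3))),
                     "vividness"),
    class = "ub_degenerate_error")
})

test_that("signed estimation errors are available behind the flag", {
  cls <- classify_trials(toy_trials())
  abs_scores <- score_subjects(cls, estimation_error = "absolute")
  sgn_scores <- score_subjects(cls, estimation_error = "signed")
  # signed errors are negative on good trials, positive on bad by definition
  expect_equal(sgn_scores$delta_estimation_error, -30 - 20)
  expect_equal(abs_scores$delta_estimation_error, 10)
})
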