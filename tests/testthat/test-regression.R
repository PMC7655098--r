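test_that("named model specifications carry the documented predictor sets", {
  m1 <- build_model_spec("model1")
  expect_length(m1$predictors, 12)
  expect_equal(m1$predictors[1], "update_bias")
  m1a <- build_model_spec("model1a")
  expect_equal(setdiff(m1$predictors, m1a$predictors), "update_bias")
  expect_equal(setdiff(m1a$predictors, m1$predictors), "mean_update_good")
  m2 <- build_model_spec("model2")
  expect_length(m2$predictors, 23)
  expect_true(all(m1$predictors %in% m2$predictors))
  pol <- build_model_spec("model1_polarity")
  expect_equal(pol$subset, "relapsers")
  expect_equal(pol$interactions, list(c("update_bias", "next_polarity")))
  expect_error(build_model_spec("model99"), "model1.*model2",
               class = "ub_validation_error")
})

test_that("an exact linear relationship is fit exactly", {
  dat <- data.frame(subject_id = paste0("S", 1:10),
                    x = 1:10, log_months = 2 * (1:10) + 1)
  fit <- suppressWarnings(fit_linear_model(new_model_spec("line", "x"), dat))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
})

test_that("OLS coefficients agree with the normal-equations oracle", {
  inst <- random_instance(n = 8, p = 3, seed = 77)
  fit <- fit_linear_model(inst$spec, inst$dat)
  oracle <- drop(solve(t(inst$X) %*% inst$X) %*% t(inst$X) %*% inst$y)
  expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-10)
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  cohort <- small_cohort(seed = 31)
  fit1 <- fit_linear_model("model1", cohort)
  cohort$update_bias <- cohort$update_bias * 1000
  fit2 <- fit_linear_model("model1", cohort)
  expect_equal(fit1$beta_std, fit2$beta_std, tolerance = 1e-9)
  expect_equal(fit2$coefficients$estimate[2],
               fit1$coefficients$estimate[2] / 1000, tolerance = 1e-12)
})

test_that("SSE never increases when a predictor is added", {
  cohort <- small_cohort(seed = 32)
  specs <- lapply(1:12, function(k) {
    new_model_spec(paste0("m", k), build_model_spec("model1")$predictors[1:k])
  })
  sses <- vapply(specs, function(s) fit_linear_model(s, cohort)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-10))
})

test_that("VIF is 1 for orthogonal predictors and infinite under duplication", {
  dat <- data.frame(subject_id = paste0("S", 1:8),
                    x1 = rep(c(1, 1, -1, -1), 2), x2 = rep(c(1, -1, 1, -1), 2),
                    log_months = rnorm(8))
  v <- model_vif(new_model_spec("orth", c("x1", "x2")), dat)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)
  dat$x3 <- dat$x1
  w <- capture_warnings(
    v2 <- model_vif(new_model_spec("dup", c("x1", "x2", "x3")), dat))
  expect_true(all(grepl("collinear", w)))
  expect_length(w, 2)  # x1 and its duplicate x3
  expect_true(is.infinite(v2[["x1"]]))
  expect_error(fit_linear_model(new_model_spec("dup", c("x1", "x2", "x3")), dat),
               "collinear", class = "ub_validation_error")
})

test_that("VIFs match the car package on a full model", {
  cohort <- small_cohort(seed = 33)
  fit <- fit_linear_model("model1", cohort)
  expect_equal(fit$vif[names(car::vif(fit$lm))], car::vif(fit$lm),
               tolerance = 1e-8)
  expect_lt(fit$vif[["update_bias"]], 4)  # no collinearity at the usual cut
})

test_that("bootstrap intervals are deterministic given a seed and collapse on exact fits", {
  dat <- data.frame(subject_id = paste0("S", 1:12),
                    x = rnorm(12), stringsAsFactors = FALSE)
  dat$log_months <- 1 + 2 * dat$x
  spec <- new_model_spec("line", "x")
  ci <- bootstrap_ci(spec, dat, n_boot = 200, seed = 4)
  expect_equal(unname(ci$ci_raw["x", ]), c(2, 2), tolerance = 1e-9)
  cohort <- small_cohort(seed = 34)
  b1 <- bootstrap_ci("model1", cohort, n_boot = 150, seed = 99)
  b2 <- bootstrap_ci("model1", cohort, n_boot = 150, seed = 99)
  expect_identical(b1$ci_raw, b2$ci_raw)
  expect_identical(b1$ci_std, b2$ci_std)
  expect_error(bootstrap_ci("model1", cohort, n_boot = 50),
               class = "ub_validation_error")
})

test_that("BCa intervals are produced behind the flag", {
  cohort <- small_cohort(seed = 35)
  spec <- new_model_spec("uni", "update_bias")
  ci <- bootstrap_ci(spec, cohort, n_boot = 400, seed = 5, type = "bca")
  expect_true(ci$ci_raw["update_bias", "low"] < ci$ci_raw["update_bias", "high"])
})

test_that("the Fisher-z power calculation reproduces the design sample size", {
  expect_equal(required_sample_size_correlation(0.5, 0.05, 0.80, tails = 1), 23L)
  # two-tailed needs more subjects; agree with the exact-power iteration
  n2_fisher <- required_sample_size_correlation(0.5, 0.05, 0.80, tails = 2)
  n2_exact <- required_sample_size_correlation(0.5, 0.05, 0.80, tails = 2,
                                               method = "exact")
  expect_gt(n2_fisher, 23)
  expect_lte(abs(n2_fisher - n2_exact), 1)
  # near-perfect correlations approach the formula floor
  expect_lte(required_sample_size_correlation(0.999, 0.05, 0.80), 4L)
  expect_error(required_sample_size_correlation(1), class = "ub_validation_error")
  expect_error(required_sample_size_correlation(0.5, alpha = 0),
               class = "ub_validation_error")
})

test_that("exact correlation power matches a Monte Carlo simulation", {
  set.seed(8)
  n <- 20; rho <- 0.5; B <- 4000
  z1 <- matrix(rnorm(n * B), n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * matrix(rnorm(n * B), n)
  r <- vapply(seq_len(B), function(b) cor(z1[, b], z2[, b]), numeric(1))
  tc <- qt(0.95, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  expect_equal(power_correlation_exact(n, rho, 0.05, tails = 1),
               mean(r > rc), tolerance = 0.03)
})

test_that("the polarity model runs on relapsers only", {
  cohort <- small_cohort(seed = 36)
  fit <- fit_linear_model("model1_polarity", cohort)
  expect_equal(fit$n_used, sum(!cohort$censored))
  expect_true("update_bias:next_polarity" %in% fit$coefficients$term)
})
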