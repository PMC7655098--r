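# The prognostic linear-model family: named model specifications, OLS fits
# with standardized coefficients, VIF collinearity diagnostics, case-resampling
# bootstrap intervals, and the design-stage power calculation.

TASK_CONTROLS <- c(
  "mean_first_estimate", "delta_estimation_error", "delta_memory_error",
  "delta_n_trials", "delta_rt_first", "delta_rt_second", "delta_familiarity",
  "delta_prior_experience", "delta_vividness", "delta_arousal",
  "delta_negativity"
)

CLINICAL_CONTROLS <- c(
  "age", "education", "gender", "bipolar_type", "bdi", "mood_stabilizers",
  "antidepressants", "antipsychotics", "lithium", "psychotic_history",
  "illness_duration"
)

MODEL_NAMES <- c("model1", "model1a", "model1b", "model1_both",
                 "model1_polarity", "model_subjective", "model2",
                 "model2_lotr", "model2_past_episodes")

#' Build one of the named prognostic model specifications
#'
#' The model family predicts log future time in euthymia. `model1` regresses
#' it on the update bias plus eleven task controls (mean first estimate and
#' the good-minus-bad deltas of estimation error, memory error, trial counts,
#' both reaction times and the five subjective ratings). `model1a` / `model1b`
#' replace the update bias with the mean update from good / bad news, and
#' `model1_both` enters both updates. `model1_polarity` adds next-episode
#' polarity and its interaction with the update bias, restricted to subjects
#' who relapsed (censored subjects have no next episode). `model_subjective`
#' keeps only the five rating deltas as controls. `model2` adds eleven
#' clinical/demographic controls to `model1`; `model2_lotr` and
#' `model2_past_episodes` extend it with trait optimism (LOT-R) and the
#' number of past episodes respectively.
#'
#' @param name One of `model1`, `model1a`, `model1b`, `model1_both`,
#'   `model1_polarity`, `model_subjective`, `model2`, `model2_lotr`,
#'   `model2_past_episodes`.
#' @return An object of class `ub_model_spec`: a list with `name`, `outcome`,
#'   `predictors`, `interactions` (list of character pairs) and `subset`
#'   (`NULL` or `"relapsers"`).
#' @export
build_model_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% MODEL_NAMES) {
    ub_validation_error(paste0("unknown model name '", name, "'; valid names: ",
                               paste(MODEL_NAMES, collapse = ", ")))
  }
  predictors <- switch(name,
    model1 = c("update_bias", TASK_CONTROLS),
    model1a = c("mean_update_good", TASK_CONTROLS),
    model1b = c("mean_update_bad", TASK_CONTROLS),
    model1_both = c("mean_update_good", "mean_update_bad", TASK_CONTROLS),
    model1_polarity = c("update_bias", TASK_CONTROLS, "next_polarity"),
    model_subjective = c("update_bias", "delta_familiarity",
                         "delta_prior_experience", "delta_vividness",
                         "delta_arousal", "delta_negativity"),
    model2 = c("update_bias", TASK_CONTROLS, CLINICAL_CONTROLS),
    model2_lotr = c("update_bias", TASK_CONTROLS, CLINICAL_CONTROLS, "lot_r"),
    model2_past_episodes = c("update_bias", TASK_CONTROLS, CLINICAL_CONTROLS,
                             "past_episodes")
  )
  new_model_spec(
    name = name,
    predictors = predictors,
    interactions = if (name == "model1_polarity") {
      list(c("update_bias", "next_polarity"))
    } else {
      list()
    },
    subset = if (name == "model1_polarity") "relapsers" else NULL
  )
}

#' Construct a custom model specification
#'
#' @param name Identifier for the model.
#' @param predictors Character vector of predictor column names (unique).
#' @param interactions List of length-2 character vectors; each pair must
#'   reference declared predictors.
#' @param subset `NULL`, or `"relapsers"` to drop censored subjects.
#' @param outcome Outcome column name (default `"log_months"`).
#' @return An `ub_model_spec` object.
#' @export
new_model_spec <- function(name, predictors, interactions = list(),
                           subset = NULL, outcome = "log_months") {
  if (anyDuplicated(predictors)) {
    ub_validation_error("predictor names must be unique")
  }
  for (pair in interactions) {
    if (length(pair) != 2L || !all(pair %in% predictors)) {
      ub_validation_error("interaction terms must be pairs of declared predictors")
    }
  }
  if (!is.null(subset) && !identical(subset, "relapsers")) {
    ub_validation_error("subset must be NULL or 'relapsers'")
  }
  structure(list(name = name, outcome = outcome, predictors = predictors,
                 interactions = interactions, subset = subset),
            class = "ub_model_spec")
}

spec_formula <- function(spec) {
  terms <- c(spec$predictors,
             vapply(spec$interactions, paste, character(1), collapse = ":"))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste(spec$outcome, "~", rhs), env = baseenv())
}

# Resolve the rows and design matrix a spec uses on a cohort table:
# subset rule, then complete cases over all referenced variables.
model_frame <- function(spec, cohort) {
  vars <- c(spec$outcome, spec$predictors)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols)) {
    ub_validation_error(paste("cohort table is missing model variables:",
                              paste(missing_cols, collapse = ", ")))
  }
  if (identical(spec$subset, "relapsers")) {
    if (!"censored" %in% names(cohort)) {
      ub_validation_error("relapsers-only model needs a 'censored' column")
    }
    cohort <- cohort[!cohort$censored, , drop = FALSE]
  }
  cc <- complete.cases(cohort[, vars, drop = FALSE])
  data <- cohort[cc, , drop = FALSE]
  X <- model.matrix(spec_formula(spec), data)
  list(data = data, X = X, y = data[[spec$outcome]],
       subject_id = if ("subject_id" %in% names(data)) data$subject_id else rownames(data))
}

# BIC on the SSE scale: n log(SSE/n) + k log(n), with k counting the
# regression coefficients plus the error variance. Additive constants are
# shared by all models on the same rows and cancel in BIC differences.
bic_from_sse <- function(sse, n, n_coef) {
  n * log(sse / n) + (n_coef + 1) * log(n)
}

# VIFs of the non-intercept columns of a design matrix: 1/(1 - R^2_j) from
# regressing each column on the others. Perfect collinearity yields Inf with
# a warning.
design_vif <- function(X) {
  cols <- setdiff(colnames(X), "(Intercept)")
  if (length(cols) < 2L) {
    return(setNames(rep(1, length(cols)), cols))
  }
  vapply(cols, function(j) {
    xj <- X[, j]
    Xo <- X[, setdiff(colnames(X), j), drop = FALSE]
    fit <- stats::lm.fit(Xo, xj)
    r2 <- 1 - sum(fit$residuals^2) / sum((xj - mean(xj))^2)
    if (r2 >= 1 - 1e-12) {
      warning(sprintf("predictor '%s' is perfectly collinear; VIF infinite", j),
              call. = FALSE)
      return(Inf)
    }
    1 / (1 - r2)
  }, numeric(1))
}

#' Variance inflation factors of a model's predictors
#'
#' VIF of predictor j is \eqn{1/(1 - R^2_j)}, where \eqn{R^2_j} comes from
#' regressing that predictor on all the others; 1 means the predictor is
#' orthogonal to the rest. Values below 4 are conventionally read as showing
#' no concerning collinearity. Perfectly collinear predictors yield `Inf`
#' with a warning. A model with a single predictor has VIF 1 by convention.
#'
#' @param spec Model specification or name.
#' @param cohort Subject-level data frame.
#' @return Named numeric vector of VIFs, one per design column.
#' @export
model_vif <- function(spec, cohort) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  design_vif(model_frame(spec, cohort)$X)
}

#' Fit a prognostic linear model
#'
#' Ordinary least squares with intercept on the complete cases of the
#' specification's variables. Alongside the raw coefficient table, the fit
#' reports standardized coefficients (the slopes after z-scoring the outcome
#' and every design column, the "Beta" convention of SPSS-family software),
#' VIFs for every predictor, SSE, R-squared and BIC.
#'
#' @param spec An `ub_model_spec`, or a model name accepted by
#'   [build_model_spec()].
#' @param cohort Subject-level data frame holding the outcome and predictor
#'   columns (scores merged with outcomes/covariates).
#' @return Object of class `ub_fit`: list with `spec`, `n_used`,
#'   `coefficients` (term/estimate/se/t/p data frame), `beta_std`, `vif`,
#'   `sse`, `r_squared`, `bic`, `sigma` and the underlying `lm` object.
#' @export
fit_linear_model <- function(spec, cohort) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  mf <- model_frame(spec, cohort)
  n <- nrow(mf$X)
  p <- ncol(mf$X)
  if (n <= p) {
    ub_validation_error(sprintf(
      "insufficient complete cases (n = %d) for %d coefficients in model '%s'",
      n, p, spec$name))
  }
  fit <- lm(spec_formula(spec), data = mf$data)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    ub_validation_error(paste("rank-deficient design; collinear terms:",
                              paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefficients <- data.frame(term = rownames(ct), estimate = ct[, 1],
                             se = ct[, 2], t = ct[, 3], p = ct[, 4],
                             row.names = NULL, stringsAsFactors = FALSE)
  sdy <- sd(mf$y)
  sdx <- apply(mf$X[, -1, drop = FALSE], 2, sd)
  beta_std <- coef(fit)[-1] * sdx / sdy
  sse <- sum(resid(fit)^2)
  structure(list(
    spec = spec,
    n_used = n,
    coefficients = coefficients,
    beta_std = beta_std,
    vif = design_vif(mf$X),
    sse = sse,
    r_squared = sm$r.squared,
    bic = bic_from_sse(sse, n, p),
    sigma = sm$sigma,
    lm = fit
  ), class = "ub_fit")
}

#' @export
print.ub_fit <- function(x, ...) {
  cat(sprintf("Linear model '%s' on %d subjects (R^2 = %.3f, SSE = %.3f)\n",
              x$spec$name, x$n_used, x$r_squared, x$sse))
  tab <- x$coefficients
  tab$beta <- c(NA, unname(x$beta_std))
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Case-resampling bootstrap intervals for a linear model
#'
#' Resamples subjects (rows) with replacement, refits the model on each
#' replicate, and returns percentile confidence bounds for both raw and
#' standardized coefficients. Replicates with a rank-deficient design are
#' redrawn and counted. Results are reproducible given a seed.
#'
#' @param spec Model specification or name.
#' @param cohort Subject-level data frame.
#' @param n_boot Number of bootstrap replicates (default 10000, the
#'   convention of the reporting software family; at least 100).
#' @param seed Optional integer seed.
#' @param level Confidence level (default 0.95).
#' @param type `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration).
#' @return List with `estimates` (raw coefficients), `ci_raw` and `ci_std`
#'   (matrices with `low`/`high` columns), `n_redrawn`, `n_boot`, `level`,
#'   `type`.
#' @export
bootstrap_ci <- function(spec, cohort, n_boot = 10000, seed = NULL,
                         level = 0.95, type = c("percentile", "bca")) {
  type <- match.arg(type)
  if (n_boot < 100) {
    ub_validation_error("n_boot must be at least 100")
  }
  if (is.character(spec)) spec <- build_model_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  mf <- model_frame(spec, cohort)
  X <- mf$X
  y <- mf$y
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) ub_validation_error("insufficient complete cases for bootstrap")
  sdy <- sd(y)

  boot_once <- function(idx) {
    qx <- qr(X[idx, , drop = FALSE])
    if (qx$rank < p) return(NULL)
    b <- qr.coef(qx, y[idx])
    sdx <- apply(X[idx, -1, drop = FALSE], 2, sd)
    list(raw = b, std = b[-1] * sdx / sd(y[idx]))
  }

  raw <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, colnames(X)))
  std <- matrix(NA_real_, n_boot, p - 1,
                dimnames = list(NULL, colnames(X)[-1]))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      res <- boot_once(sample.int(n, n, replace = TRUE))
      if (!is.null(res)) break
      n_redrawn <- n_redrawn + 1L
    }
    raw[b, ] <- res$raw
    std[b, ] <- res$std
  }
  if (n_redrawn > 0L) {
    message(sprintf("%d rank-deficient bootstrap replicate(s) redrawn", n_redrawn))
  }

  full <- qr.coef(qr(X), y)
  sdx <- apply(X[, -1, drop = FALSE], 2, sd)
  full_std <- full[-1] * sdx / sdy

  probs <- c((1 - level) / 2, (1 + level) / 2)
  ci_of <- function(mat, theta_hat) {
    if (type == "percentile") {
      t(apply(mat, 2, quantile, probs = probs))
    } else {
      t(vapply(seq_len(ncol(mat)), function(j) {
        bca_interval(mat[, j], theta_hat[j], X, y, j, probs)
      }, numeric(2)))
    }
  }
  ci_raw <- ci_of(raw, full)
  ci_std <- ci_of(std, full_std)
  colnames(ci_raw) <- colnames(ci_std) <- c("low", "high")
  rownames(ci_raw) <- colnames(X)
  rownames(ci_std) <- colnames(X)[-1]
  list(estimates = full, estimates_std = full_std, ci_raw = ci_raw,
       ci_std = ci_std, n_redrawn = n_redrawn, n_boot = n_boot,
       level = level, type = type)
}

# BCa bounds for one coefficient: bias correction from the bootstrap
# distribution, acceleration from the jackknife. `j` indexes the raw
# coefficient used for the jackknife (standardized bounds reuse the same
# acceleration geometry, which is standard practice for smooth functionals).
bca_interval <- function(theta_star, theta_hat, X, y, j, probs) {
  prop_below <- mean(theta_star < theta_hat)
  prop_below <- min(max(prop_below, 1e-6), 1 - 1e-6)
  z0 <- qnorm(prop_below)
  n <- nrow(X)
  jk <- vapply(seq_len(n), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    if (j <= length(b)) b[j] else NA_real_
  }, numeric(1))
  d <- mean(jk, na.rm = TRUE) - jk
  a <- sum(d^3, na.rm = TRUE) / (6 * sum(d^2, na.rm = TRUE)^1.5)
  if (!is.finite(a)) a <- 0
  adj <- function(pr) {
    z <- qnorm(pr)
    pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  }
  quantile(theta_star, probs = vapply(probs, adj, numeric(1)), names = FALSE)
}

#' Required sample size for detecting a correlation
#'
#' Fisher-z approximation for the sample size needed to detect a population
#' correlation `r` at significance level `alpha` with the stated power:
#' \eqn{n = ((z_{1-\alpha/\mathrm{tails}} + z_{\mathrm{power}}) /
#' \mathrm{atanh}(|r|))^2 + 3}, rounded to the nearest integer. The default is
#' one-tailed, the convention under which a medium-large correlation of 0.50
#' at alpha 0.05 and 80% power requires 23 subjects. `method = "exact"`
#' instead iterates the sample size against the exact power of the
#' correlation t-test computed from the sampling density of the correlation
#' coefficient (see [power_correlation_exact()]).
#'
#' @param r Hypothesized population correlation, `0 < |r| < 1`.
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param tails 1 or 2.
#' @param method `"fisher_z"` (default) or `"exact"`.
#' @return Integer sample size.
#' @export
required_sample_size_correlation <- function(r, alpha = 0.05, power = 0.80,
                                             tails = 1,
                                             method = c("fisher_z", "exact")) {
  method <- match.arg(method)
  if (!is.finite(r) || abs(r) <= 0 || abs(r) >= 1) {
    ub_validation_error("r must satisfy 0 < |r| < 1")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    ub_validation_error("alpha and power must lie strictly in (0, 1)")
  }
  if (!tails %in% c(1, 2)) ub_validation_error("tails must be 1 or 2")
  if (method == "fisher_z") {
    n <- ((qnorm(1 - alpha / tails) + qnorm(power)) / atanh(abs(r)))^2 + 3
    return(as.integer(round(n)))
  }
  n <- 5L
  while (power_correlation_exact(n, abs(r), alpha, tails) < power) {
    n <- n + 1L
    if (n > 100000L) ub_logic_error("exact power iteration failed to converge")
  }
  n
}

# Gauss hypergeometric 2F1(1/2, 1/2; c; z) by its (rapidly converging for
# z < 1) power series.
hyp2f1_half <- function(c0, z) {
  term <- 1
  total <- 1
  k <- 0
  while (abs(term) > 1e-14 && k < 500) {
    term <- term * (0.5 + k)^2 / ((c0 + k) * (k + 1)) * z
    total <- total + term
    k <- k + 1
  }
  total
}

# Sampling density of the Pearson correlation coefficient of n bivariate
# normal pairs with population correlation rho (Hotelling's form).
dcorr <- function(x, n, rho) {
  lgam <- lgamma(n - 1) - lgamma(n - 0.5)
  hyp <- vapply(x, function(xx) hyp2f1_half(n - 0.5, (rho * xx + 1) / 2),
                numeric(1))
  (n - 2) * exp(lgam) * (1 - rho^2)^((n - 1) / 2) *
    (1 - x^2)^((n - 4) / 2) / (sqrt(2 * pi) * (1 - rho * x)^(n - 1.5)) * hyp
}

#' Exact power of the Pearson correlation test
#'
#' Power of the t-test for a zero correlation at sample size `n` against a
#' true correlation `r`, computed by integrating the exact sampling density
#' of the correlation coefficient beyond the critical value. Serves as the
#' independent cross-check for the Fisher-z sample-size approximation.
#'
#' @param n Sample size (at least 5).
#' @param r True population correlation, `0 < |r| < 1`.
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
power_correlation_exact <- function(n, r, alpha = 0.05, tails = 1) {
  if (n < 5) ub_validation_error("n must be at least 5")
  if (!is.finite(r) || abs(r) <= 0 || abs(r) >= 1) {
    ub_validation_error("r must satisfy 0 < |r| < 1")
  }
  tc <- qt(1 - alpha / tails, df = n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  upper <- integrate(dcorr, rc, 1, n = n, rho = abs(r),
                     rel.tol = 1e-9)$value
  if (tails == 2) {
    lower <- integrate(dcorr, -1, -rc, n = n, rho = abs(r),
                       rel.tol = 1e-9)$value
    upper + lower
  } else {
    upper
  }
}
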