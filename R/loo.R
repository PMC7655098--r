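# Leave-one-out predictive validation: each subject's log time in euthymia is
# predicted from a model fit on everyone else, and the predictions are scored
# by correlation with the observed values, a paired t-test of the means, and
# the prediction sum of squared errors.

#' Leave-one-out predictions
#'
#' For each complete-case subject, refits the model on the remaining
#' subjects and predicts the held-out subject's outcome from that fold's
#' coefficients; no subject's outcome ever informs its own prediction.
#' Censored subjects participate with their horizon value, exactly as in the
#' fitted models. Predictions are made on the log-months scale; back-
#' transformed months are included for convenience.
#'
#' @param spec Model specification or name.
#' @param cohort Subject-level data frame.
#' @return Data frame with `subject_id`, `actual`, `predicted` (both log
#'   months) and `predicted_months`.
#' @export
loo_predictions <- function(spec, cohort) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  mf <- model_frame(spec, cohort)
  X <- mf$X
  y <- mf$y
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2L) {
    ub_validation_error(sprintf(
      "leave-one-out needs more than %d complete cases for %d coefficients",
      p + 1L, p))
  }
  predicted <- vapply(seq_len(n), function(i) {
    qx <- qr(X[-i, , drop = FALSE])
    if (qx$rank < p) {
      ub_validation_error(sprintf("rank-deficient design in fold %d (subject %s)",
                                  i, mf$subject_id[i]))
    }
    sum(qr.coef(qx, y[-i]) * X[i, ])
  }, numeric(1))
  data.frame(subject_id = mf$subject_id, actual = y, predicted = predicted,
             predicted_months = exp(predicted), stringsAsFactors = FALSE)
}

#' Score predictions against observed outcomes
#'
#' Three evaluation surfaces: the Pearson correlation between predicted and
#' actual values (with its test p-value), a paired t-test comparing the two
#' means (a calibrated predictor shows no mean shift), and the prediction
#' sum of squared errors.
#'
#' @param predicted,actual Equal-length numeric vectors (log months),
#'   at least 3 values.
#' @return List with `r`, `p_r`, `t`, `df`, `p_t`, `sse` and `n`.
#' @export
validate_loo <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    ub_validation_error("predicted and actual must have equal length")
  }
  n <- length(actual)
  if (n < 3L) ub_validation_error("validation needs at least 3 subjects")
  if (sd(predicted) == 0 || sd(actual) == 0) {
    ub_degenerate_error("zero variance in predictions or outcomes; correlation undefined")
  }
  ct <- stats::cor.test(actual, predicted)
  d <- actual - predicted
  if (sd(d) == 0) {
    # constant differences: a zero mean difference is a perfectly calibrated
    # predictor (t = 0), a nonzero one an exact systematic shift
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p_t <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(actual, predicted, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_t <- tt$p.value
  }
  list(r = unname(ct$estimate), p_r = ct$p.value,
       t = t_stat, df = n - 1L, p_t = p_t,
       sse = sum((actual - predicted)^2), n = n)
}

#' Leave-one-out comparison of two nested model variants
#'
#' Runs the full leave-one-out validation for two specifications (typically
#' the model with and without the update bias) on the intersection of their
#' complete-case subjects, and reports both result tuples together with the
#' SSE and correlation differences. A smaller SSE for the variant carrying
#' the update bias indicates the bias contributes genuine predictive signal.
#'
#' @param spec_with,spec_without Model specifications or names.
#' @param cohort Subject-level data frame.
#' @return List with `with`, `without` (each a [validate_loo()] result plus
#'   predictions), `sse_diff` (`with` minus `without`) and `r_diff`.
#' @export
compare_models_loo <- function(spec_with, spec_without, cohort) {
  if (is.character(spec_with)) spec_with <- build_model_spec(spec_with)
  if (is.character(spec_without)) spec_without <- build_model_spec(spec_without)
  ids_with <- model_frame(spec_with, cohort)$subject_id
  ids_without <- model_frame(spec_without, cohort)$subject_id
  ids <- intersect(ids_with, ids_without)
  if (length(ids) < length(union(ids_with, ids_without))) {
    message(sprintf("aligning to %d subjects complete for both models", length(ids)))
  }
  sub <- cohort[cohort$subject_id %in% ids, , drop = FALSE]
  run <- function(spec) {
    preds <- loo_predictions(spec, sub)
    c(validate_loo(preds$predicted, preds$actual), list(predictions = preds))
  }
  res_with <- run(spec_with)
  res_without <- run(spec_without)
  list(with = res_with, without = res_without,
       sse_diff = res_with$sse - res_without$sse,
       r_diff = res_with$r - res_without$r,
       n = length(ids))
}

#' Drop a predictor from a model specification
#'
#' Helper for ablation comparisons: returns the specification without the
#' named predictor (and without any interaction referencing it).
#'
#' @param spec Model specification or name.
#' @param predictor Predictor to remove.
#' @return A new `ub_model_spec`.
#' @export
drop_predictor <- function(spec, predictor) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  if (!predictor %in% spec$predictors) {
    ub_validation_error(paste0("'", predictor, "' is not a predictor of model '",
                               spec$name, "'"))
  }
  keep_int <- Filter(function(pair) !predictor %in% pair, spec$interactions)
  new_model_spec(paste0(spec$name, "_minus_", predictor),
                 setdiff(spec$predictors, predictor),
                 interactions = keep_int, subset = spec$subset,
                 outcome = spec$outcome)
}
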