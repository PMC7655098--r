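# Exhaustive all-subsets regression with BIC-weighted model averaging:
# enumerate every non-empty predictor subset, fit each with the intercept
# always included, weight models by exp(-dBIC/2), and average standardized
# coefficients across models.

#' Enumerate all non-empty predictor subsets
#'
#' With p candidate predictors there are \eqn{2^p - 1} non-empty subsets
#' (three predictors a, b, c yield seven models: a, b, c, a+b, a+c, b+c,
#' a+b+c). Subsets are returned in ascending inclusion-mask order, where bit
#' i of the mask flags predictor i, which makes the enumeration
#' deterministic.
#'
#' @param predictors Character vector of 1 to 20 predictor names.
#' @return List of character vectors, one per subset; the integer mask is
#'   attached as attribute `"mask"`.
#' @export
enumerate_candidate_models <- function(predictors) {
  p <- length(predictors)
  if (p < 1L) ub_validation_error("need at least one candidate predictor")
  if (p > 20L) {
    ub_validation_error(paste0(
      "refusing to enumerate 2^", p, " - 1 subsets; reduce the candidate set",
      " to at most 20 predictors (e.g. prune or pre-screen)"))
  }
  masks <- seq_len(2^p - 1L)
  subsets <- lapply(masks, function(m) predictors[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0L])
  attr(subsets, "mask") <- masks
  subsets
}

#' Fit every predictor subset of a model
#'
#' Resolves the specification's complete cases once (so every subset is fit
#' on identical rows), then fits all \eqn{2^p - 1} subset models by least
#' squares with the intercept always included. For each subset it records
#' SSE, BIC, and the raw and standardized coefficients with their standard
#' errors.
#'
#' @param spec Model specification or name; must not contain interaction
#'   terms.
#' @param cohort Subject-level data frame.
#' @return Object of class `ub_subset_fits` with elements `predictors`,
#'   `masks`, `subsets`, `n`, `n_models`, `size` (predictors per model),
#'   `sse`, `bic`, and the model-by-predictor matrices `beta_raw`, `se_raw`,
#'   `beta_std`, `se_std` (`NA` where a predictor is absent).
#' @export
fit_model_subsets <- function(spec, cohort) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  if (length(spec$interactions)) {
    ub_validation_error("all-subsets averaging is defined over main-effect predictors only")
  }
  mf <- model_frame(spec, cohort)
  Xp <- mf$X[, -1, drop = FALSE]
  y <- mf$y
  n <- nrow(Xp)
  p <- ncol(Xp)
  subsets <- enumerate_candidate_models(colnames(Xp))
  masks <- attr(subsets, "mask")
  n_models <- length(subsets)
  if (n <= p + 1L) {
    ub_validation_error("insufficient complete cases to fit the full model")
  }
  sdy <- sd(y)
  sdx <- apply(Xp, 2, sd)

  beta_raw <- matrix(NA_real_, n_models, p, dimnames = list(NULL, colnames(Xp)))
  se_raw <- beta_raw
  sse <- numeric(n_models)
  size <- lengths(subsets)
  ones <- rep(1, n)
  for (m in seq_len(n_models)) {
    cols <- subsets[[m]]
    Xm <- cbind(ones, Xp[, cols, drop = FALSE])
    qx <- qr(Xm)
    if (qx$rank < ncol(Xm)) {
      ub_validation_error(paste("rank-deficient subset:", paste(cols, collapse = ", ")))
    }
    b <- qr.coef(qx, y)
    res <- y - Xm %*% b
    sse[m] <- sum(res^2)
    sigma2 <- sse[m] / (n - ncol(Xm))
    cov_b <- chol2inv(qr.R(qx)) * sigma2
    beta_raw[m, cols] <- b[-1]
    se_raw[m, cols] <- sqrt(diag(cov_b))[-1]
  }
  scale_mat <- matrix(sdx / sdy, n_models, p, byrow = TRUE)
  structure(list(
    predictors = colnames(Xp),
    masks = masks,
    subsets = subsets,
    n = n,
    n_models = n_models,
    size = size,
    sse = sse,
    bic = bic_from_sse(sse, n, size + 1L),
    beta_raw = beta_raw,
    se_raw = se_raw,
    beta_std = beta_raw * scale_mat,
    se_std = se_raw * scale_mat
  ), class = "ub_subset_fits")
}

# BIC weights: w_m proportional to exp(-(BIC_m - BIC_min)/2), normalized.
bic_weights <- function(bic) {
  w <- exp(-(bic - min(bic)) / 2)
  w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-12) {
    ub_logic_error("BIC weights failed to normalize")
  }
  w
}

#' BIC-weighted averaged coefficients
#'
#' Averages each predictor's coefficient across the enumerated subset models
#' with weights proportional to \eqn{\exp(-\Delta BIC/2)}. The headline
#' estimate is *conditional*: the average over the models that contain the
#' predictor, with weights renormalized over that subset. The *full* average,
#' which counts a coefficient of zero whenever the predictor is absent, is
#' reported alongside. Confidence bounds use the model-averaged standard
#' error \eqn{\sum_m w_m \sqrt{se_m^2 + (\hat\beta_m - \bar\beta)^2}}, which
#' folds between-model spread into the interval.
#'
#' @param fits An `ub_subset_fits` object from [fit_model_subsets()].
#' @param scale `"standardized"` (default) or `"raw"` coefficients.
#' @param level Confidence level (default 0.95).
#' @return Object of class `ub_averaging`: list with `n_models`, `weights`,
#'   `scale` and `table`, a data frame with one row per predictor holding the
#'   conditional estimate/CI, the full-average estimate/CI, and
#'   `appear_weight`, the total weight of models containing the predictor.
#' @export
average_coefficients <- function(fits, scale = c("standardized", "raw"),
                                 level = 0.95) {
  scale <- match.arg(scale)
  if (!inherits(fits, "ub_subset_fits")) {
    ub_validation_error("fits must come from fit_model_subsets()")
  }
  if (fits$n_models < 1L) ub_validation_error("empty fit list")
  beta <- if (scale == "standardized") fits$beta_std else fits$beta_raw
  se <- if (scale == "standardized") fits$se_std else fits$se_raw
  w <- bic_weights(fits$bic)
  z <- qnorm((1 + level) / 2)

  avg_one <- function(bvec, svec, wvec) {
    est <- sum(wvec * bvec)
    se_avg <- sum(wvec * sqrt(svec^2 + (bvec - est)^2))
    c(est, est - z * se_avg, est + z * se_avg)
  }

  rows <- lapply(seq_along(fits$predictors), function(j) {
    has <- !is.na(beta[, j])
    wc <- w[has] / sum(w[has])
    cond <- avg_one(beta[has, j], se[has, j], wc)
    b_full <- ifelse(has, beta[, j], 0)
    s_full <- ifelse(has, se[, j], 0)
    full <- avg_one(b_full, s_full, w)
    data.frame(predictor = fits$predictors[j],
               estimate = cond[1], ci_low = cond[2], ci_high = cond[3],
               estimate_full = full[1], ci_low_full = full[2],
               ci_high_full = full[3],
               appear_weight = sum(w[has]),
               stringsAsFactors = FALSE)
  })
  structure(list(n_models = fits$n_models, weights = w, scale = scale,
                 level = level, table = do.call(rbind, rows)),
            class = "ub_averaging")
}

#' @export
print.ub_averaging <- function(x, ...) {
  cat(sprintf("BIC-weighted averaging over %d models (%s coefficients)\n",
              x$n_models, x$scale))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Rank subset models by BIC
#'
#' Orders all fitted subsets by ascending BIC (lower is better), breaking
#' ties by fewer predictors, then by inclusion mask.
#'
#' @param fits An `ub_subset_fits` object.
#' @return Data frame with `rank`, `mask`, `model` (predictor names joined by
#'   `+`), `n_predictors`, `sse`, `bic` and `weight`.
#' @export
rank_models <- function(fits) {
  if (!inherits(fits, "ub_subset_fits") || fits$n_models < 1L) {
    ub_validation_error("rank_models needs a non-empty ub_subset_fits object")
  }
  w <- bic_weights(fits$bic)
  ord <- order(fits$bic, fits$size, fits$masks)
  data.frame(
    rank = seq_along(ord),
    mask = fits$masks[ord],
    model = vapply(fits$subsets[ord], paste, character(1), collapse = " + "),
    n_predictors = fits$size[ord],
    sse = fits$sse[ord],
    bic = fits$bic[ord],
    weight = w[ord],
    stringsAsFactors = FALSE
  )
}

#' Predictor membership among the k best models
#'
#' Counts, for each candidate predictor, how many of the `k` lowest-BIC
#' models include it. A predictor present in all of the best models is a
#' robust member of the model family.
#'
#' @param fits An `ub_subset_fits` object.
#' @param k Number of top models to inspect.
#' @return Named integer vector of counts.
#' @export
top_k_membership <- function(fits, k = 8) {
  ranking <- rank_models(fits)
  k <- min(k, nrow(ranking))
  top <- ranking$mask[seq_len(k)]
  counts <- vapply(seq_along(fits$predictors), function(j) {
    sum(bitwAnd(top, 2^(j - 1L)) > 0L)
  }, integer(1))
  setNames(counts, fits$predictors)
}

#' All-subsets BIC model averaging in one call
#'
#' Convenience wrapper running [fit_model_subsets()],
#' [average_coefficients()], [rank_models()] and [top_k_membership()].
#'
#' @param spec Model specification or name.
#' @param cohort Subject-level data frame.
#' @param k Top-model count for the membership summary.
#' @param scale Coefficient scale for the averaging.
#' @return List with `fits`, `averaging`, `ranking`, `top_k`.
#' @export
model_average <- function(spec, cohort, k = 8, scale = "standardized") {
  fits <- fit_model_subsets(spec, cohort)
  list(fits = fits,
       averaging = average_coefficients(fits, scale = scale),
       ranking = rank_models(fits),
       top_k = top_k_membership(fits, k))
}
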