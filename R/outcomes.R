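# Construction of the prognostic outcome: months spent in euthymia after the
# task, censored at the follow-up horizon, log-transformed for normality, plus
# next-episode polarity coding and distribution diagnostics.

#' Censored time in euthymia
#'
#' Months spent in euthymia from task completion until the next mood episode.
#' Subjects who had not relapsed by the follow-up horizon (or whose relapse
#' fell beyond it) are assigned the horizon itself and flagged as censored;
#' downstream models treat these values as observed, mirroring the censor-at-
#' horizon convention of the prognostic analysis.
#'
#' @param relapse_month Numeric vector of months to relapse; `NA` for subjects
#'   with no relapse during follow-up. Must be positive when present.
#' @param horizon Follow-up horizon in months (default 60, i.e. 5 years).
#' @return Data frame with columns `months` and `censored`.
#' @examples
#' time_in_euthymia(c(18, NA, 72))
#' @export
time_in_euthymia <- function(relapse_month, horizon = 60) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    ub_validation_error("horizon must be a single positive number of months")
  }
  if (any(!is.na(relapse_month) & relapse_month <= 0)) {
    ub_validation_error("relapse_month must be positive when present")
  }
  censored <- is.na(relapse_month) | relapse_month > horizon
  months <- ifelse(censored, horizon, relapse_month)
  data.frame(months = months, censored = censored)
}

#' Natural-log transform of the outcome
#'
#' @param months Positive months in euthymia.
#' @return Natural logarithm of `months`.
#' @export
log_transform_outcome <- function(months) {
  if (any(!is.na(months) & months <= 0)) {
    ub_validation_error("months must be positive for the log transform")
  }
  log(months)
}

#' Numeric coding of next-episode polarity
#'
#' Depressive episodes are coded -1, manic episodes +1. Subjects without a
#' next episode (censored) have no polarity and map to `NA`.
#'
#' @param next_episode Character vector with values `"depressive"`, `"manic"`,
#'   `"none"` or `NA`.
#' @return Numeric vector of -1 / +1 / `NA`.
#' @export
code_polarity <- function(next_episode) {
  known <- c("depressive", "manic", "none")
  bad <- !is.na(next_episode) & !next_episode %in% known
  if (any(bad)) {
    ub_validation_error(paste0("unknown polarity label(s): ",
                               paste(unique(next_episode[bad]), collapse = ", "),
                               "; expected depressive, manic or none"))
  }
  out <- rep(NA_real_, length(next_episode))
  out[!is.na(next_episode) & next_episode == "depressive"] <- -1
  out[!is.na(next_episode) & next_episode == "manic"] <- 1
  out
}

#' Attach outcome columns to a subject table
#'
#' Convenience wrapper applying [time_in_euthymia()], [log_transform_outcome()]
#' and [code_polarity()] to a subject-level table. Polarity labels recorded
#' for censored subjects are inconsistent (a censored subject has no next
#' episode) and are set to missing with a warning.
#'
#' @param subjects Data frame with a months-to-relapse column and a
#'   next-episode label column.
#' @param relapse_col,polarity_col Names of those columns.
#' @param horizon Censoring horizon in months.
#' @return `subjects` with `months_euthymia`, `censored`, `log_months` and
#'   `next_polarity` appended.
#' @export
build_outcomes <- function(subjects, relapse_col = "relapse_month",
                           polarity_col = "next_episode", horizon = 60) {
  for (col in c(relapse_col, polarity_col)) {
    if (!col %in% names(subjects)) {
      ub_validation_error(paste0("subject table has no column '", col, "'"))
    }
  }
  te <- time_in_euthymia(subjects[[relapse_col]], horizon)
  subjects$months_euthymia <- te$months
  subjects$censored <- te$censored
  subjects$log_months <- log_transform_outcome(te$months)
  pol <- code_polarity(subjects[[polarity_col]])
  if (any(te$censored & !is.na(pol))) {
    warning("polarity labels on censored subjects set to missing", call. = FALSE)
    pol[te$censored] <- NA_real_
  }
  subjects$next_polarity <- pol
  subjects
}

# Kolmogorov-Smirnov distance between the sample and a normal law with the
# sample's own mean and sd (Lilliefors plug-in statistic).
ks_normal_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n)
}

#' Skewness and normality-distance diagnostics
#'
#' Reports the sample skewness and the Kolmogorov-Smirnov statistic of the
#' sample against a normal distribution with estimated mean and sd (the
#' Lilliefors plug-in statistic, as produced by the usual commercial-package
#' normality screen). Used to justify the log transform of months in
#' euthymia: raw months are strongly right-skewed, log months are not.
#'
#' @param values Numeric vector, `NA` dropped, at least 3 values with
#'   positive variance.
#' @param skewness `"adjusted"` (default) for the bias-adjusted
#'   Fisher-Pearson coefficient \eqn{G_1 = n/((n-1)(n-2)) \sum z_i^3}
#'   reported by SPSS/SAS-family software, `"moment"` for the simple moment
#'   coefficient \eqn{g_1}.
#' @return List with `skewness`, `ks_statistic` and `n`.
#' @export
distribution_diagnostics <- function(values, skewness = c("adjusted", "moment")) {
  skewness <- match.arg(skewness)
  x <- values[!is.na(values)]
  if (length(x) < 3L) {
    ub_validation_error("distribution_diagnostics needs at least 3 non-missing values")
  }
  if (sd(x) == 0) {
    ub_degenerate_error("zero variance; skewness and KS statistic undefined")
  }
  list(
    skewness = e1071::skewness(x, type = if (skewness == "adjusted") 2L else 1L),
    ks_statistic = ks_normal_statistic(x),
    n = length(x)
  )
}
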