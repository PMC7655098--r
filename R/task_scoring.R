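# Scoring of the belief update task: trial valence classification, trial-level
# updates and memory errors, per-subject aggregation into the update bias and
# the good-minus-bad delta covariates used by the prognostic models.

# Trial-level columns expected in a trials table.
TRIAL_COLUMNS <- c(
  "subject_id", "event_id", "first_estimate", "base_rate", "second_estimate",
  "recalled_rate", "rt_first", "rt_second", "familiarity", "prior_experience",
  "vividness", "arousal", "negativity"
)

# Rating scales collected once per event.
RATING_VARS <- c("familiarity", "prior_experience", "vividness", "arousal",
                 "negativity")

#' Classify trials as good news, bad news, or excluded
#'
#' A trial delivers *good news* when the presented population base rate is
#' lower than the participant's own first estimate (the adverse event is less
#' likely than they feared) and *bad news* when it is higher. Trials where the
#' two coincide carry no valence, and trials without a response cannot be
#' classified; both are excluded.
#'
#' @param first_estimate Numeric vector of first estimates in percent, `NA`
#'   for missing responses. When present, values must lie in the response
#'   range \eqn{[3, 77]}.
#' @param base_rate Numeric vector of presented base rates in percent, in
#'   \eqn{[10, 70]}; recycled if scalar.
#' @return Character vector with values `"good"`, `"bad"` or `"excluded"`.
#' @examples
#' classify_trial(c(25, 40, NA), c(10, 40, 30))
#' @export
classify_trial <- function(first_estimate, base_rate) {
  if (length(base_rate) == 1L) base_rate <- rep_len(base_rate, length(first_estimate))
  if (length(first_estimate) == 1L) first_estimate <- rep_len(first_estimate, length(base_rate))
  if (length(first_estimate) != length(base_rate)) {
    ub_validation_error("first_estimate and base_rate must have equal length")
  }
  ub_check_range(base_rate, 10, 70, "base_rate")
  ub_check_range(first_estimate, 3, 77, "first_estimate", allow_na = TRUE)
  out <- rep("excluded", length(base_rate))
  out[!is.na(first_estimate) & base_rate < first_estimate] <- "good"
  out[!is.na(first_estimate) & base_rate > first_estimate] <- "bad"
  out
}

#' Trial-level belief update
#'
#' The update is the belief change between the two estimation sessions, signed
#' so that positive values always indicate movement *toward* the presented
#' information: first minus second estimate on good-news trials, second minus
#' first on bad-news trials.
#'
#' @param first_estimate,second_estimate Numeric vectors of estimates in
#'   percent; both must be present.
#' @param valence Character vector of `"good"` / `"bad"` labels as returned by
#'   [classify_trial()]. Excluded trials have no update and passing them is a
#'   caller error.
#' @return Numeric vector of signed updates in percentage points.
#' @examples
#' compute_update(40, 30, "good")  # +10, moved toward the information
#' compute_update(40, 45, "good")  # -5, moved away
#' @export
compute_update <- function(first_estimate, second_estimate, valence) {
  if (any(valence == "excluded")) {
    ub_logic_error("compute_update called with valence = 'excluded'; excluded trials have no update")
  }
  if (!all(valence %in% c("good", "bad"))) {
    ub_validation_error("valence must be 'good' or 'bad'")
  }
  if (any(is.na(first_estimate)) || any(is.na(second_estimate))) {
    ub_validation_error("compute_update requires both estimates to be present")
  }
  ifelse(valence == "good",
         first_estimate - second_estimate,
         second_estimate - first_estimate)
}

#' Trial-level memory error
#'
#' Absolute difference between the base rate presented during the task and the
#' participant's later recollection of it. Missing recollections propagate to
#' a missing memory error (the trial still contributes to other scores).
#'
#' @param presented Presented base rate, percent.
#' @param recalled Recalled base rate, percent, possibly `NA`.
#' @return Non-negative numeric vector (or `NA`).
#' @export
compute_memory_error <- function(presented, recalled) {
  abs(presented - recalled)
}

#' Classify and augment a trials table
#'
#' Adds the derived trial-level columns used for subject scoring: `valence`,
#' the exclusion bookkeeping `exclusion_reason` (`"missing_response"` when
#' either estimate is absent, `"equal_estimates"` when the first estimate
#' equals the base rate), the signed `update`, the estimation error in both
#' absolute (`estimation_error`) and signed (`estimation_error_signed`,
#' base rate minus first estimate) form, and `memory_error`.
#'
#' @param trials Data frame with the columns listed in
#'   [read_trials()] (one row per trial).
#' @return The input data frame with the derived columns appended.
#' @export
classify_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    ub_validation_error(paste("trials table is missing columns:",
                              paste(missing_cols, collapse = ", ")))
  }
  valence <- classify_trial(trials$first_estimate, trials$base_rate)
  missing_resp <- is.na(trials$first_estimate) | is.na(trials$second_estimate)
  reason <- rep(NA_character_, nrow(trials))
  reason[valence == "excluded" & !missing_resp] <- "equal_estimates"
  reason[missing_resp] <- "missing_response"
  valence[missing_resp] <- "excluded"

  update <- rep(NA_real_, nrow(trials))
  scored <- valence %in% c("good", "bad")
  if (any(scored)) {
    update[scored] <- compute_update(trials$first_estimate[scored],
                                     trials$second_estimate[scored],
                                     valence[scored])
  }
  trials$valence <- valence
  trials$exclusion_reason <- reason
  trials$update <- update
  trials$estimation_error_signed <- trials$base_rate - trials$first_estimate
  trials$estimation_error <- abs(trials$estimation_error_signed)
  trials$memory_error <- compute_memory_error(trials$base_rate,
                                              trials$recalled_rate)
  trials
}

# Variables averaged per valence when building the delta covariates.
delta_source_vars <- function(estimation_error = "absolute") {
  est_col <- if (identical(estimation_error, "signed")) {
    "estimation_error_signed"
  } else {
    "estimation_error"
  }
  c(estimation_error = est_col, memory_error = "memory_error",
    rt_first = "rt_first", rt_second = "rt_second",
    familiarity = "familiarity", prior_experience = "prior_experience",
    vividness = "vividness", arousal = "arousal", negativity = "negativity")
}

#' Aggregate classified trials into per-subject scores
#'
#' For each subject, computes the mean update separately for good- and
#' bad-news trials, the update bias (good minus bad), the mean first estimate
#' over all answered trials, trial-count bookkeeping, and the ten
#' good-minus-bad delta covariates (estimation error, memory error, trial
#' counts, both reaction times, and the five subjective ratings). Per-valence
#' means use whatever trials have the variable present (trial-level pairwise
#' deletion). Subjects without at least one good and one bad trial cannot be
#' scored; they are dropped with a warning and listed in the `"unscorable"`
#' attribute of the result.
#'
#' @param classified Output of [classify_trials()].
#' @param estimation_error `"absolute"` (default) to build the
#'   delta-estimation-error covariate from |base rate - first estimate| per
#'   valence, `"signed"` to use the signed error instead. The signed error is
#'   negative on every good-news trial and positive on every bad-news trial by
#'   construction, so its delta is confounded with valence; the absolute form
#'   is the informative default.
#' @return Data frame with one row per scorable subject.
#' @export
score_subjects <- function(classified, estimation_error = c("absolute", "signed")) {
  estimation_error <- match.arg(estimation_error)
  if (!"valence" %in% names(classified)) {
    ub_validation_error("score_subjects expects the output of classify_trials()")
  }
  src <- delta_source_vars(estimation_error)
  idx_by_subject <- split(seq_len(nrow(classified)), classified$subject_id)

  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }

  rows <- lapply(names(idx_by_subject), function(sid) {
    i <- idx_by_subject[[sid]]
    val <- classified$valence[i]
    reason <- classified$exclusion_reason[i]
    good <- i[val == "good"]
    bad <- i[val == "bad"]
    n_good <- length(good)
    n_bad <- length(bad)
    if (n_good == 0L || n_bad == 0L) {
      warning(sprintf("subject %s has no %s-news trials and cannot be scored; dropped",
                      sid, if (n_good == 0L) "good" else "bad"), call. = FALSE)
      return(NULL)
    }
    mug <- mean(classified$update[good])
    mub <- mean(classified$update[bad])
    out <- data.frame(
      subject_id = sid,
      n_good = n_good,
      n_bad = n_bad,
      n_excluded = sum(!is.na(reason) & reason == "equal_estimates"),
      n_missing = sum(!is.na(reason) & reason == "missing_response"),
      mean_update_good = mug,
      mean_update_bad = mub,
      update_bias = mug - mub,
      mean_first_estimate = mean_or_na(classified$first_estimate[i]),
      delta_n_trials = n_good - n_bad,
      stringsAsFactors = FALSE
    )
    for (nm in names(src)) {
      col <- classified[[src[[nm]]]]
      out[[paste0("delta_", nm)]] <-
        mean_or_na(col[good]) - mean_or_na(col[bad])
    }
    out
  })
  kept <- !vapply(rows, is.null, logical(1))
  res <- do.call(rbind, rows[kept])
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  attr(res, "unscorable") <- names(idx_by_subject)[!kept]
  res
}

#' Paired comparison of a task variable between good and bad news
#'
#' Computes each subject's good-news and bad-news mean of a task variable and
#' runs a classic paired t-test on the per-subject pairs (two-sided,
#' df = pairs - 1). This is the screen used to decide which subjective
#' ratings differ between valences and therefore belong in the
#' ratings-only control model.
#'
#' @param classified Output of [classify_trials()].
#' @param variable One of `"update"`, `"estimation_error"`, `"memory_error"`,
#'   `"rt_first"`, `"rt_second"`, the five rating names, or `"n_trials"`
#'   (paired comparison of good vs bad trial counts).
#' @return List with elements `variable`, `t`, `df`, `p.value`, `mean_diff`
#'   (good minus bad) and `n` (number of complete pairs).
#' @export
compare_good_bad <- function(classified, variable) {
  choices <- c("update", "estimation_error", "memory_error", "rt_first",
               "rt_second", RATING_VARS, "n_trials")
  if (!variable %in% choices) {
    ub_validation_error(paste0("unknown variable '", variable, "'; choose one of: ",
                               paste(choices, collapse = ", ")))
  }
  keep <- classified$valence %in% c("good", "bad")
  cls <- classified[keep, , drop = FALSE]
  if (variable == "n_trials") {
    tab <- table(cls$subject_id, cls$valence)
    g <- as.numeric(tab[, "good"])
    b <- as.numeric(tab[, "bad"])
  } else {
    g <- tapply(cls[[variable]][cls$valence == "good"],
                cls$subject_id[cls$valence == "good"], mean, na.rm = TRUE)
    b <- tapply(cls[[variable]][cls$valence == "bad"],
                cls$subject_id[cls$valence == "bad"], mean, na.rm = TRUE)
    ids <- intersect(names(g), names(b))
    g <- as.numeric(g[ids])
    b <- as.numeric(b[ids])
  }
  ok <- is.finite(g) & is.finite(b)
  g <- g[ok]
  b <- b[ok]
  if (length(g) < 3L) {
    ub_validation_error("compare_good_bad needs at least 3 subjects with both per-valence means")
  }
  d <- g - b
  if (sd(d) == 0) {
    ub_degenerate_error("zero variance of good-minus-bad differences; paired t undefined")
  }
  tt <- t.test(g, b, paired = TRUE)
  list(variable = variable,
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p.value = tt$p.value,
       mean_diff = mean(d),
       n = length(d))
}
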