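# Small fixtures built in code.

# A hand-written trials table for one subject: two good-news trials with
# updates +10 and +20, two bad-news trials with updates +5 each, one
# equal-estimate trial, one missing response.
toy_trials <- function(subject_id = "S1") {
  data.frame(
    subject_id = subject_id,
    event_id = paste0("E", 1:6),
    first_estimate = c(40, 50, 20, 30, 40, NA),
    base_rate = c(10, 20, 40, 50, 40, 30),
    second_estimate = c(30, 30, 25, 35, 40, NA),
    recalled_rate = c(22, 30, 42, 50, 38, 30),
    rt_first = c(1.2, 1.4, 1.1, 1.3, 1.5, NA),
    rt_second = c(1.0, 1.2, 0.9, 1.1, 1.3, NA),
    familiarity = c(3L, 4L, 2L, 3L, 5L, 2L),
    prior_experience = c(1L, 2L, 1L, 2L, 1L, 1L),
    vividness = c(4L, 5L, 3L, 3L, 4L, 3L),
    arousal = c(3L, 4L, 4L, 3L, 5L, 2L),
    negativity = c(5L, 5L, 4L, 5L, 6L, 4L),
    stringsAsFactors = FALSE
  )
}

# A small scored-and-merged synthetic cohort for model fitting.
small_cohort <- function(seed = 11, n = 36, ...) {
  cfg <- synthetic_config(n_subjects = n, seed = seed, ...)
  suppressWarnings(assemble_cohort(generate_cohort(cfg)))
}

# Random regression instance for oracle comparisons.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rnorm(n)
  dat <- data.frame(log_months = y, X, subject_id = paste0("S", seq_len(n)))
  spec <- new_model_spec("rand", paste0("x", seq_len(p)))
  list(dat = dat, spec = spec, X = cbind(1, X), y = y)
}
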