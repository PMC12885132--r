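# Internal helpers shared across modules.

#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

# Gestation constants: day 0 = conception; week w covers days [7w, 7w+6];
# preterm = GA < 259 days (< 37 completed weeks); at-risk weeks are 22..36.
PRETERM_CUTOFF_DAYS <- 259L
FIRST_RISK_WEEK <- 22L
LAST_RISK_WEEK <- 36L

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stopf("`%s` must be a probability in [0, 1]", name)
  invisible(x)
}

#' @keywords internal
assert_scalar_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      (positive && x <= 0))
    stopf("`%s` must be a positive integer", name)
  invisible(as.integer(x))
}

#' @keywords internal
ga_completed_weeks <- function(ga_days) as.integer(floor(ga_days / 7))

#' @keywords internal
is_preterm <- function(ga_days) ga_days < PRETERM_CUTOFF_DAYS
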