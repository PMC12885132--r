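# Pregnancy exposure metrics from daily wildfire PM2.5 series:
# smoke days, smoke waves, weekly / cumulative-by-week / trimester windows.

#' Standard smoke-day concentration thresholds
#'
#' Thresholds (ug/m3) at which smoke days and smoke waves are counted. `0`
#' is evaluated strictly (`> 0`), the others inclusively (`>=`), so `2.5`,
#' `5.0` and `10.0` mark increasingly intense smoke days; they sit near the
#' 50th, 75th and 90th percentiles of the smoke-day concentration
#' distribution in typical US data.
#' @export
SMOKE_THRESHOLDS <- c(0, 2.5, 5.0, 10.0)

#' Count smoke days in a daily exposure vector
#'
#' A smoke day is a day whose daily mean wildfire PM2.5 exceeds a threshold:
#' strictly (`> threshold`, used for the any-smoke threshold 0) or
#' inclusively (`>= threshold`, used for 2.5 / 5.0 / 10.0 ug/m3).
#'
#' @param x numeric vector of daily mean wildfire PM2.5 (ug/m3), one value per
#'   day, no gaps.
#' @param threshold threshold in ug/m3; must be non-negative.
#' @param strict if `TRUE` count days with `x > threshold`, else `x >=
#'   threshold`. Defaults to strict exactly when `threshold == 0`.
#' @return integer count of qualifying days.
#' @export
count_smoke_days <- function(x, threshold, strict = (threshold == 0)) {
  if (length(x) == 0L) stopf("exposure vector is empty")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stopf("`threshold` must be a single non-negative number")
  if (strict) sum(x > threshold) else sum(x >= threshold)
}

#' Count smoke waves (runs of consecutive smoke days)
#'
#' A smoke wave of duration `d` is a maximal run of consecutive smoke days
#' (at or above `threshold`) lasting at least `d` days, so a 5-day run
#' contributes one wave at each of `min_duration` 2, 3 and 4. This
#' at-least-d convention makes wave prevalence monotone non-increasing in
#' duration.
#'
#' @inheritParams count_smoke_days
#' @param min_duration minimum run length, one of 2, 3, 4 (4 means ">= 4
#'   consecutive days").
#' @param strict threshold rule, as in [count_smoke_days()].
#' @return integer number of maximal runs with length `>= min_duration`.
#' @export
count_smoke_waves <- function(x, threshold, min_duration,
                              strict = (threshold == 0)) {
  if (!min_duration %in% c(2L, 3L, 4L))
    stopf("`min_duration` must be 2, 3 or 4")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stopf("`threshold` must be a single non-negative number")
  if (length(x) < min_duration) return(0L)
  hit <- if (strict) x > threshold else x >= threshold
  r <- rle(hit)
  sum(r$values & r$lengths >= min_duration)
}

#' Cumulative exposure metrics at the start of each gestational week
#'
#' For each gestational week `w` the cumulative window runs from conception
#' to the start of the week, i.e. days `0 .. 7w - 1`. Metrics therefore
#' exclude the week's own exposure, so a week-`w` outcome is never compared
#' against exposure accrued after it.
#'
#' @inheritParams count_smoke_days
#' @param weeks integer vector of gestational weeks (`>= 1`); every requested
#'   week must satisfy `7 * w <= length(x)`.
#' @param thresholds numeric thresholds at which smoke days are counted;
#'   threshold 0 is strict, others inclusive.
#' @return data.frame with one row per week: `week`, `cum_mean` (mean daily
#'   PM2.5 over days `0..7w-1`) and one `cum_days_*` column per threshold.
#' @export
cumulative_by_week <- function(x, weeks = seq_len(length(x) %/% 7L),
                               thresholds = SMOKE_THRESHOLDS) {
  weeks <- as.integer(weeks)
  if (length(weeks) == 0L || any(weeks < 1L))
    stopf("`weeks` must be positive integers")
  if (max(weeks) * 7L > length(x))
    stopf("week %d needs %d days of exposure but only %d are available",
          max(weeks), max(weeks) * 7L, length(x))
  cs <- cumsum(x)
  out <- data.frame(week = weeks,
                    cum_mean = cs[7L * weeks] / (7 * weeks))
  for (t in thresholds) {
    hit <- if (t == 0) x > 0 else x >= t
    ch <- cumsum(hit)
    out[[smoke_col("cum_days", t)]] <- ch[7L * weeks]
  }
  out
}

#' Smoke days within one gestational week
#'
#' Counts smoke days over days `7w .. 7w+6` (week `w`, 0-based from
#' conception). Only fully covered weeks are valid; a partial terminal week
#' is an error rather than a truncated count.
#'
#' @inheritParams count_smoke_days
#' @param week gestational week, 0..36.
#' @return integer count of smoke days in that week.
#' @export
week_specific_days <- function(x, threshold, week,
                               strict = (threshold == 0)) {
  week <- assert_scalar_count(week, "week", positive = FALSE)
  if (week < 0L || week > 36L) stopf("`week` must be in 0..36")
  lo <- 7L * week + 1L
  hi <- lo + 6L
  if (hi > length(x))
    stopf("week %d is not fully covered (needs days through %d, have %d)",
          week, hi, length(x))
  count_smoke_days(x[lo:hi], threshold, strict = strict)
}

#' Trimester-specific exposure metrics
#'
#' Splits the pregnancy into trimester 1 (weeks 0-12, days 0..90),
#' trimester 2 (weeks 13-26, days 91..188) and trimester 3 (week 27 to
#' delivery). These boundaries are a documented convention. A delivery
#' before the start of trimester 3 yields an empty third trimester
#' (`n_days = 0`, metrics `NA`/0).
#'
#' @inheritParams count_smoke_days
#' @param thresholds thresholds for smoke-day counts.
#' @return data.frame with rows T1, T2, T3: `n_days`, `mean_daily`, and
#'   smoke-day counts per threshold.
#' @export
trimester_metrics <- function(x, thresholds = SMOKE_THRESHOLDS) {
  n <- length(x)
  if (n == 0L) stopf("exposure vector is empty")
  bounds <- list(T1 = c(1L, min(91L, n)),
                 T2 = if (n >= 92L) c(92L, min(189L, n)) else NULL,
                 T3 = if (n >= 190L) c(190L, n) else NULL)
  rows <- lapply(names(bounds), function(tri) {
    b <- bounds[[tri]]
    if (is.null(b)) {
      row <- data.frame(trimester = tri, n_days = 0L, mean_daily = NA_real_)
      for (t in thresholds) row[[smoke_col("days", t)]] <- 0L
      return(row)
    }
    seg <- x[b[1]:b[2]]
    row <- data.frame(trimester = tri, n_days = length(seg),
                      mean_daily = mean(seg))
    for (t in thresholds)
      row[[smoke_col("days", t)]] <- count_smoke_days(seg, t)
    row
  })
  do.call(rbind, rows)
}

#' Empirical percentiles of smoke-day concentrations
#'
#' Returns the 50th, 75th and 90th percentiles (linear interpolation,
#' `stats::quantile` type 7) of a sample of positive smoke-day
#' concentrations; the conventional way to anchor intensity thresholds.
#'
#' @param x numeric vector of smoke-day PM2.5 concentrations (> 0), non-empty.
#' @return named numeric vector `c(p50=, p75=, p90=)` in ug/m3.
#' @export
threshold_percentiles <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stopf("empty concentration sample")
  stats::setNames(stats::quantile(x, c(.5, .75, .9), names = FALSE, type = 7),
                  c("p50", "p75", "p90"))
}

#' Pearson correlations between exposure metrics
#'
#' Pairwise Pearson correlation matrix of pregnancy-level exposure metrics
#' (or of week-by-week smoke-day counts). Zero-variance columns are flagged
#' and their correlations reported as `NA` rather than an error.
#'
#' @param metrics numeric matrix or data.frame, one row per pregnancy
#'   (needs at least 3 rows).
#' @return list with `cor` (correlation matrix) and `degenerate` (names of
#'   zero-variance columns).
#' @export
correlation_diagnostics <- function(metrics) {
  m <- as.matrix(metrics)
  if (nrow(m) < 3L) stopf("need at least 3 pregnancies")
  sds <- apply(m, 2L, stats::sd)
  degenerate <- colnames(m)[!is.na(sds) & sds == 0]
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (length(degenerate)) cc[degenerate, ] <- cc[, degenerate] <- NA_real_
  diag(cc) <- ifelse(colnames(m) %in% degenerate, NA_real_, 1)
  list(cor = cc, degenerate = degenerate)
}

#' @keywords internal
smoke_col <- function(prefix, threshold) {
  if (threshold == 0) paste0(prefix, "_gt0")
  else paste0(prefix, "_ge", gsub("\\.", "_", format(threshold)))
}

#' Per-pregnancy exposure metric table for a cohort
#'
#' Applies the full metric set (pregnancy mean daily PM2.5, smoke days and
#' smoke waves at every threshold/duration) to a list of per-gestational-day
#' exposure vectors.
#'
#' @param daily named list of numeric daily exposure vectors, one per
#'   pregnancy (conception to delivery).
#' @param thresholds smoke-day thresholds; waves are counted at the
#'   non-zero thresholds.
#' @return data.frame, one row per pregnancy: `pregnancy_id`, `n_days`,
#'   `mean_daily`, `days_*` per threshold, `waves_*_d{2,3,4}` per non-zero
#'   threshold.
#' @export
cohort_exposure_metrics <- function(daily, thresholds = SMOKE_THRESHOLDS) {
  if (!length(daily)) stopf("no pregnancies supplied")
  ids <- names(daily)
  if (is.null(ids)) ids <- as.character(seq_along(daily))
  wave_thr <- thresholds[thresholds > 0]
  one <- function(x) {
    v <- c(n_days = length(x), mean_daily = mean(x))
    for (t in thresholds)
      v[smoke_col("days", t)] <- count_smoke_days(x, t)
    for (t in wave_thr) for (d in 2:4)
      v[paste0(smoke_col("waves", t), "_d", d)] <- count_smoke_waves(x, t, d)
    v
  }
  tab <- do.call(rbind, lapply(daily, one))
  out <- data.frame(pregnancy_id = ids, tab, row.names = NULL,
                    check.names = FALSE)
  out
}
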