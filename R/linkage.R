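# Linking residential history to tract-day wildfire PM2.5 series.

#' Construct a single-tract daily series
#'
#' @param tract_id tract identifier.
#' @param start_date `Date` of the first value.
#' @param values daily mean wildfire PM2.5 (ug/m3), gap-free, all `>= 0`.
#' @return object of class `daily_series`.
#' @export
daily_series <- function(tract_id, start_date, values) {
  start_date <- as.Date(start_date)
  if (anyNA(values) || any(values < 0))
    stopf("daily series values must be non-negative and complete")
  structure(list(tract_id = as.character(tract_id),
                 start_date = start_date,
                 values = as.numeric(values)),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> tract %s: %d days from %s (mean %.3f ug/m3)\n",
              x$tract_id, length(x$values), format(x$start_date),
              mean(x$values)))
  invisible(x)
}

# A series store is either a named list of daily_series, or a numeric matrix
# (days x tracts) with attribute "start_date" and tract ids as colnames --
# the compact form the simulator produces.
#' @keywords internal
series_lookup <- function(store, tract, dates) {
  if (is.matrix(store)) {
    start <- attr(store, "start_date")
    j <- match(tract, colnames(store))
    if (is.na(j)) stopf("no exposure series for tract %s", tract)
    i <- as.integer(dates - start) + 1L
    if (any(i < 1L) || any(i > nrow(store)))
      stopf("series for tract %s does not cover %s", tract,
            format(dates[which(i < 1L | i > nrow(store))[1]]))
    store[i, j]
  } else {
    s <- store[[tract]]
    if (is.null(s)) stopf("no exposure series for tract %s", tract)
    i <- as.integer(dates - s$start_date) + 1L
    if (any(i < 1L) || any(i > length(s$values)))
      stopf("series for tract %s does not cover %s", tract,
            format(dates[which(i < 1L | i > length(s$values))[1]]))
    s$values[i]
  }
}

#' Link residential history to tract series over a pregnancy
#'
#' Produces the per-gestational-day exposure vector: day `d` (0-based from
#' conception) takes the value of the tract of residence on `conception + d`.
#' Residential intervals are half-open `[start_date, end_date)`. Days not
#' covered by any interval are carried forward from the last resident tract
#' for up to `max_gap` days; a longer (or leading) gap is a linkage error
#' naming the first uncovered date.
#'
#' @param history data.frame with columns `tract_id`, `start_date`,
#'   `end_date` (half-open), non-overlapping.
#' @param store series store: named list of [daily_series()] objects or a
#'   days-by-tracts matrix with a `start_date` attribute.
#' @param conception conception `Date`.
#' @param ga_days gestational age at delivery in days (vector length).
#' @param max_gap maximum residential-history gap (days) bridged by
#'   carrying the previous tract forward.
#' @return numeric vector of length `ga_days`.
#' @export
link_residence_series <- function(history, store, conception, ga_days,
                                  max_gap = 7L) {
  conception <- as.Date(conception)
  ga_days <- assert_scalar_count(ga_days, "ga_days")
  dates <- conception + 0:(ga_days - 1L)
  tract <- rep(NA_character_, ga_days)
  hs <- as.Date(history$start_date); he <- as.Date(history$end_date)
  for (k in seq_len(nrow(history))) {
    sel <- dates >= hs[k] & dates < he[k]
    tract[sel] <- as.character(history$tract_id[k])
  }
  if (anyNA(tract)) {
    gap <- rle(is.na(tract))
    pos <- cumsum(c(1L, gap$lengths))
    for (g in which(gap$values)) {
      i0 <- pos[g]; len <- gap$lengths[g]
      if (i0 == 1L || len > max_gap)
        stopf("residential history does not cover %s (gap of %d days > max_gap = %d)",
              format(dates[i0]), len, max_gap)
      tract[i0:(i0 + len - 1L)] <- tract[i0 - 1L]
    }
  }
  out <- numeric(ga_days)
  for (tr in unique(tract)) {
    sel <- tract == tr
    out[sel] <- series_lookup(store, tr, dates[sel])
  }
  out
}

#' Link every pregnancy in a cohort to its daily exposure vector
#'
#' @param records pregnancy table with `pregnancy_id`, `conception`,
#'   `ga_days`.
#' @param history residential-history table with `pregnancy_id`, `tract_id`,
#'   `start_date`, `end_date`.
#' @param store series store (see [link_residence_series()]).
#' @param max_gap gap-bridging policy in days.
#' @param ga_days horizon in days per pregnancy; defaults to the recorded
#'   gestational age (supply explicitly for outcome-free records).
#' @return named list of daily exposure vectors keyed by `pregnancy_id`.
#' @export
link_cohort_series <- function(records, history, store, max_gap = 7L,
                               ga_days = records$ga_days) {
  if (length(ga_days) == 1L) ga_days <- rep(ga_days, nrow(records))
  hsplit <- split(history, history$pregnancy_id)
  out <- vector("list", nrow(records))
  names(out) <- as.character(records$pregnancy_id)
  for (i in seq_len(nrow(records))) {
    id <- as.character(records$pregnancy_id[i])
    h <- hsplit[[id]]
    if (is.null(h)) stopf("no residential history for pregnancy %s", id)
    out[[i]] <- link_residence_series(h, store, records$conception[i],
                                      ga_days[i], max_gap = max_gap)
  }
  out
}
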