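# Cohort inclusion rules and person-period expansion for pooled logistic
# regression over gestational weeks 22-36.

#' Apply birth-level inclusion rules
#'
#' Keeps live singleton births with a parseable conception date inside the
#' study window, a recorded gestational age, and a conception early enough
#' that a full 41-week (287-day) pregnancy is observable before the end of
#' exposure coverage. The last rule avoids fixed cohort bias: without it,
#' pregnancies conceived near the end of coverage could only enter the
#' cohort by delivering preterm. Exclusion reasons are counted disjointly,
#' in rule order.
#'
#' @param records birth table with columns `conception` (Date), `ga_days`,
#'   `live_birth`, `singleton` (logical; missing columns are treated as all
#'   `TRUE`).
#' @param exposure_end_date last date with exposure coverage.
#' @param conception_window length-2 `Date` vector of allowed conceptions.
#' @param full_term_days observability requirement in days (41 weeks).
#' @return list with `records` (included rows) and `ledger` (data.frame of
#'   `reason`, `n`; reasons sum to input minus output).
#' @export
apply_inclusion_rules <- function(records,
                                  exposure_end_date,
                                  conception_window = as.Date(c("2006-01-01",
                                                                "2020-03-20")),
                                  full_term_days = 287L) {
  exposure_end_date <- as.Date(exposure_end_date)
  conception <- as.Date(records$conception)
  live <- if ("live_birth" %in% names(records)) records$live_birth else TRUE
  singleton <- if ("singleton" %in% names(records)) records$singleton else TRUE

  reasons <- character(nrow(records))
  mark <- function(cond, label) {
    sel <- reasons == "" & cond
    reasons[sel] <<- label
  }
  mark(is.na(conception), "unparseable conception date")
  mark(is.na(records$ga_days), "missing gestational age")
  mark(!live %in% TRUE, "not a live birth")
  mark(!singleton %in% TRUE, "multiple gestation")
  mark(conception < conception_window[1] | conception > conception_window[2],
       "conception outside study window")
  # half-open comparison: conception + 287 days must not pass the day after
  # the last covered date
  mark(conception + full_term_days > exposure_end_date + 1L,
       "conceived too late for full follow-up (fixed cohort bias)")

  keep <- reasons == ""
  tab <- table(factor(reasons[!keep], levels = unique(reasons[!keep])))
  ledger <- data.frame(reason = names(tab), n = as.integer(tab),
                       row.names = NULL)
  list(records = records[keep, , drop = FALSE], ledger = ledger)
}

#' Apply site-level exclusions
#'
#' Drops every birth from a study site that (1) is flagged as selecting
#' participants on the outcome (low gestational age / birthweight), (2) has
#' fewer than `min_births` included births, or (3) exceeds `max_missing`
#' missingness in any of the listed covariates.
#'
#' @param records included birth table with `site_id`.
#' @param covariates character vector of covariate columns whose
#'   missingness is screened (typically the primary-model set).
#' @param min_births minimum births per retained site.
#' @param max_missing maximum tolerated per-covariate missingness fraction.
#' @param flagged_sites character vector of site ids excluded by design
#'   (selection on outcome).
#' @return list with `records` and `ledger` (site_id, n_births, reason).
#' @export
apply_site_exclusions <- function(records, covariates = character(),
                                  min_births = 100L, max_missing = 0.25,
                                  flagged_sites = character()) {
  assert_prob(max_missing, "max_missing")
  sites <- split(seq_len(nrow(records)), records$site_id)
  drop <- list()
  for (s in names(sites)) {
    idx <- sites[[s]]
    reason <- NULL
    if (s %in% as.character(flagged_sites)) {
      reason <- "selection on outcome"
    } else if (length(idx) < min_births) {
      reason <- sprintf("fewer than %d births", min_births)
    } else if (length(covariates)) {
      miss <- vapply(covariates, function(v) mean(is.na(records[[v]][idx])),
                     numeric(1))
      if (any(miss > max_missing))
        reason <- sprintf("covariate missingness > %d%% (%s)",
                          round(100 * max_missing),
                          covariates[which.max(miss)])
    }
    if (!is.null(reason))
      drop[[s]] <- data.frame(site_id = s, n_births = length(idx),
                              reason = reason)
  }
  ledger <- if (length(drop)) do.call(rbind, drop) else
    data.frame(site_id = character(), n_births = integer(),
               reason = character())
  keep <- !(as.character(records$site_id) %in% ledger$site_id)
  if (!any(keep)) warning("all sites excluded; empty cohort returned")
  list(records = records[keep, , drop = FALSE],
       ledger = ledger[order(ledger$site_id), , drop = FALSE])
}

#' Expand births into a person-period table
#'
#' One row per pregnancy and at-risk gestational week (22-36). A preterm
#' birth delivering in completed week `w*` contributes rows for weeks
#' `22..w*` with `event = 1` only at `w*`; a term birth (>= 259 days) is
#' censored at week 36 and contributes 15 all-zero rows. Cumulative
#' exposure is attached at start-of-week values (days `0..7w-1`), so the
#' outcome week's own exposure never enters its row.
#'
#' @param records included births with `pregnancy_id`, `site_id`, `ga_days`
#'   and covariates.
#' @param metrics long table from [cumulative_by_week()] applied per
#'   pregnancy: columns `pregnancy_id`, `week`, plus metric columns.
#' @return list with `table` (person-period data.frame carrying all record
#'   columns, `gestational_week`, `event`, metric columns) and `ledger`
#'   (exclusions, e.g. gestational age below 22 weeks).
#' @export
person_period_expand <- function(records, metrics) {
  if (any(c("gestational_week", "event") %in% names(records)))
    stopf("input already looks like a person-period table; expansion is not idempotent")
  ga_week <- ga_completed_weeks(records$ga_days)
  too_early <- ga_week < FIRST_RISK_WEEK
  ledger <- data.frame(reason = "gestational age below 22 weeks",
                       n = sum(too_early))
  rec <- records[!too_early, , drop = FALSE]
  ga_week <- ga_week[!too_early]
  last_week <- pmin(ga_week, LAST_RISK_WEEK)
  n_rows <- last_week - FIRST_RISK_WEEK + 1L
  idx <- rep(seq_len(nrow(rec)), n_rows)
  week <- unlist(lapply(n_rows, function(k) FIRST_RISK_WEEK + seq_len(k) - 1L),
                 use.names = FALSE)
  tab <- rec[idx, , drop = FALSE]
  tab$gestational_week <- week
  preterm <- is_preterm(rec$ga_days)
  tab$event <- as.integer(preterm[idx] & week == last_week[idx])
  rownames(tab) <- NULL
  if (!is.null(metrics)) {
    key_t <- paste(tab$pregnancy_id, tab$gestational_week)
    key_m <- paste(metrics$pregnancy_id, metrics$week)
    j <- match(key_t, key_m)
    if (anyNA(j)) {
      bad <- which(is.na(j))[1]
      stopf("no cumulative exposure for pregnancy %s at week %d",
            tab$pregnancy_id[bad], tab$gestational_week[bad])
    }
    mcols <- setdiff(names(metrics), c("pregnancy_id", "week"))
    for (cn in mcols) tab[[cn]] <- metrics[[cn]][j]
  }
  list(table = tab, ledger = ledger)
}

#' Closed-form person-period row count
#'
#' Number of at-risk rows a birth contributes:
#' `min(floor(ga_days / 7), 36) - 22 + 1`, and 0 below 22 weeks.
#'
#' @param ga_days gestational age(s) in days.
#' @return integer vector of row counts.
#' @export
person_period_rows <- function(ga_days) {
  w <- pmin(ga_completed_weeks(ga_days), LAST_RISK_WEEK)
  pmax(w - FIRST_RISK_WEEK + 1L, 0L)
}
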