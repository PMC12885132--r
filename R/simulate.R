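# Synthetic cohort generator: tract exposure series, pregnancies,
# outcomes from a known discrete-time hazard, and covariate missingness.

#' @keywords internal
seasonal_enter_mult <- function(dates, amplitude) {
  doy <- as.POSIXlt(dates)$yday + 1L
  1 + amplitude * cos(2 * pi * (doy - 227) / 365.25)
}

# Core simulator: one Markov chain + episode-lognormal intensity process per
# tract, all tracts advanced in lockstep one day at a time. Returns a
# days-by-tracts matrix with attribute "start_date".
#' @keywords internal
simulate_series_matrix <- function(params, tract_regions, start_date,
                                   end_date) {
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  n_days <- length(dates)
  n_tr <- length(tract_regions)
  rt <- params$region_table
  ri <- match(tract_regions, rt$region)
  if (anyNA(ri)) stopf("unknown region in tract table")
  p_enter0 <- params$p_enter_smoke * rt$enter_mult[ri]
  mu <- params$intensity_log_mean + rt$logmean_shift[ri]
  sd_ep <- params$intensity_log_sd * sqrt(params$episode_share)
  sd_day <- params$intensity_log_sd * sqrt(1 - params$episode_share)
  season <- seasonal_enter_mult(dates, params$seasonal_amplitude)

  out <- matrix(0, n_days, n_tr)
  state <- rep(FALSE, n_tr)
  episode <- numeric(n_tr)
  for (d in seq_len(n_days)) {
    p <- ifelse(state, params$p_stay_smoke, pmin(p_enter0 * season[d], 1))
    nxt <- stats::runif(n_tr) < p
    entering <- nxt & !state
    if (any(entering))
      episode[entering] <- stats::rnorm(sum(entering), 0, sd_ep)
    if (any(nxt))
      out[d, nxt] <- exp(mu[nxt] + episode[nxt] +
                           stats::rnorm(sum(nxt), 0, sd_day))
    state <- nxt
  }
  colnames(out) <- names(tract_regions)
  attr(out, "start_date") <- dates[1]
  out
}

#' Simulate one census tract's daily wildfire PM2.5 series
#'
#' Gap-free daily series: exact zeros on non-smoke days, lognormal
#' concentrations on smoke days, with smoke runs governed by the two-state
#' Markov chain of [exposure_process_params()]. Deterministic under a fixed
#' seed.
#'
#' @param params [exposure_process_params()].
#' @param tract_id tract identifier.
#' @param start_date,end_date date range (inclusive).
#' @param region census region of the tract (row of the params region
#'   table).
#' @param seed integer seed.
#' @return [daily_series()] object.
#' @export
simulate_tract_series <- function(params, tract_id, start_date, end_date,
                                  region = "West", seed = 1L) {
  set.seed(assert_scalar_count(seed, "seed", positive = FALSE))
  if (as.Date(end_date) < as.Date(start_date)) stopf("empty date range")
  m <- simulate_series_matrix(params,
                              stats::setNames(region, as.character(tract_id)),
                              start_date, end_date)
  daily_series(tract_id, start_date, m[, 1])
}

#' @keywords internal
sample_levels <- function(n, levels, probs) {
  factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
}

# Individual-level covariate draws approximating the published cohort
# marginals (demographic mix of a large nationwide US pregnancy cohort).
#' @keywords internal
draw_covariates <- function(n) {
  data.frame(
    sex = sample_levels(n, c("Male", "Female"), c(0.512, 0.488)),
    age = pmin(pmax(stats::rnorm(n, 30.6, 5.6), 14), 50),
    race = sample_levels(n, c("White", "Black", "Asian", "AIAN", "Other"),
                         c(0.669, 0.137, 0.072, 0.021, 0.101)),
    hispanic = stats::runif(n) < 0.225,
    education = sample_levels(n, c("HS or less", "Some college",
                                   "Bachelor", "Postgraduate"),
                              c(0.253, 0.223, 0.274, 0.250)),
    edu_stage = sample_levels(n, c("pregnancy", "early", "middle"),
                              c(0.73, 0.08, 0.19)),
    parity = sample_levels(n, c("0", "1", "2+"), c(0.405, 0.353, 0.242)),
    bmi = pmin(pmax(stats::rnorm(n, 26.8, 6.6), 15), 60),
    tobacco = stats::runif(n) < 0.081,
    alcohol = stats::runif(n) < 0.198,
    ga_method = sample_levels(n, c("obstetric", "ultrasound", "lmp",
                                   "neonatal", "report"),
                              c(0.45, 0.25, 0.15, 0.10, 0.05)),
    stringsAsFactors = FALSE
  )
}

#' Simulate pregnancies, covariates and residential histories
#'
#' Draws sites (assigned to census regions by the params region shares,
#' with unequal lognormal site sizes), tracts within sites (with
#' pseudo-coordinates and a tract-level neighbourhood poverty rate), and
#' pregnancies with conception dates uniform over the configured window and
#' covariates approximating a large US pregnancy cohort: mean age 30.6 y
#' (SD 5.6), 51.2% male infants, race and ethnicity mix, education, parity,
#' BMI 26.8 (6.6), tobacco 8%, alcohol 20%. A configurable fraction of
#' pregnancies has one mid-pregnancy move to another tract of the same
#' site. No outcomes are assigned here.
#'
#' @param config [cohort_config()].
#' @param params [exposure_process_params()] (supplies the region table).
#' @return list with `records` (one row per pregnancy, outcome-free),
#'   `history` (residential intervals, half-open), `tracts` and `sites`
#'   tables.
#' @export
simulate_pregnancies <- function(config, params = exposure_process_params()) {
  set.seed(config$seed)
  rt <- params$region_table
  n <- config$n_pregnancies

  site_id <- sprintf("S%02d", seq_len(config$n_sites))
  site_region <- sample(rt$region, config$n_sites, replace = TRUE,
                        prob = rt$share)
  site_w <- stats::rlnorm(config$n_sites, 0, 0.6)
  # guarantee every region keeps representation proportional to its share:
  # weight sites so regional birth totals track the region shares
  reg_w <- rt$share[match(site_region, rt$region)] /
    tapply(site_w, site_region, sum)[site_region]
  site_prob <- site_w * as.numeric(reg_w)

  tract_site <- rep(site_id, each = config$n_tracts_per_site)
  tract_id <- paste0("T_", tract_site, "_",
                     sequence(rep(config$n_tracts_per_site,
                                  config$n_sites)))
  centers <- data.frame(region = c("West", "Midwest", "Northeast", "South"),
                        lon = c(-115, -93, -75, -85),
                        lat = c(40, 42, 42, 33))
  tr_region <- site_region[match(tract_site, site_id)]
  ci <- match(tr_region, centers$region)
  tracts <- data.frame(
    tract_id = tract_id, site_id = tract_site, region = tr_region,
    lon = centers$lon[ci] + stats::rnorm(length(tract_id), 0, 3),
    lat = centers$lat[ci] + stats::rnorm(length(tract_id), 0, 2),
    poverty = pmin(pmax(stats::rgamma(length(tract_id),
                                      shape = 1.32, scale = 11.1), 0), 80),
    stringsAsFactors = FALSE
  )

  p_site <- sample(site_id, n, replace = TRUE, prob = site_prob)
  tr_by_site <- split(tracts$tract_id, tracts$site_id)
  p_tract <- vapply(p_site, function(s) sample(tr_by_site[[s]], 1L), "")

  window_days <- as.integer(config$conception_window[2] -
                              config$conception_window[1])
  conception <- config$conception_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  records <- cbind(
    data.frame(
      pregnancy_id = sprintf("P%06d", seq_len(n)),
      site_id = p_site,
      region = tracts$region[match(p_tract, tracts$tract_id)],
      tract_at_conception = p_tract,
      conception = conception,
      singleton = TRUE, live_birth = TRUE,
      stringsAsFactors = FALSE),
    draw_covariates(n))
  records$poverty <- tracts$poverty[match(p_tract, tracts$tract_id)]
  records$lon <- tracts$lon[match(p_tract, tracts$tract_id)]
  records$lat <- tracts$lat[match(p_tract, tracts$tract_id)]
  records$season <- conception_season(conception)

  # residential history: cover conception .. conception + 301 days so any
  # gestational age through 42 weeks + 6 days is linkable
  moves <- stats::runif(n) < config$move_fraction
  move_day <- ifelse(moves, sample.int(280L, n, replace = TRUE), NA_integer_)
  hist_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!moves[i]) {
      hist_rows[[i]] <- data.frame(pregnancy_id = records$pregnancy_id[i],
                                   tract_id = p_tract[i],
                                   start_date = conception[i],
                                   end_date = conception[i] + 301L)
    } else {
      alt <- setdiff(tr_by_site[[p_site[i]]], p_tract[i])
      to <- if (length(alt)) sample(alt, 1L) else p_tract[i]
      hist_rows[[i]] <- data.frame(
        pregnancy_id = records$pregnancy_id[i],
        tract_id = c(p_tract[i], to),
        start_date = c(conception[i], conception[i] + move_day[i]),
        end_date = c(conception[i] + move_day[i], conception[i] + 301L))
    }
  }
  history <- do.call(rbind, hist_rows)
  sites <- data.frame(site_id = site_id, region = site_region,
                      stringsAsFactors = FALSE)
  list(records = records, history = history, tracts = tracts, sites = sites)
}

#' @keywords internal
conception_season <- function(dates) {
  m <- as.POSIXlt(dates)$mon + 1L
  factor(c("Winter", "Spring", "Summer", "Autumn")[(m - 1L) %/% 3L + 1L],
         levels = c("Winter", "Spring", "Summer", "Autumn"))
}

# Covariate contribution to the hazard linear predictor, on centred
# covariates so the baseline refers to an average individual.
#' @keywords internal
hazard_covariate_lp <- function(records, beta) {
  lp <- numeric(nrow(records))
  add <- function(term, x) if (!is.na(beta[term])) lp <<- lp + beta[term] * x
  add("male", as.numeric(records$sex == "Male"))
  add("age_c", records$age - 30.6)
  add("race_black", as.numeric(records$race == "Black"))
  add("race_aian", as.numeric(records$race == "AIAN"))
  add("race_asian", as.numeric(records$race == "Asian"))
  add("race_other", as.numeric(records$race == "Other"))
  add("hispanic", as.numeric(records$hispanic))
  add("poverty_c", records$poverty - 14.7)
  add("tobacco", as.numeric(records$tobacco))
  add("bmi_c", records$bmi - 26.8)
  lp
}

#' Assign gestational-age outcomes from the discrete-time hazard
#'
#' Runs the weekly Bernoulli delivery trials at gestational weeks 22..36:
#' `logit(h_w) = baseline_logit[w-21] + beta_exposure * cumexp(w) +
#' covariate terms + site intercept`. The first success sets delivery in
#' that week, with the day uniform within the week; survivors draw a term
#' gestational week from the term distribution. Preterm means gestational
#' age < 259 days.
#'
#' @param records outcome-free pregnancy table from
#'   [simulate_pregnancies()].
#' @param cumexp matrix `n_pregnancies x 15` of the cumulative exposure
#'   metric at the start of weeks 22..36 (columns in week order).
#' @param hazard [hazard_params()].
#' @param seed integer seed.
#' @param offset optional per-pregnancy constant added to the weekly logit
#'   (e.g. an injected window-specific exposure effect).
#' @return `records` with added `ga_days`, `ga_week`, `preterm`,
#'   `delivery_date`, `birth_year` and the realised `site_intercept`.
#' @export
assign_outcomes <- function(records, cumexp, hazard, seed = 1L,
                            offset = NULL) {
  set.seed(assert_scalar_count(seed, "seed", positive = FALSE))
  n <- nrow(records)
  if (!is.matrix(cumexp) || nrow(cumexp) != n || ncol(cumexp) != 15L)
    stopf("`cumexp` must be an n x 15 matrix (weeks 22..36)")
  if (anyNA(cumexp)) stopf("missing cumulative exposure for an at-risk week")
  sites <- unique(records$site_id)
  b_site <- stats::setNames(stats::rnorm(length(sites), 0, hazard$sigma_site),
                            sites)
  # centre the realised intercepts over the cohort so the marginal preterm
  # rate reflects the hazard calibration, not the luck of the site draws
  if (hazard$sigma_site > 0)
    b_site <- b_site - mean(b_site[records$site_id])
  lp0 <- hazard_covariate_lp(records, hazard$beta_covariates) +
    b_site[records$site_id]
  if (!is.null(offset)) lp0 <- lp0 + offset

  ga_week <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (w in FIRST_RISK_WEEK:LAST_RISK_WEEK) {
    if (!any(alive)) break
    j <- w - FIRST_RISK_WEEK + 1L
    logit <- hazard$baseline_logit[j] +
      hazard$beta_exposure * cumexp[alive, j] + lp0[alive]
    hit <- stats::runif(sum(alive)) < expit(logit)
    idx <- which(alive)[hit]
    ga_week[idx] <- w
    alive[idx] <- FALSE
  }
  term_weeks <- as.integer(names(hazard$term_ga_distribution))
  if (any(alive))
    ga_week[alive] <- sample(term_weeks, sum(alive), replace = TRUE,
                             prob = hazard$term_ga_distribution)
  ga_days <- 7L * ga_week + sample.int(7L, n, replace = TRUE) - 1L

  records$ga_days <- ga_days
  records$ga_week <- ga_week
  records$preterm <- is_preterm(ga_days)
  records$delivery_date <- records$conception + ga_days
  records$birth_year <- as.integer(format(records$delivery_date, "%Y"))
  records$site_intercept <- as.numeric(b_site[records$site_id])
  records
}

#' Default covariate missingness specification
#'
#' MCAR masking at rates mirroring the covariate missingness of a large US
#' pregnancy cohort (race ~7%, education ~14%, parity ~14%, BMI ~12%,
#' tobacco ~12%, alcohol ~18%, poverty ~0.5%, age ~0.3%, ethnicity ~2%).
#' @export
default_missingness_spec <- function() {
  list(race = list(mech = "MCAR", rate = 0.069),
       hispanic = list(mech = "MCAR", rate = 0.021),
       education = list(mech = "MCAR", rate = 0.137),
       parity = list(mech = "MCAR", rate = 0.142),
       bmi = list(mech = "MCAR", rate = 0.122),
       tobacco = list(mech = "MCAR", rate = 0.122),
       alcohol = list(mech = "MCAR", rate = 0.184),
       poverty = list(mech = "MCAR", rate = 0.005),
       age = list(mech = "MCAR", rate = 0.003))
}

#' Inject covariate missingness
#'
#' Masks covariates according to a per-variable specification. `MCAR`
#' masks each value independently at `rate`; `MAR` masks with probability
#' `expit(a + delta * z)` where `z` is the (standardised numeric, or level
#' index of a factor) value of a fully observed conditioning variable and
#' the intercept `a` is solved so the marginal masking rate equals `rate`.
#' Outcome, exposure and identifier fields are never maskable, and a MAR
#' mechanism may only condition on a fully observed field.
#'
#' @param records pregnancy table.
#' @param spec named list; each element
#'   `list(mech = "none"|"MCAR"|"MAR", rate, condition_on, delta)`.
#' @param seed integer seed.
#' @return `records` with `NA`s injected.
#' @export
inject_missingness <- function(records, spec, seed = 1L) {
  set.seed(assert_scalar_count(seed, "seed", positive = FALSE))
  protected <- c("pregnancy_id", "site_id", "conception", "ga_days",
                 "ga_week", "preterm", "delivery_date", "tract_at_conception")
  for (v in names(spec)) {
    s <- spec[[v]]
    mech <- if (is.null(s$mech)) "MCAR" else s$mech
    if (mech == "none" || isTRUE(s$rate == 0)) next
    assert_prob(s$rate, paste0("rate for ", v))
    if (v %in% protected) stopf("refusing to mask protected field `%s`", v)
    if (!v %in% names(records)) stopf("no column `%s` to mask", v)
    n <- nrow(records)
    if (mech == "MCAR") {
      mask <- stats::runif(n) < s$rate
    } else if (mech == "MAR") {
      cv <- s$condition_on
      if (is.null(cv) || !cv %in% names(records))
        stopf("MAR for `%s` needs a valid `condition_on` field", v)
      if (cv %in% names(spec) && !identical(spec[[cv]]$mech, "none"))
        stopf("MAR for `%s` conditions on `%s`, which is itself masked", v, cv)
      zraw <- records[[cv]]
      if (anyNA(zraw))
        stopf("MAR for `%s` conditions on `%s`, which has missing values",
              v, cv)
      z <- if (is.numeric(zraw)) as.numeric(scale(zraw)) else
        as.numeric(as.factor(zraw)) - mean(as.numeric(as.factor(zraw)))
      delta <- if (is.null(s$delta)) 1 else s$delta
      a <- stats::uniroot(function(a) mean(expit(a + delta * z)) - s$rate,
                          c(-20, 20))$root
      mask <- stats::runif(n) < expit(a + delta * z)
    } else stopf("unknown missingness mechanism `%s`", mech)
    records[[v]][mask] <- NA
  }
  records
}

#' Cumulative exposure matrix for outcome assignment
#'
#' Builds the `n x 15` matrix of a cumulative metric at the start of weeks
#' 22..36 from per-pregnancy daily exposure vectors (needs at least 252
#' days each).
#'
#' @param daily named list of daily exposure vectors.
#' @param metric `"cum_days_gt0"` (cumulative smoke days > 0) or
#'   `"cum_mean"` (cumulative mean daily PM2.5).
#' @return numeric matrix, rows in `daily` order, columns weeks 22..36.
#' @export
cumulative_exposure_matrix <- function(daily, metric = "cum_days_gt0") {
  weeks <- FIRST_RISK_WEEK:LAST_RISK_WEEK
  t(vapply(daily, function(x) {
    if (length(x) < 7L * LAST_RISK_WEEK)
      stopf("daily vector shorter than %d days", 7L * LAST_RISK_WEEK)
    if (metric == "cum_days_gt0") cumsum(x > 0)[7L * weeks]
    else if (metric == "cum_mean") cumsum(x)[7L * weeks] / (7 * weeks)
    else stopf("unknown cumulative metric `%s`", metric)
  }, numeric(15L)))
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: tract series, pregnancies, residence linkage,
#' outcome assignment from the discrete-time hazard, optional missingness.
#' With all defaults this emulates the published nationwide cohort
#' marginals (n = 20 034-scale, ~8.4% preterm, mean 22.2 smoke days, mean
#' daily wildfire PM2.5 0.36 ug/m3, smoke-wave prevalences from 80.6% for
#' 2-day waves at >= 2.5 ug/m3 down to 6.0% for >= 4-day waves at >= 10
#' ug/m3).
#'
#' @param config [cohort_config()].
#' @param params [exposure_process_params()].
#' @param hazard [hazard_params()].
#' @return list with `records` (with outcomes), `history`, `tracts`,
#'   `sites`, `series` (days-by-tracts matrix), `daily` (per-pregnancy
#'   exposure vectors, conception to delivery), `cumexp` (n x 15 matrix),
#'   and the echoed `config`, `params`, `hazard`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            params = exposure_process_params(),
                            hazard = hazard_params()) {
  pop <- simulate_pregnancies(config, params)
  series <- simulate_series_matrix(
    params,
    stats::setNames(pop$tracts$region, pop$tracts$tract_id),
    config$conception_window[1],
    config$conception_window[2] + 301L)
  full <- link_cohort_series(pop$records, pop$history, series,
                             ga_days = 301L)
  cumexp <- cumulative_exposure_matrix(full, hazard$exposure_metric)
  records <- assign_outcomes(pop$records, cumexp, hazard,
                             seed = config$seed + 1L)
  daily <- full
  for (i in seq_along(daily))
    daily[[i]] <- daily[[i]][seq_len(records$ga_days[i])]
  if (!is.null(config$missingness_spec))
    records <- inject_missingness(records, config$missingness_spec,
                                  seed = config$seed + 2L)
  list(records = records, history = pop$history, tracts = pop$tracts,
       sites = pop$sites, series = series, daily = daily, cumexp = cumexp,
       config = config, params = params, hazard = hazard)
}

#' Simulate ambient temperature and ambient PM2.5 confounder series
#'
#' Seasonal sinusoid plus noise per tract: daily mean temperature (deg C)
#' and ambient all-source PM2.5 (ug/m3), for sensitivity analyses that
#' adjust for pregnancy-average values of both.
#'
#' @param tracts tract table (`tract_id`, `lat`).
#' @param start_date,end_date coverage.
#' @param seed integer seed.
#' @return list of two days-by-tracts matrices, `temperature` and
#'   `pm25_ambient`, each with a `start_date` attribute.
#' @export
simulate_confounder_series <- function(tracts, start_date, end_date,
                                       seed = 1L) {
  set.seed(assert_scalar_count(seed, "seed", positive = FALSE))
  dates <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1L
  base <- cos(2 * pi * (doy - 205) / 365.25)
  n_tr <- nrow(tracts)
  temp <- matrix(0, length(dates), n_tr)
  pm <- matrix(0, length(dates), n_tr)
  for (j in seq_len(n_tr)) {
    lvl <- 22 - 0.6 * (tracts$lat[j] - 38)
    temp[, j] <- lvl + 10 * base + stats::rnorm(length(dates), 0, 3)
    pm[, j] <- pmax(stats::rnorm(length(dates), 8 + 2 * base, 3), 0.1)
  }
  colnames(temp) <- colnames(pm) <- tracts$tract_id
  attr(temp, "start_date") <- attr(pm, "start_date") <- dates[1]
  list(temperature = temp, pm25_ambient = pm)
}

#' Lean replicate cohort for Monte-Carlo studies
#'
#' A fast known-truth testbed for parameter recovery, type-I error and
#' critical-window studies: each pregnancy gets its own independent daily
#' exposure series (no shared geography or residential mobility), the full
#' covariate draw, a site label, and an outcome from the discrete-time
#' hazard. Also returns the ready person-period expansion with the
#' hazard's cumulative exposure metric attached.
#'
#' @param n number of pregnancies.
#' @param hazard [hazard_params()].
#' @param params [exposure_process_params()].
#' @param seed integer seed.
#' @param n_sites number of site labels.
#' @param days series length in days (>= 252 so week 36 is covered).
#' @param window_effect optional `list(weeks =, beta =)`: adds
#'   `beta * (smoke days in those gestational weeks)` to every weekly
#'   logit, an exposure effect confined to a gestational window.
#' @param start_date first day of all series (conceptions coincide).
#' @return list with `records` (outcomes assigned), `daily` (days-by-n
#'   exposure matrix), `cumexp`, `window_days` (counts in
#'   `window_effect$weeks`, else `NULL`) and `pp` (person-period table
#'   carrying the exposure metric column).
#' @export
simulate_replicate_cohort <- function(n, hazard = hazard_params(),
                                      params = exposure_process_params(),
                                      seed = 1L, n_sites = 10L,
                                      days = 260L,
                                      window_effect = NULL,
                                      start_date = as.Date("2014-01-01")) {
  seed <- assert_scalar_count(seed, "seed", positive = FALSE)
  if (days < 7L * (LAST_RISK_WEEK + 1L) - 1L && days < 252L)
    stopf("`days` must cover gestational week 36 (252 days)")
  set.seed(seed)
  ids <- sprintf("P%06d", seq_len(n))
  mat <- simulate_series_matrix(params,
                                stats::setNames(rep("West", n), ids),
                                start_date, start_date + days - 1L)
  records <- cbind(
    data.frame(pregnancy_id = ids,
               site_id = sprintf("S%02d", sample.int(n_sites, n,
                                                     replace = TRUE)),
               region = "West", conception = start_date,
               singleton = TRUE, live_birth = TRUE,
               poverty = pmin(pmax(stats::rgamma(n, 1.32, scale = 11.1),
                                   0), 80),
               stringsAsFactors = FALSE),
    draw_covariates(n))
  weeks <- FIRST_RISK_WEEK:LAST_RISK_WEEK
  hit <- mat > 0
  cum_hit <- apply(hit, 2L, cumsum)
  cumexp <- if (hazard$exposure_metric == "cum_mean")
    t(apply(mat, 2L, cumsum)[7L * weeks, , drop = FALSE] / (7 * weeks))
  else t(cum_hit[7L * weeks, , drop = FALSE])
  window_days <- NULL
  offset <- NULL
  if (!is.null(window_effect)) {
    wd <- sort(unlist(lapply(window_effect$weeks,
                             function(w) 7L * w + 1:7)))
    window_days <- colSums(hit[wd, , drop = FALSE])
    offset <- window_effect$beta * window_days
  }
  records <- assign_outcomes(records, cumexp, hazard, seed = seed + 1L,
                             offset = offset)
  records$season <- conception_season(records$conception)
  metric_long <- data.frame(
    pregnancy_id = rep(ids, length(weeks)),
    week = rep(weeks, each = n),
    metric = as.vector(cumexp))
  names(metric_long)[3] <- hazard$exposure_metric
  pp <- person_period_expand(records, metric_long)$table
  list(records = records, daily = mat, cumexp = cumexp,
       window_days = window_days, pp = pp)
}
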