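# Parameter objects for the synthetic cohort generator.

#' Census-region shares and exposure scalers
#'
#' Default regional structure: share of births per US census region and
#' region-specific multipliers on the smoke-day entry probability
#' (`enter_mult`) and shifts of the lognormal log-mean intensity
#' (`logmean_shift`). Defaults are calibrated so that regional mean smoke
#' days, mean smoke days at >= 10 ug/m3, and mean daily wildfire PM2.5
#' approximate published US cohort values (Midwest: most smoke days; West:
#' most intense smoke days).
#' @export
default_region_table <- function() {
  data.frame(
    region = c("West", "Midwest", "Northeast", "South"),
    share = c(0.290, 0.178, 0.318, 0.214),
    enter_mult = c(1.00, 1.74, 0.81, 0.67),
    logmean_shift = c(0.095, -0.35, -0.08, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Exposure-process parameters
#'
#' Defines the daily wildfire PM2.5 process per census tract: a two-state
#' (smoke / no smoke) Markov chain with seasonally varying entry
#' probability, and lognormal concentrations on smoke days. Concentrations
#' within one smoke run share an episode-level random effect (fraction
#' `episode_share` of the log-scale variance), which makes consecutive-day
#' threshold exceedances (smoke waves) cluster the way multi-day fire
#' episodes do. Non-smoke days are exactly 0.
#'
#' @param p_enter_smoke daily probability of entering the smoke state from
#'   the clear state (before seasonal/regional scaling).
#' @param p_stay_smoke daily probability of remaining in the smoke state.
#' @param intensity_log_mean,intensity_log_sd lognormal parameters of
#'   smoke-day PM2.5 (ug/m3) before regional shifts.
#' @param episode_share fraction of log-scale intensity variance shared by
#'   all days of one smoke run, in `[0, 1)`.
#' @param seasonal_amplitude relative amplitude of the sinusoidal seasonal
#'   modulation of `p_enter_smoke` (peak mid-August).
#' @param region_table data.frame as [default_region_table()].
#' @return validated object of class `exposure_process_params`.
#' @export
exposure_process_params <- function(p_enter_smoke = 0.0293,
                                    p_stay_smoke = 0.660,
                                    intensity_log_mean = 1.045,
                                    intensity_log_sd = 1.00,
                                    episode_share = 0.72,
                                    seasonal_amplitude = 0.75,
                                    region_table = default_region_table()) {
  assert_prob(p_enter_smoke, "p_enter_smoke")
  assert_prob(p_stay_smoke, "p_stay_smoke")
  if (intensity_log_sd <= 0) stopf("`intensity_log_sd` must be > 0")
  if (episode_share < 0 || episode_share >= 1)
    stopf("`episode_share` must be in [0, 1)")
  if (seasonal_amplitude < 0 || seasonal_amplitude > 1)
    stopf("`seasonal_amplitude` must be in [0, 1]")
  stopifnot(all(c("region", "share", "enter_mult", "logmean_shift") %in%
                  names(region_table)))
  if (abs(sum(region_table$share) - 1) > 1e-8)
    stopf("region shares must sum to 1")
  structure(list(p_enter_smoke = p_enter_smoke, p_stay_smoke = p_stay_smoke,
                 intensity_log_mean = intensity_log_mean,
                 intensity_log_sd = intensity_log_sd,
                 episode_share = episode_share,
                 seasonal_amplitude = seasonal_amplitude,
                 region_table = region_table),
            class = "exposure_process_params")
}

#' Stationary smoke-day fraction of the exposure process
#'
#' Closed-form stationary probability of the smoke state of the two-state
#' chain, `p_enter / (p_enter + 1 - p_stay)`, at a given regional entry
#' multiplier and ignoring seasonality (whose sinusoidal modulation averages
#' out over whole years to first order).
#'
#' @param params [exposure_process_params()].
#' @param enter_mult regional multiplier on the entry probability.
#' @return stationary smoke-day fraction.
#' @export
smoke_day_fraction <- function(params, enter_mult = 1) {
  pe <- params$p_enter_smoke * enter_mult
  pe / (pe + 1 - params$p_stay_smoke)
}

#' Discrete-time hazard parameters for outcome assignment
#'
#' The data-generating analogue of the pooled logistic model: each
#' pregnancy reaching gestational week 22 undergoes weekly Bernoulli
#' delivery trials at weeks 22..36 with
#' `logit(h_w) = baseline_logit[w - 21] + beta_exposure * cumexp(w) +
#' covariate terms + site intercept`. Survivors of week 36 deliver at term
#' with a completed week drawn from `term_ga_distribution`.
#'
#' Default `baseline_logit` is piecewise-constant over the severity bands
#' (weeks 22-31, 32-33, 34-36) and calibrated, jointly with the default
#' covariate effects and exposure coefficient, to give a marginal preterm
#' fraction near 8.4% split roughly 1.0 : 0.9 : 6.4 across the bands.
#' Covariate effects are applied to centred covariates (age at 30.6 y,
#' poverty at 14.7%, BMI at 26.8) so the baseline refers to an average
#' individual.
#'
#' @param baseline_logit numeric length-15 vector of per-week baseline
#'   log-odds for weeks 22..36.
#' @param beta_exposure log-OR per unit of `exposure_metric`.
#' @param exposure_metric name of the cumulative metric column driving the
#'   hazard (default cumulative smoke days > 0).
#' @param beta_covariates named numeric vector of log-ORs over the terms
#'   `male`, `age_c` (per year), `race_black`, `race_aian`, `race_asian`,
#'   `race_other`, `hispanic`, `poverty_c` (per %), `tobacco`, `bmi_c`.
#' @param sigma_site SD of Normal site random intercepts (log-odds scale).
#' @param term_ga_distribution named probability vector over completed
#'   term weeks `"37".."42"`; must sum to 1.
#' @return validated object of class `hazard_params`.
#' @export
hazard_params <- function(baseline_logit = default_baseline_logit(),
                          beta_exposure = log(1.01),
                          exposure_metric = "cum_days_gt0",
                          beta_covariates = default_hazard_betas(),
                          sigma_site = 0.3,
                          term_ga_distribution = default_term_distribution()) {
  if (length(baseline_logit) != 15L)
    stopf("`baseline_logit` must have exactly 15 entries (weeks 22..36)")
  if (sigma_site < 0) stopf("`sigma_site` must be >= 0")
  if (abs(sum(term_ga_distribution) - 1) > 1e-8)
    stopf("`term_ga_distribution` must sum to 1")
  if (!identical(names(term_ga_distribution), as.character(37:42)))
    stopf("`term_ga_distribution` must be named '37'..'42'")
  structure(list(baseline_logit = baseline_logit,
                 beta_exposure = beta_exposure,
                 exposure_metric = exposure_metric,
                 beta_covariates = beta_covariates,
                 sigma_site = sigma_site,
                 term_ga_distribution = term_ga_distribution),
            class = "hazard_params")
}

#' @rdname hazard_params
#' @export
default_baseline_logit <- function() {
  # piecewise-constant weekly log-odds over severity bands; calibrated so
  # the default generator yields ~1.0% / 0.9% / 6.4% band incidences
  stats::qlogis(c(rep(0.00088, 10), rep(0.00310, 2), rep(0.01545, 3)))
}

#' @rdname hazard_params
#' @export
default_hazard_betas <- function() {
  c(male = 0.05, age_c = 0.010, race_black = 0.45, race_aian = 0.55,
    race_asian = 0.03, race_other = 0.05, hispanic = 0.03,
    poverty_c = 0.008, tobacco = 0.25, bmi_c = 0.012)
}

#' @rdname hazard_params
#' @export
default_term_distribution <- function() {
  stats::setNames(c(0.07, 0.17, 0.35, 0.27, 0.12, 0.02), as.character(37:42))
}

#' Cohort simulation configuration
#'
#' @param n_pregnancies number of pregnancies to simulate.
#' @param n_sites number of cohort study sites.
#' @param n_tracts_per_site census tracts per site.
#' @param conception_window length-2 Date vector of allowed conceptions;
#'   the generator additionally respects the fixed-cohort restriction
#'   implied by `exposure_end_date`.
#' @param exposure_end_date end of exposure coverage used by the inclusion
#'   rules.
#' @param seed integer seed; recorded in all outputs.
#' @param move_fraction fraction of pregnancies with one mid-pregnancy
#'   residential move (uniform over pregnancy days, to another tract of the
#'   same site).
#' @param missingness_spec optional per-covariate missingness specification
#'   (see [inject_missingness()]); `NULL` leaves data complete.
#' @return validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_pregnancies = 20000L,
                          n_sites = 30L,
                          n_tracts_per_site = 10L,
                          conception_window = as.Date(c("2006-01-01",
                                                        "2020-03-20")),
                          exposure_end_date = as.Date("2020-12-31"),
                          seed = 1L,
                          move_fraction = 0.10,
                          missingness_spec = NULL) {
  n_pregnancies <- assert_scalar_count(n_pregnancies, "n_pregnancies")
  n_sites <- assert_scalar_count(n_sites, "n_sites")
  n_tracts_per_site <- assert_scalar_count(n_tracts_per_site,
                                           "n_tracts_per_site")
  seed <- assert_scalar_count(seed, "seed", positive = FALSE)
  assert_prob(move_fraction, "move_fraction")
  conception_window <- as.Date(conception_window)
  if (conception_window[2] < conception_window[1])
    stopf("conception window is empty")
  if (conception_window[2] + 287L > as.Date(exposure_end_date) + 1L)
    stopf("conception window must end at least 41 weeks before exposure coverage ends")
  structure(list(n_pregnancies = n_pregnancies, n_sites = n_sites,
                 n_tracts_per_site = n_tracts_per_site,
                 conception_window = conception_window,
                 exposure_end_date = as.Date(exposure_end_date),
                 seed = seed, move_fraction = move_fraction,
                 missingness_spec = missingness_spec),
            class = "cohort_config")
}
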