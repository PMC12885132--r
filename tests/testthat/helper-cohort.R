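# Shared fixtures built in code. The mid-size linked cohort is built once
# per session, lazily, and reused by model and pipeline tests.

.fixture_env <- new.env(parent = emptyenv())

small_linked_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- cohort_config(
      n_pregnancies = 800L, n_sites = 8L, n_tracts_per_site = 4L,
      conception_window = as.Date(c("2012-01-01", "2012-12-31")),
      exposure_end_date = as.Date("2013-12-31"), seed = 42L)
    coh <- simulate_cohort(cfg)
    rec <- merge(coh$records, cohort_exposure_metrics(coh$daily),
                 by = "pregnancy_id", sort = FALSE)
    daily <- coh$daily[match(rec$pregnancy_id, names(coh$daily))]
    lw <- pmin(floor(rec$ga_days / 7), 36L)
    cum <- cumulative_metrics_table(daily, lw)
    pp <- person_period_expand(rec, cum)$table
    .fixture_env$small <- list(cohort = coh, records = rec, daily = daily,
                               cum = cum, pp = pp)
  }
  .fixture_env$small
}

# default-parameter nationwide cohort at the published scale; built once
calibration_cohort <- function(seed = 20060101 %% 100000L) {
  if (is.null(.fixture_env$calib)) {
    coh <- simulate_cohort(cohort_config(n_pregnancies = 20000L,
                                         seed = as.integer(seed)))
    metrics <- cohort_exposure_metrics(coh$daily)
    .fixture_env$calib <- list(cohort = coh, metrics = metrics)
  }
  .fixture_env$calib
}
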