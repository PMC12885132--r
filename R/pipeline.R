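# End-to-end pipeline orchestration and result tabulation.

#' Pipeline configuration
#'
#' Assembles (or loads from a YAML file) the configuration for
#' [run_pipeline()]. A seed is mandatory; every stochastic stage derives
#' its stream from it, so a configuration fully determines the results
#' bundle.
#'
#' @param seed integer seed (mandatory).
#' @param n_pregnancies synthetic cohort size.
#' @param exposure_terms cumulative exposure metrics to model.
#' @param covariate_set,cluster_mode passed to [model_spec()].
#' @param missingness `"none"` or `"default"` (covariate missingness at
#'   published rates, triggering multiple imputation with `m_imputations`
#'   datasets and Rubin pooling).
#' @param m_imputations number of imputed datasets when missingness is on.
#' @param week_windows fit the 36 week-specific models (threshold 0).
#' @param min_births,max_missing site-exclusion thresholds; the default
#'   `min_births = 0` keeps all synthetic sites (the generator produces no
#'   degenerate sites by design).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @param yaml_file optional YAML file whose fields override the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            n_pregnancies = 2000L,
                            exposure_terms = c("cum_mean", "cum_days_gt0",
                                               "cum_days_ge2_5",
                                               "cum_days_ge5",
                                               "cum_days_ge10"),
                            covariate_set = "model1",
                            cluster_mode = "random_intercept",
                            missingness = c("none", "default"),
                            m_imputations = 5L,
                            week_windows = FALSE,
                            min_births = 0L,
                            max_missing = 0.25,
                            output_dir = NULL,
                            yaml_file = NULL) {
  cfg <- list(seed = seed, n_pregnancies = n_pregnancies,
              exposure_terms = exposure_terms,
              covariate_set = covariate_set, cluster_mode = cluster_mode,
              missingness = match.arg(missingness),
              m_imputations = m_imputations, week_windows = week_windows,
              min_births = min_births, max_missing = max_missing,
              output_dir = output_dir)
  if (!is.null(yaml_file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml_file))
  if (is.null(cfg$seed)) stopf("pipeline config must carry a seed")
  cfg$seed <- assert_scalar_count(cfg$seed, "seed", positive = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Long cumulative-metric table for person-period expansion
#'
#' @param daily named list of per-pregnancy daily exposure vectors.
#' @param last_weeks named/same-order integer vector: last at-risk week per
#'   pregnancy (22..36).
#' @return long data.frame `pregnancy_id`, `week`, `cum_mean`,
#'   `cum_days_*`.
#' @export
cumulative_metrics_table <- function(daily, last_weeks) {
  rows <- vector("list", length(daily))
  for (i in seq_along(daily)) {
    wk <- FIRST_RISK_WEEK:last_weeks[i]
    cm <- cumulative_by_week(daily[[i]], weeks = wk)
    cm <- cbind(pregnancy_id = names(daily)[i], cm)
    rows[[i]] <- cm
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages: simulate cohort -> exposure metrics -> inclusion and site rules
#' -> person-period expansion -> (optional) multiple imputation -> pooled
#' logistic fits per exposure metric -> (optional) week-window models ->
#' gestational-age linear model -> tabulation. Each stage's output is kept
#' in the returned bundle; identical configurations yield identical
#' bundles.
#'
#' @param config [pipeline_config()].
#' @return results bundle (list) with `cohort`, `metrics`, `inclusion`,
#'   `person_period`, `fits`, `week_windows`, `ga_linear`, `tables`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("need a pipeline_config")
  ccfg <- cohort_config(
    n_pregnancies = config$n_pregnancies, seed = config$seed,
    missingness_spec = if (config$missingness == "default")
      default_missingness_spec() else NULL)
  coh <- simulate_cohort(ccfg)
  rec <- coh$records

  metrics <- cohort_exposure_metrics(coh$daily)
  rec <- merge(rec, metrics, by = "pregnancy_id", sort = FALSE)

  inc <- apply_inclusion_rules(rec, ccfg$exposure_end_date,
                               ccfg$conception_window)
  site <- apply_site_exclusions(inc$records,
                                covariates = c("age", "race", "poverty"),
                                min_births = config$min_births,
                                max_missing = config$max_missing)
  rec <- site$records

  keep <- match(rec$pregnancy_id, names(coh$daily))
  daily <- coh$daily[keep]
  last_week <- pmin(ga_completed_weeks(rec$ga_days), LAST_RISK_WEEK)
  cum_tab <- cumulative_metrics_table(daily, last_week)
  pp <- person_period_expand(rec, cum_tab)

  fit_one <- function(tab, term) {
    spec <- model_spec(exposure_term = term,
                       covariate_set = config$covariate_set,
                       cluster_mode = config$cluster_mode)
    fit_pooled_logistic(tab, spec)
  }
  fits <- list()
  if (config$missingness == "default") {
    imps <- mice_by_site(rec, spec = imputation_spec(m = config$m_imputations,
                                                     max_iter = 5L),
                         seed = config$seed + 3L)
    for (term in config$exposure_terms) {
      per_imp <- lapply(imps, function(d)
        fit_one(person_period_expand(d, cum_tab)$table, term))
      fits[[term]] <- rubin_pool(per_imp)
    }
  } else {
    for (term in config$exposure_terms)
      fits[[term]] <- fit_one(pp$table, term)
  }

  ww <- NULL
  if (isTRUE(config$week_windows)) {
    wd <- weekly_days_matrix(daily, threshold = 0)
    ww <- fit_week_window_models(
      rec, wd, model_spec(covariate_set = config$covariate_set,
                          cluster_mode = config$cluster_mode))
  }

  expo32 <- vapply(daily, function(x)
    count_smoke_days(x[seq_len(min(length(x), 224L))], 0), numeric(1))
  ga_rec <- rec
  ga_rec$days_gt0_to32wk <- expo32
  ga_spec <- model_spec(exposure_term = "days_gt0_to32wk",
                        covariate_set = config$covariate_set,
                        cluster_mode = config$cluster_mode)
  ga_fit <- fit_gestational_age_linear(ga_rec, ga_spec)

  bundle <- list(cohort = coh, records = rec, metrics = metrics,
                 inclusion = list(birth = inc$ledger, site = site$ledger),
                 person_period = pp, fits = fits, week_windows = ww,
                 ga_linear = ga_fit, config = config)
  bundle$tables <- tabulate_results(bundle)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' Tabulate pipeline results
#'
#' Produces the long OR table (one estimate per row: analysis, exposure
#' metric, OR and CI, n, events) and descriptive summaries of the cohort:
#' covariate distributions, exposure by census region, and the smoke-wave
#' prevalence matrix (monotone non-increasing in duration by
#' construction).
#'
#' @param bundle results bundle from [run_pipeline()].
#' @return list with `or_table`, `cohort_summary`, `exposure_by_region`,
#'   `wave_prevalence`.
#' @export
tabulate_results <- function(bundle) {
  rows <- lapply(names(bundle$fits), function(term) {
    f <- bundle$fits[[term]]
    ex <- coef_table(f, exposure_only = TRUE)
    data.frame(analysis = "pooled_logistic", exposure_metric = term,
               estimate = ex$estimate, se = ex$se, or = exp(ex$estimate),
               or_low = exp(ex$ci_low), or_high = exp(ex$ci_high),
               n = f$n_pregnancies, events = f$n_events,
               converged = f$converged)
  })
  ga <- coef_table(bundle$ga_linear, exposure_only = TRUE)
  rows <- c(rows, list(data.frame(
    analysis = "gestational_age_days", exposure_metric = ga$term,
    estimate = ga$estimate, se = ga$se, or = NA_real_, or_low = NA_real_,
    or_high = NA_real_, n = bundle$ga_linear$n_rows,
    events = bundle$ga_linear$n_events,
    converged = bundle$ga_linear$converged)))
  if (!is.null(bundle$week_windows)) {
    wt <- bundle$week_windows$table
    rows <- c(rows, list(data.frame(
      analysis = sprintf("week_window_%02d", wt$week),
      exposure_metric = "week_smoke_days", estimate = wt$estimate,
      se = wt$se, or = wt$or, or_low = wt$or_low, or_high = wt$or_high,
      n = wt$n, events = wt$events, converged = !wt$skipped)))
  }
  or_table <- do.call(rbind, rows)

  rec <- bundle$records
  m <- bundle$metrics[match(rec$pregnancy_id, bundle$metrics$pregnancy_id), ]
  cohort_summary <- data.frame(
    n = nrow(rec),
    preterm = sum(rec$preterm), preterm_pct = 100 * mean(rec$preterm),
    mean_age = mean(rec$age, na.rm = TRUE),
    mean_daily_pm25 = mean(m$mean_daily),
    mean_smoke_days = mean(m$days_gt0),
    mean_smoke_days_ge10 = mean(m$days_ge10),
    any_exposure_pct = 100 * mean(m$days_gt0 > 0))
  exposure_by_region <- do.call(rbind, lapply(split(m, rec$region),
    function(s) data.frame(n = nrow(s), mean_daily = mean(s$mean_daily),
                           days_gt0 = mean(s$days_gt0),
                           days_ge10 = mean(s$days_ge10))))
  exposure_by_region$region <- rownames(exposure_by_region)
  wave_prevalence <- expand.grid(threshold = c(2.5, 5, 10), duration = 2:4)
  wave_prevalence$pct <- mapply(function(t, d) {
    col <- paste0(smoke_col("waves", t), "_d", d)
    100 * mean(m[[col]] >= 1)
  }, wave_prevalence$threshold, wave_prevalence$duration)

  list(or_table = or_table, cohort_summary = cohort_summary,
       exposure_by_region = exposure_by_region,
       wave_prevalence = wave_prevalence)
}

#' @keywords internal
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$tables$or_table,
                   file.path(dir, "or_table.csv"), row.names = FALSE)
  utils::write.csv(bundle$tables$wave_prevalence,
                   file.path(dir, "wave_prevalence.csv"), row.names = FALSE)
  utils::write.csv(bundle$tables$exposure_by_region,
                   file.path(dir, "exposure_by_region.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         inclusion = bundle$inclusion,
         cohort_summary = bundle$tables$cohort_summary),
    file.path(dir, "pipeline.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  yaml::write_yaml(unclass(bundle$config)[setdiff(names(bundle$config),
                                                  "output_dir")],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
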