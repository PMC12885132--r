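# Statistical models: pooled logistic regression on person-period tables,
# week-window logistic models, gestational-age linear model, effect
# modification and the sensitivity suite.

#' Model specification
#'
#' @param exposure_term name of the exposure column (e.g. `"cum_days_gt0"`
#'   for cumulative smoke days, `"cum_mean"` for cumulative mean daily
#'   wildfire PM2.5).
#' @param covariate_set `"model1"` (primary: infant sex, age spline df 3,
#'   race, Hispanic ethnicity, neighbourhood poverty rate, season of
#'   conception, birth-year spline df 4, spatial thin-plate spline df 10),
#'   `"model2"` (extended: model 1 plus parity, prepregnancy BMI, tobacco,
#'   alcohol, gestational-age determination method, education by
#'   collection-stage interaction), or `"none"` (exposure and time terms
#'   only).
#' @param extra_covariates character vector of additional columns entered
#'   linearly (e.g. pregnancy-average temperature and ambient PM2.5).
#' @param spline_df named degrees of freedom for the age, birth-year and
#'   spatial smooths.
#' @param cluster column holding the cohort study site id.
#' @param cluster_mode `"random_intercept"` (default; adaptive
#'   Gauss-Hermite quadrature), `"random_slope"` (adds a site-level random
#'   slope on the exposure; Laplace approximation), `"fixed_effects"`
#'   (site indicator fixed effects) or `"none"`.
#' @param nAGQ quadrature nodes for the random-intercept logistic fit.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(exposure_term = "cum_days_gt0",
                       covariate_set = c("model1", "model2", "none"),
                       extra_covariates = character(),
                       spline_df = c(age = 3, birth_year = 4, spatial = 10),
                       cluster = "site_id",
                       cluster_mode = c("random_intercept", "random_slope",
                                        "fixed_effects", "none"),
                       nAGQ = 7L) {
  covariate_set <- match.arg(covariate_set)
  cluster_mode <- match.arg(cluster_mode)
  if (any(spline_df < 1)) stopf("spline dfs must be positive")
  structure(list(exposure_term = exposure_term,
                 covariate_set = covariate_set,
                 extra_covariates = extra_covariates,
                 spline_df = spline_df, cluster = cluster,
                 cluster_mode = cluster_mode, nAGQ = as.integer(nAGQ)),
            class = "model_spec")
}

# Augment `data` with spline-basis columns and return the RHS covariate
# terms for the requested covariate set. A smooth whose variable has too
# few distinct values for its df degrades to a linear term.
#' @keywords internal
build_design <- function(data, spec) {
  terms <- character()
  # generated design columns are standardised: mixed-model optimisers are
  # sensitive to wildly scaled fixed-effect columns, and rescaling basis
  # columns leaves the fitted smooth (and the exposure term) unchanged
  zscale <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x, na.rm = TRUE)) / s
  }
  add_smooth <- function(var, df, label) {
    v <- data[[var]]
    if (length(unique(v[!is.na(v)])) > df) {
      b <- spline_basis(v, df)
      cn <- paste0(label, "_ns", seq_len(ncol(b)))
      for (k in seq_len(ncol(b))) data[[cn[k]]] <<- zscale(b[, k])
      terms <<- c(terms, cn)
    } else {
      cn <- paste0(label, "_lin")
      data[[cn]] <<- zscale(as.numeric(v))
      terms <<- c(terms, cn)
    }
  }
  if (spec$covariate_set %in% c("model1", "model2")) {
    add_smooth("age", spec$spline_df[["age"]], "age")
    add_smooth("birth_year", spec$spline_df[["birth_year"]], "year")
    terms <- c(terms, "sex", "race", "hispanic", "poverty", "season")
    xy <- cbind(data$lon, data$lat)
    if (nrow(unique(xy)) > spec$spline_df[["spatial"]]) {
      b <- spline_basis(xy, spec$spline_df[["spatial"]], "thin_plate_2d")
      cn <- paste0("sp_tp", seq_len(ncol(b)))
      for (k in seq_len(ncol(b))) data[[cn[k]]] <- zscale(b[, k])
      terms <- c(terms, cn)
    }
  }
  if (spec$covariate_set == "model2")
    terms <- c(terms, "parity", "bmi", "tobacco", "alcohol", "ga_method",
               "education * edu_stage")
  terms <- c(terms, spec$extra_covariates)
  list(data = data, terms = terms)
}

#' @keywords internal
new_fit_result <- function(model, coef_tab, spec, n_rows, n_pregnancies,
                           n_events, converged, var_site = NA_real_,
                           var_slope = NA_real_, scale = "logit") {
  structure(list(coefficients = coef_tab, spec = spec,
                 n_rows = n_rows, n_pregnancies = n_pregnancies,
                 n_events = n_events, converged = converged,
                 var_site = var_site, var_slope = var_slope,
                 loglik = as.numeric(stats::logLik(model)), scale = scale),
            class = "ptb_fit")
}

#' @export
print.ptb_fit <- function(x, ...) {
  cat(sprintf("<ptb_fit> %s | %d rows, %s pregnancies, %d events | %s\n",
              x$scale, x$n_rows,
              ifelse(is.na(x$n_pregnancies), "?", x$n_pregnancies),
              x$n_events,
              if (x$converged) "converged" else "NOT CONVERGED"))
  ex <- x$coefficients[x$coefficients$role == "exposure", , drop = FALSE]
  if (nrow(ex)) print(ex, row.names = FALSE, digits = 4)
  if (!is.na(x$var_site))
    cat(sprintf("site intercept variance: %.4f\n", x$var_site))
  invisible(x)
}

#' Tidy the coefficients of a fit
#'
#' @param fit `ptb_fit` object.
#' @param exposure_only return only the exposure row(s).
#' @return data.frame of term, estimate (link scale), se, ci bounds, OR.
#' @export
coef_table <- function(fit, exposure_only = FALSE) {
  tab <- fit$coefficients
  if (exposure_only) tab <- tab[tab$role == "exposure", , drop = FALSE]
  tab
}

#' @keywords internal
make_coef_tab <- function(est, se, exposure_terms, or_scale = TRUE) {
  z <- est / se
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    ci_low = unname(est - 1.96 * se),
                    ci_high = unname(est + 1.96 * se),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    role = ifelse(names(est) %in% exposure_terms,
                                  "exposure", "covariate"),
                    row.names = NULL)
  if (or_scale) {
    tab$or <- exp(tab$estimate)
    tab$or_low <- exp(tab$ci_low)
    tab$or_high <- exp(tab$ci_high)
  }
  tab
}

#' Pooled logistic regression on a person-period table
#'
#' Discrete-time survival model for preterm birth: logistic regression of
#' the weekly event indicator on a gestational-week indicator fixed effect,
#' the time-updated cumulative exposure, the covariate set, and the cohort
#' study site handled per `cluster_mode` (random intercepts estimated by
#' adaptive Gauss-Hermite quadrature by default). The exposure coefficient
#' is the conditional log-OR of delivery per unit of cumulative exposure,
#' given survival to the start of the week.
#'
#' @param table person-period table from [person_period_expand()].
#' @param spec [model_spec()].
#' @param week_col,event_col column names of the week indicator and event.
#' @return [`ptb_fit`][coef_table] object; `converged` is `FALSE` (with a
#'   warning) if the optimiser failed or standard errors are unstable, and
#'   zero events is an error.
#' @export
fit_pooled_logistic <- function(table, spec = model_spec(),
                                week_col = "gestational_week",
                                event_col = "event") {
  if (!spec$exposure_term %in% names(table))
    stopf("exposure column `%s` not in table", spec$exposure_term)
  if (sum(table[[event_col]]) == 0L) stopf("no events in person-period table")
  des <- build_design(table, spec)
  rhs <- c(sprintf("factor(%s)", week_col), spec$exposure_term, des$terms)
  fit_logistic_engine(des$data, event_col, rhs, spec,
                      n_pregnancies = length(unique(table$pregnancy_id)))
}

# Shared engine for the logistic fits (pooled and birth-level).
#' @keywords internal
fit_logistic_engine <- function(data, ycol, rhs_terms, spec,
                                n_pregnancies = NA_integer_) {
  rhs <- paste(rhs_terms, collapse = " + ")
  n_events <- sum(data[[ycol]])
  mode <- spec$cluster_mode
  if (mode == "fixed_effects")
    rhs <- paste(rhs, sprintf("factor(%s)", spec$cluster), sep = " + ")
  if (mode %in% c("none", "fixed_effects")) {
    f <- stats::as.formula(paste(ycol, "~", rhs))
    fit <- stats::glm(f, family = stats::binomial(), data = data)
    sm <- summary(fit)$coefficients
    # sanity bound on the reported (exposure) standard errors only: a
    # zero-event week indicator drifting to -Inf is benign quasi-separation
    ex_se <- sm[rownames(sm) %in% spec$exposure_term, 2]
    conv <- isTRUE(fit$converged) && all(is.finite(sm[, 2])) &&
      all(ex_se < 1e2)
    if (!conv) warning("logistic fit did not converge cleanly; flagged")
    tab <- make_coef_tab(sm[, 1], sm[, 2], spec$exposure_term)
    res <- new_fit_result(fit, tab, spec, nrow(data), n_pregnancies,
                          n_events, conv)
    attr(res, "vcov") <- stats::vcov(fit)
    return(res)
  }
  re <- if (mode == "random_intercept")
    sprintf("(1 | %s)", spec$cluster)
  else
    sprintf("(1 + %s | %s)", spec$exposure_term, spec$cluster)
  f <- stats::as.formula(paste(ycol, "~", rhs, "+", re))
  # adaptive quadrature cannot profile out fixed effects, so it is kept for
  # lean designs and replaced by the Laplace approximation (nAGQ = 1) when
  # the fixed-effect design is wide
  p_fixed <- ncol(stats::model.matrix(
    stats::as.formula(paste("~", rhs)), data = data))
  nagq <- if (mode == "random_intercept" && p_fixed <= 10L) spec$nAGQ else 1L
  fit <- suppressMessages(
    lme4::glmer(f, family = stats::binomial(), data = data, nAGQ = nagq,
                control = lme4::glmerControl(optimizer = "nloptwrap",
                                             calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))
  sm <- summary(fit)$coefficients
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    isTRUE(fit@optinfo$conv$opt == 0) && all(is.finite(sm[, 2])) &&
    all(sm[rownames(sm) %in% spec$exposure_term, 2] < 1e2)
  if (!conv) warning("mixed logistic fit did not converge cleanly; flagged")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_site <- vc$vcov[vc$var1 == "(Intercept)" & is.na(vc$var2)][1]
  var_slope <- if (mode == "random_slope")
    vc$vcov[vc$var1 == spec$exposure_term & is.na(vc$var2)][1] else NA_real_
  tab <- make_coef_tab(sm[, 1], sm[, 2], spec$exposure_term)
  res <- new_fit_result(fit, tab, spec, nrow(data), n_pregnancies, n_events,
                        conv, var_site = var_site, var_slope = var_slope)
  attr(res, "vcov") <- as.matrix(stats::vcov(fit))
  res
}

#' Week-specific critical-window models
#'
#' One birth-level logistic model of preterm status per gestational week
#' `w` in 0..35, with the week's smoke-day count as exposure. Each model
#' includes only births whose week `w` was fully observed before delivery
#' (`ga_days > 7 * (w + 1)`), so late windows are estimated on the births
#' still at risk of contributing them. Weeks with zero exposure variance
#' are flagged and skipped, not errors.
#'
#' @param births birth-level table (one row per pregnancy, with `ga_days`,
#'   `preterm` and covariates).
#' @param weekly_days numeric matrix `n x 36` of smoke-day counts in
#'   gestational weeks 0..35 (as from [weekly_days_matrix()]).
#' @param spec [model_spec()]; its `exposure_term` is ignored in favour of
#'   the per-week count.
#' @param weeks integer subset of 0..35 to fit.
#' @return list with `fits` (per-week `ptb_fit` or `NULL` when skipped) and
#'   `table` (tidy per-week OR table).
#' @export
fit_week_window_models <- function(births, weekly_days, spec = model_spec(),
                                   weeks = 0:35) {
  if (any(weeks < 0L | weeks > 35L)) stopf("`weeks` must lie in 0..35")
  if (nrow(weekly_days) != nrow(births))
    stopf("weekly_days rows must match births")
  fits <- vector("list", length(weeks))
  names(fits) <- paste0("week", weeks)
  rows <- list()
  for (k in seq_along(weeks)) {
    w <- weeks[k]
    at_risk <- births$ga_days > 7 * (w + 1)
    x <- weekly_days[, w + 1L]
    ok <- at_risk & !is.na(x)
    if (sum(ok) < 10L || stats::var(x[ok]) == 0) {
      rows[[k]] <- data.frame(week = w, estimate = NA_real_, se = NA_real_,
                              or = NA_real_, or_low = NA_real_,
                              or_high = NA_real_, n = sum(ok),
                              events = NA_integer_, skipped = TRUE)
      next
    }
    d <- births[ok, , drop = FALSE]
    d$week_smoke_days <- x[ok]
    d$preterm_i <- as.integer(d$preterm)
    wspec <- spec
    wspec$exposure_term <- "week_smoke_days"
    des <- build_design(d, wspec)
    fit <- fit_logistic_engine(des$data, "preterm_i",
                               c("week_smoke_days", des$terms), wspec,
                               n_pregnancies = nrow(d))
    fits[[k]] <- fit
    ex <- coef_table(fit, exposure_only = TRUE)
    rows[[k]] <- data.frame(week = w, estimate = ex$estimate, se = ex$se,
                            or = ex$or, or_low = ex$or_low,
                            or_high = ex$or_high, n = fit$n_rows,
                            events = fit$n_events, skipped = FALSE)
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' Smoke days per gestational week for a cohort
#'
#' @param daily named list of per-pregnancy daily exposure vectors.
#' @param threshold smoke-day threshold (0 is strict).
#' @param weeks gestational weeks (0-based).
#' @return matrix `n x length(weeks)`; `NA` where a week is not fully
#'   covered by the pregnancy.
#' @export
weekly_days_matrix <- function(daily, threshold = 0, weeks = 0:35) {
  out <- matrix(NA_real_, length(daily), length(weeks))
  rownames(out) <- names(daily)
  for (i in seq_along(daily)) {
    x <- daily[[i]]
    full <- weeks[7 * (weeks + 1) <= length(x)]
    for (w in full)
      out[i, match(w, weeks)] <- week_specific_days(x, threshold, w)
  }
  out
}

#' Linear model for gestational age at delivery
#'
#' Mixed-effects (or plain) linear regression of gestational age in days on
#' exposure accumulated from conception to 32 weeks (a fixed window), with
#' the spec's covariates. Births delivered before 32 weeks (< 224 days) are
#' excluded so every analysed birth has the full window.
#'
#' @param births birth-level table with `ga_days` and the exposure column
#'   named by `spec$exposure_term` (exposure through day 223).
#' @param spec [model_spec()]; `cluster_mode` `"random_intercept"` uses
#'   [lme4::lmer()], anything else ordinary least squares.
#' @return `ptb_fit` with coefficients in days per exposure unit.
#' @export
fit_gestational_age_linear <- function(births, spec = model_spec()) {
  keep <- births$ga_days >= 224L
  d <- births[keep, , drop = FALSE]
  des <- build_design(d, spec)
  rhs <- paste(c(spec$exposure_term, des$terms), collapse = " + ")
  if (spec$cluster_mode %in% c("random_intercept", "random_slope")) {
    f <- stats::as.formula(paste("ga_days ~", rhs,
                                 sprintf("+ (1 | %s)", spec$cluster)))
    fit <- lme4::lmer(f, data = des$data, REML = TRUE)
    sm <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_site <- vc$vcov[vc$grp == spec$cluster][1]
    tab <- make_coef_tab(sm[, 1], sm[, 2], spec$exposure_term,
                         or_scale = FALSE)
    res <- new_fit_result(fit, tab, spec, nrow(d), nrow(d),
                          sum(is_preterm(d$ga_days)), TRUE,
                          var_site = var_site, scale = "days")
  } else {
    f <- stats::as.formula(paste("ga_days ~", rhs))
    fit <- stats::lm(f, data = des$data)
    sm <- summary(fit)$coefficients
    tab <- make_coef_tab(sm[, 1], sm[, 2], spec$exposure_term,
                         or_scale = FALSE)
    res <- new_fit_result(fit, tab, spec, nrow(d), nrow(d),
                          sum(is_preterm(d$ga_days)), TRUE, scale = "days")
  }
  res
}

#' Effect modification: stratified fits and interaction test
#'
#' Fits the pooled logistic model within each stratum of the modifier and a
#' pooled model with exposure-by-modifier interaction terms. For a binary
#' modifier the interaction p-value is the Wald p of the product term; for
#' a categorical modifier it is a multi-degree-of-freedom Wald chi-square
#' over all interaction coefficients.
#'
#' @param table person-period table.
#' @param spec [model_spec()].
#' @param modifier column name of the modifier (factor with >= 2 populated
#'   levels; e.g. infant sex, census region, race, poverty tertile).
#' @return list with `strata` (named `ptb_fit`s), `pooled` (interaction
#'   fit), `interaction_p`, `wald_chisq`, `wald_df`.
#' @export
effect_modification <- function(table, spec = model_spec(), modifier) {
  m <- droplevels(factor(table[[modifier]]))
  lv <- levels(m)
  if (length(lv) < 2L) stopf("modifier `%s` has fewer than 2 levels", modifier)
  strata <- lapply(lv, function(l)
    fit_pooled_logistic(table[which(m == l), , drop = FALSE], spec))
  names(strata) <- lv

  d <- table
  d$.mod <- m
  des <- build_design(d, spec)
  # drop the modifier's own main-effect duplicate if it is a model covariate
  terms <- des$terms[des$terms != modifier]
  ix <- sprintf("%s * .mod", spec$exposure_term)
  rhs <- c("factor(gestational_week)", ix, terms)
  pooled <- fit_logistic_engine(des$data, "event", rhs, spec,
                                n_pregnancies = length(unique(d$pregnancy_id)))
  ct <- pooled$coefficients
  int_rows <- grepl(paste0("^", spec$exposure_term, ":\\.mod"), ct$term)
  est <- ct$estimate[int_rows]
  if (length(est) == 1L) {
    p <- ct$p[int_rows]; chisq <- (est / ct$se[int_rows])^2; df <- 1L
  } else {
    V <- vcov_by_terms(pooled, ct$term[int_rows])
    chisq <- as.numeric(t(est) %*% solve(V, est))
    df <- length(est)
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  list(strata = strata, pooled = pooled, interaction_p = p,
       wald_chisq = chisq, wald_df = df)
}

# The engine does not keep the fitted object; recover the interaction
# block of the covariance matrix from the stored coefficient table when
# possible, else refit. To avoid that cost we stash vcov on the result.
#' @keywords internal
vcov_by_terms <- function(fit, terms) {
  V <- attr(fit, "vcov")
  if (is.null(V)) stopf("covariance matrix unavailable for Wald test")
  V[terms, terms, drop = FALSE]
}

#' Empirical poverty-rate tertiles
#'
#' @param poverty numeric neighbourhood poverty rates.
#' @return factor with levels `T1` (lowest) .. `T3`.
#' @export
poverty_tertiles <- function(poverty) {
  q <- stats::quantile(poverty, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  cut(poverty, c(-Inf, q, Inf), labels = c("T1", "T2", "T3"))
}

#' Sensitivity-analysis suite
#'
#' Refits the primary association under five alternative specifications:
#' 1. trimester-specific exposure (three coefficients from one birth-level
#'    logistic model) instead of the weekly cumulative metric;
#' 2. additional adjustment for pregnancy-average daily mean ambient
#'    temperature and ambient all-source PM2.5 (columns `temp_avg`,
#'    `ambient_pm_avg` in the person-period table);
#' 3. site fixed effects plus census-region adjustment instead of random
#'    intercepts;
#' 4. site random intercept plus a site-level random slope on exposure;
#' 5. complete-case analysis (rows complete in the model covariates).
#'
#' @param table person-period table (primary analysis input).
#' @param births birth-level table with `preterm` and covariates.
#' @param daily named list of per-pregnancy daily exposure vectors (for
#'   trimester metrics), same order as `births`.
#' @param spec primary [model_spec()].
#' @param variants subset of 1:5.
#' @return named list of `ptb_fit` objects keyed `"trimester"`,
#'   `"ambient_adjusted"`, `"fixed_effects"`, `"random_slope"`,
#'   `"complete_case"`.
#' @export
sensitivity_suite <- function(table, births, daily, spec = model_spec(),
                              variants = 1:5) {
  out <- list()
  if (1 %in% variants) {
    tm <- t(vapply(daily, function(x) {
      tt <- trimester_metrics(x)
      stats::setNames(tt$days_gt0, tt$trimester)
    }, numeric(3)))
    d <- births
    d$expo_T1 <- tm[, "T1"]; d$expo_T2 <- tm[, "T2"]; d$expo_T3 <- tm[, "T3"]
    d$preterm_i <- as.integer(d$preterm)
    vspec <- spec; vspec$exposure_term <- c("expo_T1", "expo_T2", "expo_T3")
    des <- build_design(d, vspec)
    out$trimester <- fit_logistic_engine(
      des$data, "preterm_i", c("expo_T1", "expo_T2", "expo_T3", des$terms),
      vspec, n_pregnancies = nrow(d))
  }
  if (2 %in% variants) {
    if (!all(c("temp_avg", "ambient_pm_avg") %in% names(table)))
      stopf("variant 2 needs `temp_avg` and `ambient_pm_avg` columns (see simulate_confounder_series)")
    vspec <- spec
    vspec$extra_covariates <- c(spec$extra_covariates, "temp_avg",
                                "ambient_pm_avg")
    out$ambient_adjusted <- fit_pooled_logistic(table, vspec)
  }
  if (3 %in% variants) {
    vspec <- spec; vspec$cluster_mode <- "fixed_effects"
    vspec$extra_covariates <- c(spec$extra_covariates,
                                if ("region" %in% names(table)) "region")
    out$fixed_effects <- fit_pooled_logistic(table, vspec)
  }
  if (4 %in% variants) {
    vspec <- spec; vspec$cluster_mode <- "random_slope"
    out$random_slope <- fit_pooled_logistic(table, vspec)
  }
  if (5 %in% variants) {
    base_vars <- c("age", "sex", "race", "hispanic", "poverty", "season",
                   "birth_year")
    model_vars <- switch(spec$covariate_set,
                         none = character(),
                         model1 = base_vars,
                         model2 = c(base_vars, "parity", "bmi", "tobacco",
                                    "alcohol", "education", "edu_stage",
                                    "ga_method"))
    model_vars <- intersect(model_vars, names(table))
    cc <- stats::complete.cases(table[, c(spec$exposure_term, model_vars),
                                      drop = FALSE])
    out$complete_case <- fit_pooled_logistic(table[cc, , drop = FALSE], spec)
  }
  out
}
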