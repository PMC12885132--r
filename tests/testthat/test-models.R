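test_that("spline bases have the right span and invariances", {
  set.seed(1)
  x <- rnorm(200)
  b <- spline_basis(x, 3)
  expect_equal(ncol(b), 3L)
  # a linear trend is exactly representable on the basis + intercept
  y <- 2 + 3 * x
  fit <- lm(y ~ b)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)

  xy <- cbind(runif(80, -120, -70), runif(80, 30, 45))
  tb <- spline_basis(xy, 10, "thin_plate_2d")
  expect_equal(ncol(tb), 10L)
  z <- sin(xy[, 1] / 10) + xy[, 2] / 5 + rnorm(80, 0, .1)
  f1 <- fitted(lm(z ~ tb))
  tb2 <- spline_basis(sweep(xy, 2, c(100, -7), "+"), 10, "thin_plate_2d")
  f2 <- fitted(lm(z ~ tb2))
  expect_lt(max(abs(f1 - f2)), 1e-8)   # translation invariance

  expect_error(spline_basis(rep(1:3, 10), 3), "distinct")
  expect_error(spline_basis(x, 0), "positive integer")
})

test_that("pooled logistic without clustering equals an independent IRLS fit", {
  # flat weekly hazard so every week carries events (no quasi-separation)
  hz <- hazard_params(baseline_logit = qlogis(rep(0.004, 15)),
                      beta_exposure = log(1.02), sigma_site = 0,
                      beta_covariates = c(male = 0))
  rc <- simulate_replicate_cohort(2000L, hz, seed = 301L)
  spec <- model_spec(covariate_set = "none", cluster_mode = "none")
  fit <- fit_pooled_logistic(rc$pp, spec)
  X <- model.matrix(~ factor(gestational_week) + cum_days_gt0, rc$pp)
  beta <- irls_logistic(X, rc$pp$event)
  expect_lt(max(abs(fit$coefficients$estimate - beta)), 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_events, sum(rc$pp$event))
  expect_equal(fit$n_pregnancies, length(unique(rc$pp$pregnancy_id)))
  # OR column is exp(estimate)
  expect_equal(fit$coefficients$or, exp(fit$coefficients$estimate),
               tolerance = 1e-12)
})

test_that("cluster modes run and zero events error out", {
  sm <- small_linked_cohort()
  spec_ri <- model_spec(covariate_set = "none",
                        cluster_mode = "random_intercept")
  fri <- fit_pooled_logistic(sm$pp, spec_ri)
  expect_true(fri$converged)
  expect_gte(fri$var_site, 0)
  spec_fe <- model_spec(covariate_set = "none", cluster_mode = "fixed_effects")
  ffe <- fit_pooled_logistic(sm$pp, spec_fe)
  # with modest clustering the two exposure estimates should be close
  d <- abs(coef_table(fri, TRUE)$estimate - coef_table(ffe, TRUE)$estimate)
  expect_lt(d, 2 * coef_table(fri, TRUE)$se)

  none <- sm$pp[sm$pp$event == 0, ]
  expect_error(fit_pooled_logistic(none, spec_ri), "no events")
  bad <- model_spec(exposure_term = "no_such_column")
  expect_error(fit_pooled_logistic(sm$pp, bad), "not in table")
})

test_that("exposure estimate is invariant to factor reference levels", {
  sm <- small_linked_cohort()
  spec <- model_spec(covariate_set = "model1", cluster_mode = "none")
  # small-sample fits may warn about fitted probabilities near 0/1
  f1 <- suppressWarnings(fit_pooled_logistic(sm$pp, spec))
  pp2 <- sm$pp
  pp2$race <- relevel(pp2$race, "Black")
  pp2$season <- relevel(pp2$season, "Summer")
  f2 <- suppressWarnings(fit_pooled_logistic(pp2, spec))
  expect_equal(coef_table(f1, TRUE)$estimate, coef_table(f2, TRUE)$estimate,
               tolerance = 1e-8)
})

test_that("week-window models respect risk sets and skip degenerate weeks", {
  sm <- small_linked_cohort()
  wd <- weekly_days_matrix(sm$daily, 0)
  spec <- model_spec(covariate_set = "none", cluster_mode = "none")
  res <- fit_week_window_models(sm$records, wd, spec, weeks = c(0, 15, 30))
  expect_equal(nrow(res$table), 3L)
  # week-30 risk set: only births observed past week 30
  expect_equal(res$table$n[res$table$week == 30],
               sum(sm$records$ga_days > 7 * 31))
  expect_error(fit_week_window_models(sm$records, wd, spec, weeks = 36),
               "0..35")
  wd0 <- wd; wd0[, 16] <- 0   # degenerate exposure in week 15
  res0 <- fit_week_window_models(sm$records, wd0, spec, weeks = 15)
  expect_true(res0$table$skipped)
  expect_true(is.na(res0$table$or))
})

test_that("gestational-age model excludes <32-week births and recovers a known slope", {
  set.seed(42)
  n <- 4000
  x <- rpois(n, 15)
  ga <- round(277 - 0.5 * x + rnorm(n, 0, 9))
  rec <- data.frame(pregnancy_id = sprintf("P%04d", 1:n),
                    site_id = sample(sprintf("S%02d", 1:8), n, TRUE),
                    ga_days = ga, days_gt0_to32wk = x)
  spec <- model_spec(exposure_term = "days_gt0_to32wk",
                     covariate_set = "none", cluster_mode = "none")
  fit <- fit_gestational_age_linear(rec, spec)
  expect_equal(fit$n_rows, sum(ga >= 224))
  ex <- coef_table(fit, TRUE)
  expect_lt(abs(ex$estimate - (-0.5)), 3 * ex$se)
  expect_equal(fit$scale, "days")
  # mixed version runs and reports a site variance
  spec_ri <- model_spec(exposure_term = "days_gt0_to32wk",
                        covariate_set = "none",
                        cluster_mode = "random_intercept")
  fit_ri <- fit_gestational_age_linear(rec, spec_ri)
  expect_false(is.na(fit_ri$var_site))
  # a 30-week birth is absent from the analysis set
  expect_false(any(rec$ga_days[rec$ga_days < 224] %in% NA))
})

test_that("effect modification reports stratified fits and Wald tests", {
  sm <- small_linked_cohort()
  spec <- model_spec(covariate_set = "none", cluster_mode = "none")
  em <- effect_modification(sm$pp, spec, "sex")
  expect_named(em$strata, c("Male", "Female"))
  expect_equal(em$wald_df, 1L)
  expect_true(em$interaction_p >= 0 && em$interaction_p <= 1)
  em4 <- effect_modification(sm$pp, spec, "region")
  expect_equal(em4$wald_df, length(unique(sm$pp$region)) - 1L)
  one <- sm$pp; one$sex <- factor("Male", levels = c("Male", "Female"))
  expect_error(effect_modification(one, spec, "sex"), "fewer than 2")
})

test_that("a strong injected interaction is detected", {
  # person-period style data generated directly from a logistic model with
  # a sex-by-exposure interaction
  set.seed(7)
  n <- 60000
  d <- data.frame(pregnancy_id = sprintf("P%05d", 1:n),
                  gestational_week = sample(22:36, n, TRUE),
                  sex = factor(sample(c("Male", "Female"), n, TRUE)),
                  cum_days_gt0 = rpois(n, 12))
  lp <- -4.2 + 0.00 * d$cum_days_gt0 +
    ifelse(d$sex == "Female", 0.08, 0) * d$cum_days_gt0
  d$event <- rbinom(n, 1, plogis(lp))
  spec <- model_spec(covariate_set = "none", cluster_mode = "none")
  em <- effect_modification(d, spec, "sex")
  expect_lt(em$interaction_p, 0.05)
  est <- vapply(em$strata, function(f) coef_table(f, TRUE)$estimate,
                numeric(1))
  expect_gt(est["Female"], est["Male"])
})

test_that("poverty tertiles split the sample into thirds", {
  set.seed(8)
  pov <- rgamma(3001, 1.3, scale = 11)
  tt <- poverty_tertiles(pov)
  expect_true(max(abs(table(tt) - 3001 / 3)) <= 1)
})

test_that("sensitivity suite variants behave as documented", {
  sm <- small_linked_cohort()
  spec <- model_spec(covariate_set = "none",
                     cluster_mode = "random_intercept")
  ss <- sensitivity_suite(sm$pp, sm$records, sm$daily, spec,
                          variants = c(1, 3, 5))
  # trimester variant returns three exposure coefficients
  expect_equal(nrow(coef_table(ss$trimester, TRUE)), 3L)
  # complete case on complete data reproduces the primary fit exactly
  primary <- fit_pooled_logistic(sm$pp, spec)
  expect_lt(max(abs(coef_table(ss$complete_case, TRUE)$estimate -
                      coef_table(primary, TRUE)$estimate)), 1e-10)
  # fixed-effects estimate close to primary under weak clustering
  d <- abs(coef_table(ss$fixed_effects, TRUE)$estimate -
             coef_table(primary, TRUE)$estimate)
  expect_lt(d, coef_table(primary, TRUE)$se)
  # variant 2 demands confounder columns
  expect_error(sensitivity_suite(sm$pp, sm$records, sm$daily, spec,
                                 variants = 2), "temp_avg")
  pp2 <- sm$pp
  pp2$temp_avg <- rnorm(nrow(pp2), 15, 5)
  pp2$ambient_pm_avg <- rnorm(nrow(pp2), 8, 2)
  ss2 <- sensitivity_suite(pp2, sm$records, sm$daily, spec, variants = 2)
  expect_true(ss2$ambient_adjusted$converged)
})

test_that("confounder series are seasonal and reproducible", {
  tr <- data.frame(tract_id = c("A", "B"), lat = c(34, 45))
  cs <- simulate_confounder_series(tr, "2015-01-01", "2016-12-31", seed = 4)
  cs2 <- simulate_confounder_series(tr, "2015-01-01", "2016-12-31", seed = 4)
  expect_identical(cs, cs2)
  jul <- as.integer(as.Date("2015-07-15") - as.Date("2015-01-01")) + 1
  jan <- 15
  expect_gt(cs$temperature[jul, "A"] - cs$temperature[jan, "A"], 5)
  expect_true(all(cs$pm25_ambient > 0))
})
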