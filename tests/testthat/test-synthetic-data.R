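test_that("exposure process parameters are validated", {
  expect_error(exposure_process_params(p_enter_smoke = 1.2), "probability")
  expect_error(exposure_process_params(intensity_log_sd = 0), "> 0")
  expect_error(exposure_process_params(episode_share = 1), "\\[0, 1\\)")
  rt <- default_region_table(); rt$share <- rt$share * 2
  expect_error(exposure_process_params(region_table = rt), "sum to 1")
})

test_that("tract series honour the smoke-state contract", {
  p0 <- exposure_process_params(p_enter_smoke = 0)
  s <- simulate_tract_series(p0, "T1", "2015-01-01", "2015-12-31", seed = 3)
  expect_true(all(s$values == 0))   # smoke state unreachable

  p <- exposure_process_params()
  a <- simulate_tract_series(p, "T1", "2015-01-01", "2016-12-31", seed = 9)
  b <- simulate_tract_series(p, "T1", "2015-01-01", "2016-12-31", seed = 9)
  expect_identical(a$values, b$values)          # determinism
  expect_true(all(a$values >= 0))
  expect_true(any(a$values == 0))               # exact zeros off smoke
})

test_that("empirical smoke-day fraction matches the stationary closed form", {
  # seasonality off so the two-state chain is homogeneous
  p <- exposure_process_params(seasonal_amplitude = 0)
  s <- simulate_tract_series(p, "T1", "2006-01-01", "2033-05-18", seed = 21)
  expect_equal(length(s$values), 10000L)
  frac <- mean(s$values > 0)
  expected <- smoke_day_fraction(p)
  # Monte-Carlo error for autocorrelated days: ~3 SE of an effective n
  expect_lt(abs(frac - expected), 0.012)
})

test_that("pregnancy records match documented covariate marginals", {
  cfg <- cohort_config(n_pregnancies = 20000L, seed = 31L,
                       move_fraction = 0)
  pop <- simulate_pregnancies(cfg)
  expect_equal(nrow(pop$records), 20000L)
  # no moves: exactly one residential interval each
  expect_equal(nrow(pop$history), 20000L)
  expect_lt(abs(mean(pop$records$age) - 30.6), 0.2)
  expect_lt(abs(mean(pop$records$sex == "Male") - 0.512), 0.02)
  win <- cfg$conception_window
  expect_true(all(pop$records$conception >= win[1] &
                    pop$records$conception <= win[2]))
  # every history covers the whole potential pregnancy
  expect_true(all(as.Date(pop$history$end_date) -
                    as.Date(pop$history$start_date) > 0))
  expect_error(cohort_config(n_pregnancies = 0), "positive")
})

test_that("covariate samplers agree with independent marginal samplers", {
  cfg <- cohort_config(n_pregnancies = 50000L, seed = 13L)
  pop <- simulate_pregnancies(cfg)
  set.seed(99)
  age_oracle <- pmin(pmax(rnorm(50000, 30.6, 5.6), 14), 50)
  expect_gt(suppressWarnings(ks.test(pop$records$age, age_oracle))$p.value,
            0.01)
  bmi_oracle <- pmin(pmax(rnorm(50000, 26.8, 6.6), 15), 60)
  expect_gt(suppressWarnings(ks.test(pop$records$bmi, bmi_oracle))$p.value,
            0.01)
  race_oracle <- sample(c("White", "Black", "Asian", "AIAN", "Other"),
                        50000, TRUE, c(0.669, 0.137, 0.072, 0.021, 0.101))
  expect_gt(chisq.test(rbind(table(pop$records$race),
                             table(factor(race_oracle,
                                          levels(pop$records$race)))))$p.value,
            0.01)
})

test_that("outcome assignment follows the weekly hazard contract", {
  set.seed(5)
  n <- 3000L
  rec <- cbind(data.frame(pregnancy_id = sprintf("P%04d", 1:n),
                          site_id = "S01", conception = as.Date("2015-01-01"),
                          poverty = 14.7, stringsAsFactors = FALSE),
               smokeptb:::draw_covariates(n))
  cum0 <- matrix(0, n, 15)

  # hazard zero: no preterm births at all
  hz0 <- hazard_params(baseline_logit = rep(-Inf, 15), sigma_site = 0)
  out0 <- assign_outcomes(rec, cum0, hz0, seed = 2)
  expect_equal(sum(out0$preterm), 0L)
  expect_true(all(out0$ga_days >= 259))
  expect_gt(min(table(out0$ga_week)), 0)

  # closed form: marginal preterm = 1 - prod_w (1 - h_w) under the null
  hz <- hazard_params(beta_exposure = 0, sigma_site = 0,
                      beta_covariates = c(male = 0))
  out <- assign_outcomes(rec, cum0, hz, seed = 3)
  expected <- 1 - prod(1 - plogis(hz$baseline_logit))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(out$preterm) - expected), 3.5 * se)

  # preterm gestational ages fall in the at-risk weeks, term in 37..42
  expect_true(all(out$ga_week[out$preterm] %in% 22:36))
  expect_true(all(out$ga_week[!out$preterm] %in% 37:42))
  expect_true(all(out$ga_days >= 7 * out$ga_week &
                    out$ga_days <= 7 * out$ga_week + 6))
  expect_error(assign_outcomes(rec, cum0[, 1:10], hz), "n x 15")
})

test_that("a positive exposure effect raises risk in the top quartile", {
  hz <- hazard_params(beta_exposure = log(1.04), sigma_site = 0,
                      beta_covariates = c(male = 0))
  rc <- simulate_replicate_cohort(8000L, hz, seed = 17L)
  tot <- rc$cumexp[, 15]
  q <- quantile(tot, c(.25, .75))
  expect_gt(mean(rc$records$preterm[tot >= q[2]]),
            mean(rc$records$preterm[tot <= q[1]]))
})

test_that("missingness injection matches its specification", {
  cfg <- cohort_config(n_pregnancies = 5000L, seed = 23L)
  pop <- simulate_pregnancies(cfg)
  rec <- pop$records

  same <- inject_missingness(rec, list(bmi = list(mech = "none")), seed = 1)
  expect_identical(same, rec)

  mcar <- inject_missingness(rec, list(bmi = list(mech = "MCAR", rate = .2)),
                             seed = 1)
  p <- mean(is.na(mcar$bmi))
  expect_lt(abs(p - 0.2), 3 * sqrt(.2 * .8 / 5000))
  expect_identical(mcar$age, rec$age)   # untouched columns intact

  mar <- inject_missingness(
    rec, list(tobacco = list(mech = "MAR", rate = .2,
                             condition_on = "education", delta = 1)),
    seed = 2)
  rates <- tapply(is.na(mar$tobacco), rec$education, mean)
  expect_lt(abs(mean(is.na(mar$tobacco)) - 0.2), 0.02)
  expect_true(all(diff(rates) > 0))   # masking increases along the levels

  expect_error(inject_missingness(
    rec, list(tobacco = list(mech = "MAR", rate = .2,
                             condition_on = "bmi", delta = 1),
              bmi = list(mech = "MCAR", rate = .1)), seed = 3),
    "itself masked")
  expect_error(inject_missingness(
    rec, list(preterm = list(mech = "MCAR", rate = .1)), seed = 3),
    "protected")
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_pregnancies = 300L, n_sites = 5L,
                       n_tracts_per_site = 3L,
                       conception_window = as.Date(c("2012-01-01",
                                                     "2012-06-30")),
                       exposure_end_date = as.Date("2013-06-30"), seed = 77L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$daily, b$daily)
  expect_identical(a$history, b$history)
})

test_that("a null exposure-outcome linkage yields uniform p-values", {
  hz <- hazard_params(beta_exposure = 0, sigma_site = 0,
                      beta_covariates = c(male = 0))
  pvals <- vapply(1:60, function(r) {
    rc <- simulate_replicate_cohort(600L, hz, seed = 4000L + r)
    tot <- rc$cumexp[, 15]
    f <- glm(rc$records$preterm ~ tot, family = binomial())
    summary(f)$coefficients["tot", 4]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("preterm severity bands split approximately 1.0 : 0.9 : 6.4", {
  cal <- calibration_cohort()
  rec <- cal$cohort$records
  w <- rec$ga_week[rec$preterm]
  frac <- c(mean(rec$preterm & rec$ga_week <= 31),
            mean(rec$preterm & rec$ga_week %in% 32:33),
            mean(rec$preterm & rec$ga_week %in% 34:36))
  target <- c(0.010, 0.009, 0.064)
  expect_true(all(abs(frac / target - 1) < 0.30))
})
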