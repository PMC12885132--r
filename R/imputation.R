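# Site-specific multiple imputation by chained equations, and Rubin
# pooling of repeated model fits.

#' Imputation specification
#'
#' @param m number of imputed datasets (>= 2 for pooling).
#' @param max_iter chained-equation sweeps per imputation.
#' @param by_site run the chained equations independently within each
#'   cohort study site; sites with fewer than `min_site_n` records fall
#'   back to pooled-sample imputation with a site indicator (with a
#'   warning).
#' @param min_site_n minimum records for a stable within-site model.
#' @param pmm_donors donor-pool size for predictive mean matching.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 10L, max_iter = 10L, by_site = TRUE,
                            min_site_n = 50L, pmm_donors = 5L) {
  structure(list(m = assert_scalar_count(m, "m"),
                 max_iter = assert_scalar_count(max_iter, "max_iter"),
                 by_site = isTRUE(by_site),
                 min_site_n = assert_scalar_count(min_site_n, "min_site_n"),
                 pmm_donors = assert_scalar_count(pmm_donors, "pmm_donors")),
            class = "imputation_spec")
}

#' @keywords internal
impute_init <- function(x) {
  miss <- is.na(x)
  x[miss] <- sample(x[!miss], sum(miss), replace = TRUE)
  x
}

# One chained-equation pass over the incomplete variables of `d`.
# Continuous -> predictive mean matching on a linear fit; logical/binary ->
# logistic draw; factor -> multinomial draw (nnet). Predictors: all other
# variables in `vars` plus `extra` (exposure summary, outcome), which
# follows standard congeniality practice.
#' @keywords internal
impute_sweep <- function(d, miss, vars, extra, donors) {
  for (v in vars) {
    mi <- miss[[v]]
    if (!any(mi)) next
    preds <- setdiff(c(vars, extra), v)
    rhs <- paste(preds, collapse = " + ")
    f <- stats::as.formula(paste(v, "~", rhs))
    obs <- d[!mi, , drop = FALSE]
    misdat <- d[mi, , drop = FALSE]
    y <- d[[v]]
    if (is.numeric(y)) {
      fit <- stats::lm(f, data = obs)
      yhat_obs <- stats::predict(fit, obs)
      yhat_mis <- stats::predict(fit, misdat)
      # PMM: draw from the `donors` observed values closest in prediction
      d[[v]][mi] <- vapply(yhat_mis, function(p) {
        k <- order(abs(yhat_obs - p))[seq_len(min(donors, length(yhat_obs)))]
        sample(obs[[v]][k], 1L)
      }, numeric(1))
    } else if (is.logical(y)) {
      fit <- suppressWarnings(stats::glm(f, stats::binomial(), data = obs))
      p <- stats::predict(fit, misdat, type = "response")
      d[[v]][mi] <- stats::runif(sum(mi)) < p
    } else {
      fit <- suppressWarnings(
        nnet::multinom(f, data = obs, trace = FALSE, maxit = 200))
      p <- stats::predict(fit, misdat, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p, deparse.level = 0)
      lv <- fit$lev
      pick <- apply(p, 1L, function(pr) sample(lv, 1L, prob = pr))
      d[[v]][mi] <- factor(pick, levels = levels(y))
    }
  }
  d
}

#' Site-specific multiple imputation by chained equations
#'
#' Fills missing covariates with `m` completed datasets. Within each site
#' (or in the pooled sample with a site indicator, for sites below the
#' stability threshold) incomplete variables are initialised by random
#' draws from their observed values and updated by `max_iter` chained
#' sweeps. Observed cells are never modified; exposure and outcome are
#' used as predictors but never imputed.
#'
#' @param records data.frame with missing covariate cells.
#' @param vars character vector of covariate columns eligible for
#'   imputation (defaults to every incomplete covariate among the analysis
#'   covariates).
#' @param spec [imputation_spec()].
#' @param seed integer seed.
#' @param extra_predictors fully observed columns used as predictors only
#'   (defaults to smoke-day total and preterm status when present).
#' @return list of `m` completed data.frames, with a `manifest` attribute
#'   recording `m`, `seed`, methods and sweep count.
#' @export
mice_by_site <- function(records, vars = NULL, spec = imputation_spec(),
                         seed = 1L, extra_predictors = NULL) {
  set.seed(assert_scalar_count(seed, "seed", positive = FALSE))
  cand <- c("age", "race", "hispanic", "education", "parity", "bmi",
            "tobacco", "alcohol", "poverty")
  if (is.null(vars))
    vars <- names(which(vapply(intersect(cand, names(records)),
                               function(v) anyNA(records[[v]]), logical(1))))
  if (is.null(extra_predictors))
    extra_predictors <- intersect(c("days_gt0", "preterm"), names(records))
  for (v in extra_predictors) if (anyNA(records[[v]]))
    stopf("predictor `%s` must be fully observed", v)
  if (!length(vars)) return(replicate(spec$m, records, simplify = FALSE))

  site <- as.character(records$site_id)
  tab <- table(site)
  small <- names(tab)[tab < spec$min_site_n]
  if (spec$by_site && length(small))
    warning(sprintf("sites below %d records imputed in the pooled sample: %s",
                    spec$min_site_n, paste(small, collapse = ", ")))
  groups <- if (spec$by_site) ifelse(site %in% small, ".pooled", site)
  else rep(".pooled", nrow(records))
  for (g in unique(groups)) for (v in vars) {
    idx <- groups == g
    if (all(is.na(records[[v]][idx])))
      stopf("variable `%s` is entirely missing within site %s", v, g)
  }

  miss <- lapply(records[vars], is.na)
  use_site_ind <- "site_id" %in% names(records) &&
    length(unique(records$site_id)) > 1L
  out <- vector("list", spec$m)
  for (imp in seq_len(spec$m)) {
    d <- records
    for (v in vars) d[[v]] <- impute_init(d[[v]])
    for (it in seq_len(spec$max_iter)) {
      for (g in unique(groups)) {
        idx <- which(groups == g)
        extra <- extra_predictors
        if (g == ".pooled" && use_site_ind) extra <- c(extra, "site_id")
        sub <- d[idx, , drop = FALSE]
        submiss <- lapply(miss, `[`, idx)
        sub <- impute_sweep(sub, submiss, vars, extra, spec$pmm_donors)
        d[idx, vars] <- sub[, vars]
      }
    }
    out[[imp]] <- d
  }
  attr(out, "manifest") <- list(m = spec$m, seed = seed, vars = vars,
                                max_iter = spec$max_iter,
                                by_site = spec$by_site,
                                methods = vapply(records[vars], function(x)
                                  if (is.numeric(x)) "pmm"
                                  else if (is.logical(x)) "logistic"
                                  else "multinomial", character(1)))
  out
}

#' Pool fits across imputed datasets by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance; degrees of freedom follow the standard
#' small-sample formula `(m - 1) (1 + W / ((1 + 1/m) B))^2`, and CIs use
#' the t distribution.
#'
#' @param fits list of `ptb_fit` objects from identical specifications on
#'   the `m` imputed datasets.
#' @return `ptb_fit`-like pooled result with columns `estimate`, `se`,
#'   `ci_low`, `ci_high`, `df`, `between_var`, `within_var`.
#' @export
rubin_pool <- function(fits) {
  m <- length(fits)
  if (m < 1L) stopf("no fits to pool")
  terms <- fits[[1]]$coefficients$term
  for (f in fits)
    if (!identical(f$coefficients$term, terms))
      stopf("coefficient names differ across imputations")
  k <- length(terms)
  est <- matrix(vapply(fits, function(f) f$coefficients$estimate,
                       numeric(k)), nrow = k)
  ses <- matrix(vapply(fits, function(f) f$coefficients$se,
                       numeric(k)), nrow = k)
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1L) apply(est, 1L, stats::var) else rep(0, length(qbar))
  Tvar <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tcrit <- stats::qt(0.975, df)
  roles <- fits[[1]]$coefficients$role
  tab <- data.frame(term = terms, estimate = qbar, se = sqrt(Tvar),
                    ci_low = qbar - tcrit * sqrt(Tvar),
                    ci_high = qbar + tcrit * sqrt(Tvar),
                    p = 2 * stats::pt(-abs(qbar / sqrt(Tvar)), df),
                    role = roles, df = df, within_var = W, between_var = B,
                    row.names = NULL)
  if (fits[[1]]$scale == "logit") {
    tab$or <- exp(tab$estimate)
    tab$or_low <- exp(tab$ci_low)
    tab$or_high <- exp(tab$ci_high)
  }
  structure(list(coefficients = tab, spec = fits[[1]]$spec, m = m,
                 n_rows = fits[[1]]$n_rows,
                 n_pregnancies = fits[[1]]$n_pregnancies,
                 n_events = fits[[1]]$n_events,
                 converged = all(vapply(fits, `[[`, logical(1), "converged")),
                 var_site = mean(vapply(fits, `[[`, numeric(1), "var_site")),
                 var_slope = NA_real_, loglik = NA_real_,
                 scale = fits[[1]]$scale),
            class = "ptb_fit")
}
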