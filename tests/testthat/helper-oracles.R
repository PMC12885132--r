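# Independent oracles: deliberately naive implementations used only to
# check the package's counting and fitting routines.

# day-by-day loop over the vector
brute_smoke_days <- function(x, threshold, strict = (threshold == 0)) {
  n <- 0L
  for (v in x) {
    hit <- if (strict) v > threshold else v >= threshold
    if (hit) n <- n + 1L
  }
  n
}

# enumerate maximal runs explicitly, then count those long enough
brute_smoke_waves <- function(x, threshold, min_duration,
                              strict = (threshold == 0)) {
  if (length(x) == 0L) return(0L)
  hit <- if (strict) x > threshold else x >= threshold
  runs <- integer(0)
  cur <- 0L
  for (h in hit) {
    if (h) cur <- cur + 1L
    else { if (cur > 0L) runs <- c(runs, cur); cur <- 0L }
  }
  if (cur > 0L) runs <- c(runs, cur)
  sum(runs >= min_duration)
}

# plain IRLS for logistic regression, no shortcuts shared with glm
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    new <- fit$coefficients
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  beta
}

# zero-inflated random daily vectors for oracle-equivalence checks
random_daily_vector <- function(len = NULL) {
  if (is.null(len)) len <- sample(1:60, 1)
  v <- numeric(len)
  smoke <- runif(len) < 0.3
  v[smoke] <- round(rlnorm(sum(smoke), 1, 1), 2)
  # inject exact-threshold values so >= vs > is exercised
  k <- runif(len) < 0.1
  v[k] <- sample(c(2.5, 5, 10), sum(k), replace = TRUE)
  v
}
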