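# Independent oracles: loop/moment-based re-computations and numerical
# integration, deliberately written without reusing any package internals.

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2
    sy2 <- sy2 + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  sx2 <- sx2 / n; sy2 <- sy2 / n; sxy <- sxy / n
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  list(ccc = ccc, r = r, cb = ccc / r)
}

oracle_me_rmse <- function(pred, ref) {
  n <- length(pred)
  s <- 0; s2 <- 0
  for (i in seq_len(n)) {
    d <- pred[i] - ref[i]
    s <- s + d
    s2 <- s2 + d^2
  }
  list(me = s / n, rmse = sqrt(s2 / n))
}

# truncated-normal mean by numerical integration
oracle_truncnorm_mean <- function(mean, sd, lower, upper) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lower,
                        upper)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lower,
                   upper)$value / z
}

# OLS by explicit normal equations (no lm)
oracle_ols <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  res <- y - X1 %*% beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X)
  r2 <- 1 - sse / sst
  list(beta = drop(beta), sse = sse, r2 = 100 * r2,
       adjusted_r2 = 100 * (1 - (1 - r2) * (n - 1) / (n - p - 1)),
       see = sqrt(sse / (n - p - 1)))
}

# Exhaustive subset ranking via bitmask enumeration (independent of combn)
oracle_best_subsets <- function(y, X, size) {
  k <- ncol(X)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(idx) != size) next
    fit <- oracle_ols(y, X[, idx, drop = FALSE])
    out[[length(out) + 1L]] <- list(
      predictors = sort(names(X)[idx]),
      adjusted_r2 = fit$adjusted_r2, see = fit$see
    )
  }
  keys <- vapply(out, function(f) paste(f$predictors, collapse = ","), "")
  adj <- vapply(out, `[[`, 0, "adjusted_r2")
  out[order(-adj, keys)]
}

random_subjects <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("R%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 20, 85),
    weight = runif(n, 45, 120),
    bmi = runif(n, 18, 38),
    ck = runif(n, 30, 300),
    hscrp = runif(n, 0.2, 8),
    ldh = runif(n, 100, 300),
    stringsAsFactors = FALSE
  )
}
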