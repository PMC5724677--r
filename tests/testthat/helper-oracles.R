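# Independent oracles, deliberately naive.

# OLS through the normal equations, with slope t-test.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  list(
    slope = slope, intercept = intercept,
    r_squared = sxy^2 / (sxx * syy),
    p_value = 2 * stats::pt(-abs(tval), df = n - 2),
    se = se
  )
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to group A (no ties assumed).
mann_whitney_enum <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(length(pooled), n_a)
  u_all <- apply(sets, 2, function(idx) {
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2
  })
  mu <- n_a * length(b) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = min(1, p))
}
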