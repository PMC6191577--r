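# Independent scalar oracles used across the suite.

# Scalar hexcone RGB -> HSB bytes, coded with explicit branches (the
# package's vectorized core uses mask arithmetic instead).
oracle_hsb <- function(r, g, b) {
  mx <- max(r, g, b)
  mn <- min(r, g, b)
  d <- mx - mn
  h6 <- 0
  if (d > 0) {
    if (mx == r) h6 <- (g - b) / d
    else if (mx == g) h6 <- (b - r) / d + 2
    else h6 <- (r - g) / d + 4
    if (h6 < 0) h6 <- h6 + 6
  }
  s <- if (mx > 0) round(d / mx * 255) else 0
  c(round(h6 * 42.5), s, mx)
}

# Closed-form simple linear regression: slope, intercept, R2 and the
# two-sided slope p-value from the t distribution with n - 2 df.
oracle_linreg <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, r2 = 1 - sse / sst,
       p = 2 * stats::pt(-abs(tval), n - 2))
}

# A small scenario for unit tests (study-condition trait targets, fewer
# plots so the suite stays quick).
test_scenario <- function(seed = 1, n_plots = 12, ...) {
  scenario_2014(seed = seed, n_plots = n_plots, ...)
}

# Reference NDVI-style two-band index straight from the definition.
raw_ndsi <- function(ra, rb) (ra - rb) / (ra + rb)

# Seeded Gaussian noise for planted-signal fixtures.
with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed + 500000L)
  stats::rnorm(n, sd = sd)
}
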