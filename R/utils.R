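# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# write.csv with numeric columns rendered at 17 significant digits so that
# reading the file back reproduces every double bit-exactly (analyze mode on
# simulate outputs must regenerate identical downstream tables).
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Truncated-normal sampling by inverse CDF, and the truncated mean used for
# moment matching.  Kept in-package: a handful of lines against qnorm/pnorm.
qtruncnorm <- function(p, mean, sd, lower, upper) {
  if (sd <= 0 || lower >= upper) return(rep((lower + upper) / 2, length(p)))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + p * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Solve for the untruncated mu such that the [lower, upper]-truncated normal
# with sd = (upper - lower)/4 has the requested mean (moment matching to a
# min/mean/max summary).
truncnorm_match <- function(lower, mean_target, upper) {
  sd <- (upper - lower) / 4
  if (sd == 0) return(list(mean = lower, sd = 0))
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - mean_target
  mu <- stats::uniroot(f, c(lower - 6 * sd, upper + 6 * sd), tol = 1e-10)$root
  list(mean = mu, sd = sd)
}
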