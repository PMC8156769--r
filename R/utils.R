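# Internal helpers shared across modules.

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards. Keeps all generator randomness
# behind one explicit, named seed with no global side effects.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

# Periodic Gaussian bump on cycle phase u in [0, 1): unit height at centre
# `c`, width `w` (fraction of the cycle), wrapped at the cycle boundary.
phase_bump <- function(u, c, w) {
  d <- abs(u - c)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / w)^2)
}

# Normal draw truncated to [lower, upper] by resampling.
rnorm_range <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

# Normal draw truncated below (resampled), vectorised over n.
rnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

# Sample skewness m3/m2^(3/2) and excess kurtosis m4/m2^2 - 3, both defined
# as 0 for (near-)zero-variance input so degenerate cycles propagate zeros
# rather than NaN.
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^4) / m2^2 - 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
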