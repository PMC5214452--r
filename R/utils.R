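# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Draws from N(mu, sd) truncated to (0, Inf): non-positive draws are
# redrawn.  Degenerate sd = 0 returns mu (which must be positive).
rtruncnorm0 <- function(n, mu, sd) {
  if (sd == 0) {
    stopifnot(mu > 0)
    return(rep(mu, n))
  }
  x <- rnorm(n, mu, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mu, sd)
  x
}

# P(X >= t | X > 0) for X ~ N(mu, sd) truncated to (0, Inf).
truncnormTail <- function(t, mu, sd) {
  if (sd == 0) return(as.numeric(t <= mu))
  denom <- pnorm(mu / sd)
  ifelse(t <= 0, 1, pnorm((t - mu) / sd, lower.tail = FALSE) / denom)
}
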