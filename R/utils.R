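# Internal helpers.

# Seed the RNG for a deterministic draw path. A NULL seed leaves the RNG
# stream untouched so callers can manage randomness themselves.
local_rng <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587)
}

# Multivariate normal draw via Cholesky; sigma must be positive definite.
rmvnorm_chol <- function(n, sigma) {
  p <- nrow(sigma)
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance matrix is not positive definite"))
  matrix(stats::rnorm(n * p), n, p) %*% ch
}

softmax2 <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate fn() under a private RNG stream, restoring the caller's stream
# afterwards (used by constructors that draw fixed quantities, so that lazy
# evaluation can never disturb a caller's seeded draw path).
isolated_rng <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
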