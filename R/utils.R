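# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the session stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Log-density of n bivariate-normal observations with common mean vector
# (mu1, mu2), variances (v1, v2) and correlation rho; x1, x2 are vectors.
# Returns the summed log-likelihood, or -Inf if the covariance is not PD.
bvn_loglik <- function(x1, x2, mu1, mu2, v1, v2, rho) {
  n <- length(x1)
  if (n == 0L) return(0)
  if (v1 <= 0 || v2 <= 0 || abs(rho) >= 1) return(-Inf)
  c12 <- rho * sqrt(v1 * v2)
  det <- v1 * v2 - c12^2
  d1 <- x1 - mu1
  d2 <- x2 - mu2
  quad <- (d1^2 * v2 - 2 * d1 * d2 * c12 + d2^2 * v1) / det
  -n * log(2 * pi) - n / 2 * log(det) - sum(quad) / 2
}

# Summed univariate normal log-density for singleton observations.
uvn_loglik <- function(x, mu, v) {
  if (length(x) == 0L) return(0)
  if (v <= 0) return(-Inf)
  sum(dnorm(x, mu, sqrt(v), log = TRUE))
}

# Deterministic multiplicative jitter factors used for optimizer restarts,
# so refits are reproducible without touching the RNG.
restart_factors <- function(k) {
  base <- c(0.5, 1.6, 0.75, 1.25, 0.4, 2.0, 0.9, 1.1)
  base[((seq_len(k) - 1L) %% length(base)) + 1L]
}
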