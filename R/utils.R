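# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library functions never clobber a user's random stream.
with_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Exact truncated-normal draws by inverse-CDF; adequate for calendar-scale
# quantities (cycle and bleed lengths) where tails are mild.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Moment-matched lognormal parameters: E[X] = mean, SD[X] = sd.
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sigma2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}
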