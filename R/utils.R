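# Shared internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic entry points in the
# package route their randomness through this so that a dataset is
# bit-reproducible for a fixed seed without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated-normal draws by rejection; truncation at `lower` (exclusive).
# Jitter sds are <= 20 % of the mean so the acceptance probability is ~1
# and the loop terminates immediately in practice.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection failed; sd too large relative to mean")
  }
  out
}

# Percentile by inverse empirical CDF (type 1): the smallest observed value
# with at least p% of the sample at or below it.  Used for the lightning
# threshold so the rule matches an exhaustive sort exactly.
percentile_type1 <- function(x, p) {
  stopifnot(p > 0, p < 100)
  xs <- sort(x)
  xs[ceiling(p / 100 * length(xs))]
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
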