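#' @keywords internal
"_PACKAGE"

# Deterministic seed substreams.
#
# A single master seed spawns independent substreams keyed by (stream, index)
# so that, e.g., patient i's covariate draws do not change when the cohort
# grows, and ensemble iteration k's subsample does not change when n_iter
# grows. Multiplier kept small so products stay exactly representable in
# doubles (< 2^53).
derive_seed <- function(master, stream, index = 0L) {
  m <- as.double(master) %% 2147483563
  s <- (m * 69069 + as.double(stream)) %% 2147483563
  s <- (s * 69069 + as.double(index)) %% 2147483563
  as.integer(s) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Lognormal parameterized by arithmetic mean m and coefficient of variation.
rlnorm_meancv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
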