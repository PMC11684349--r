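# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package internals never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed derivation for per-round / per-client substreams.
# Mixes (seed, stream, substream) through two rounds of multiplicative
# hashing modulo the Mersenne prime 2^31 - 1, keeping the result a valid
# 32-bit integer seed. All arithmetic stays below 2^53 so it is exact in
# doubles.
derive_seed <- function(seed, stream, substream = 0L) {
  m <- 2147483647
  x <- as.double(seed) %% m
  x <- (x * 48271 + as.double(stream) * 8191 +
          as.double(substream) * 524287 + 11) %% m
  x <- (x * 16807 + 43) %% m
  as.integer(x) + 1L
}

# Stop with a classed condition so callers/tests can match on error class.
stop_fs <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fedstress_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Full-precision number formatting used by the plain-text writers; %.17g
# round-trips IEEE doubles exactly.
format_full <- function(x) sprintf("%.17g", x)

# Majority state of a window of 0/1 labels; ties resolve to stress (1).
majority_label <- function(states) {
  if (length(states) == 0L) stop_fs("invalid_argument", "empty state window")
  as.integer(mean(states) >= 0.5)
}
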