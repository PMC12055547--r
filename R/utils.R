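# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rgamma median fft sd var pt pnorm complete.cases
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation. Mixes a base seed with stream labels so
# that e.g. each (round, node) pair gets an independent, reproducible RNG
# stream. Kept below 2^31 - 1 so it is a valid R integer seed.
mixSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 2654435761 + (p %% 1000003) + 97) %% 2147483629
  }
  as.integer(h + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Attach/retrieve degeneracy flags without polluting the numeric payload.
setFlags <- function(x, flags) {
  attr(x, "flags") <- flags
  x
}

#' Retrieve degeneracy flags attached to a result
#'
#' Several operators (zero-signal spectra, zero-denominator ratios, clamped
#' probabilities, degenerate significance tests) return valid numeric output
#' while recording what was degenerate. The flags are carried as an attribute
#' and read with this accessor.
#'
#' @param x an object returned by a cardiofed operator.
#' @return character vector of flags (possibly empty).
#' @export
getFlags <- function(x) {
  f <- attr(x, "flags")
  if (is.null(f)) character(0) else f
}

stopParam <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

checkCount <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopParam(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

checkNumber <- function(x, field, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x))
    stopParam(field, "must be a single finite number")
  if (strict && x <= min) stopParam(field, sprintf("must be > %g", min))
  if (!strict && x < min) stopParam(field, sprintf("must be >= %g", min))
  as.numeric(x)
}

# Softmax over rows with max subtraction for numerical stability.
rowSoftmax <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# One-hot encode 0-based integer labels into an n x C indicator matrix.
oneHot <- function(labels, nClasses) {
  n <- length(labels)
  out <- matrix(0, n, nClasses)
  out[cbind(seq_len(n), labels + 1L)] <- 1
  out
}
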