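# Internal helpers shared across modules.

# Circular (shortest-arc) distance between positions a and b on a chromosome
# of length len. Vectorised over a and b.
circ_dist <- function(a, b, len) {
  d <- abs(a - b) %% len
  pmin(d, len - d)
}

# Evaluate expr under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Centered moving average of odd width k. Positions closer than (k-1)/2 to an
# edge use the partial window that fits, so the output covers the full span.
# A uniform centered kernel reproduces constant and linear inputs exactly on
# the interior.
moving_average <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1, k <= length(x))
  if (k == 1) return(x)
  h <- (k - 1L) / 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# stop()/warning() wrappers that keep call noise out of user-facing messages
abort2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
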