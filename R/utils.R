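# Internal helpers shared across modules.

# Rec. 601 luma weights used everywhere a scalar intensity is needed.
LUMA <- c(0.299, 0.587, 0.114)

# round() in R rounds half to even; raster arithmetic here wants half-up.
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' @noRd
# Mirror 1-based indices into 1..n without repeating the edge sample
# (.. 3 2 | 1 2 3 .. n | n-1 n-2 ..). Valid for any offset.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  j <- (idx - 1L) %% period
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

# Named-stream seeding: every random draw in the package flows from one
# user seed through a (seed, stream-name) hash, so adding a stream never
# perturbs the others. Kept below 2^31 (R integers).
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(seed) * 7919 + h) %% 2147480009)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
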