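# shared low-level helpers

#' Convert seconds to an integer number of samples
#'
#' One rounding rule is used for every ms-to-sample conversion in the package:
#' `round()` (round-half-even). All search-window arithmetic goes through this
#' helper so window edges are reproducible across modules.
#'
#' @param t time in seconds (vectorized)
#' @param fs sampling frequency in Hz
#' @return integer sample counts
#' @export
sec_to_samples <- function(t, fs) {
  as.integer(round(t * fs))
}

# earliest argmax (ties break toward the smallest index, globally)
arg_max_first <- function(x) {
  which.max(x) # which.max already returns the first maximum
}

# running standard deviation over a centered window of `w` samples,
# edge-clipped (windows shrink near the record edges). O(n) via cumsums.
rolling_sd_centered <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1L, 1L)
  sqrt(pmax(v, 0))
}

# local maxima indices: strictly greater than the left neighbour,
# not smaller than the right one (plateaus resolve to their first sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
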