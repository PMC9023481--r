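#' @name twave
#' @title T wave localization
#'
#' @description
#' Each beat's T wave is the maximum of the phasor-transformed (`rv_t = 0.1`)
#' cleaned signal inside an RR-proportional window after the QRS:
#' `R(i) + 0.12 * RR(i)` to `R(i) + 0.57 * RR(i) + 60 ms`, where `RR(i)` is
#' the interval following `R(i)` (the last beat reuses the preceding
#' interval). The literal phase maximum is used, so deeply inverted T waves
#' are a known limitation.
NULL

#' T search window for one beat
#'
#' Pure offset arithmetic around the R position; seconds are converted to
#' samples with the shared [sec_to_samples()] rounding rule. Optionally
#' clipped to `[1, sig_len]`.
#'
#' @param r R position of the beat (sample index)
#' @param rr_next following RR interval, seconds
#' @param fs sampling frequency, Hz
#' @param cfg a [detector_config()]
#' @param sig_len clip bound (optional)
#' @return `c(left, right)` sample interval, or `NULL` when degenerate
#' @export
t_search_window <- function(r, rr_next, fs, cfg = detector_config(),
                            sig_len = NULL) {
  if (!is.finite(rr_next) || rr_next <= 0) return(NULL)
  a <- r + sec_to_samples(cfg$t_win[1] * rr_next, fs)
  b <- r + sec_to_samples(cfg$t_win[2] * rr_next + cfg$t_win[3], fs)
  if (!is.null(sig_len)) {
    a <- max(a, 1L)
    b <- min(b, sig_len)
  }
  if (a > b) return(NULL)
  c(as.integer(a), as.integer(b))
}

#' Detect T waves for every beat
#'
#' @param cleaned a `filtered_signal` of kind `"cleaned"` (see [clean_ecg()])
#' @param beats a `beat_set` with R positions
#' @param cfg a [detector_config()]
#' @return the `beat_set` with `t_peaks` filled (NA where the window is empty)
#' @export
detect_t <- function(cleaned, beats, cfg = detector_config()) {
  stopifnot(inherits(cleaned, "filtered_signal"), inherits(beats, "beat_set"))
  x <- cleaned$samples
  fs <- cleaned$fs
  r <- beats$r_peaks
  nb <- length(r)
  if (nb == 0) return(beats)
  rr_next <- if (nb >= 2) c(diff(r) / fs, (r[nb] - r[nb - 1]) / fs) else NA_real_
  for (i in seq_len(nb)) {
    w <- t_search_window(r[i], rr_next[i], fs, cfg, sig_len = length(x))
    if (is.null(w)) next
    seg <- w[1]:w[2]
    pt <- phasor_transform(x[seg], cfg$rv_t)
    beats$t_peaks[i] <- seg[arg_max_first(pt)]
  }
  beats
}
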