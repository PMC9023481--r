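#' @name qrs
#' @title QRS detection on the phasor-transformed band-passed ECG
#'
#' @description
#' R peaks are found on the phasor transform (`rv_qrs`) of the 12-19 Hz
#' band-passed signal. Candidate peaks are the largest local maxima in
#' non-overlapping 300 ms windows; a candidate is kept when the band-passed
#' amplitude at its position exceeds an adaptive threshold of twice the local
#' standard deviation in a centered 2 s moving window. Detections closer than
#' the 200 ms refractory distance are merged to the larger peak. A backward
#' search then re-scans any RR interval more than 1.75 times longer than its
#' predecessor with a lowered threshold (30% of the last detected QRS
#' amplitude) to recover missed beats.
#'
#' Amplitudes for the adaptive and backward-search thresholds are compared in
#' the band-passed domain: the arctangent is strictly increasing, so peak
#' positions on the phase signal and on the band-passed signal coincide, but
#' amplitude ratios are only meaningful before the arctangent compresses them.
NULL

beat_set <- function(r_peaks, fs) {
  r_peaks <- as.integer(sort(unique(r_peaks)))
  structure(
    list(r_peaks = r_peaks,
         fs = fs,
         rr = c(NA_real_, diff(r_peaks) / fs),
         pvc = rep(FALSE, length(r_peaks)),
         afib = rep(FALSE, length(r_peaks)),
         t_peaks = rep(NA_integer_, length(r_peaks)),
         p_peaks = rep(NA_integer_, length(r_peaks))),
    class = "beat_set"
  )
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats @ %g Hz | PVC: %d, AFIB: %d, T: %d, P: %d\n",
              length(x$r_peaks), x$fs, sum(x$pvc), sum(x$afib),
              sum(!is.na(x$t_peaks)), sum(!is.na(x$p_peaks))))
  invisible(x)
}

# greedy refractory pruning: accept peaks in decreasing amplitude order,
# reject any candidate within `refr` samples of an accepted one
prune_refractory <- function(idx, amp, refr) {
  if (length(idx) < 2) return(idx)
  ord <- order(amp, decreasing = TRUE)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(idx[j] - kept) >= refr)) kept <- c(kept, idx[j])
  }
  sort(kept)
}

#' Detect R peaks
#'
#' @param sig a `filtered_signal` of kind `"qrs_band"` (see [bandpass_qrs()])
#' @param cfg a [detector_config()]
#' @return a `beat_set` with R positions on the original time axis
#' @export
detect_qrs <- function(sig, cfg = detector_config()) {
  stopifnot(inherits(sig, "filtered_signal"), sig$kind == "qrs_band")
  x <- sig$samples
  fs <- sig$fs
  if (length(x) < 2 * fs) stop("signal too short: need at least 2 s")
  pt <- phasor_transform(x, cfg$rv_qrs)

  thr <- 2 * rolling_sd_centered(x, sec_to_samples(cfg$std_window, fs))
  refr <- sec_to_samples(cfg$refractory, fs)
  win <- max(2L, sec_to_samples(cfg$slide_window, fs))

  lm <- local_maxima(pt)
  lm <- lm[x[lm] > thr[lm]]
  cand <- integer(0)
  if (length(lm)) {
    # one candidate per non-overlapping 300 ms window: its largest local max
    bins <- (lm - 1L) %/% win
    for (b in unique(bins)) {
      ii <- lm[bins == b]
      cand <- c(cand, ii[arg_max_first(pt[ii])])
    }
  }
  cand <- prune_refractory(cand, x[cand], refr)
  beats <- beat_set(cand, fs)
  backward_search(beats, sig, cfg)
}

#' Backward search for missed beats
#'
#' Whenever `RR(i) > rr_gap_factor * RR(i-1)`, the open interval between the
#' two detections is re-scanned for local maxima whose band-passed amplitude
#' exceeds `back_thresh` times the amplitude of the last detected QRS before
#' the gap. Any peaks found are inserted (largest first, respecting the
#' refractory distance) and the RR sequence recomputed; the scan repeats until
#' no interval fires, so the operation is idempotent.
#'
#' @param beats a `beat_set` from the threshold pass
#' @param sig the `filtered_signal` of kind `"qrs_band"` the beats came from
#' @param cfg a [detector_config()]
#' @return the augmented `beat_set`
#' @export
backward_search <- function(beats, sig, cfg = detector_config()) {
  stopifnot(inherits(beats, "beat_set"),
            inherits(sig, "filtered_signal"), sig$kind == "qrs_band")
  x <- sig$samples
  fs <- sig$fs
  pt <- phasor_transform(x, cfg$rv_qrs)
  refr <- sec_to_samples(cfg$refractory, fs)
  r <- beats$r_peaks
  repeat {
    inserted <- FALSE
    if (length(r) >= 3) {
      rr <- diff(r)
      new_pk <- integer(0)
      for (i in 2:length(rr)) {
        if (rr[i] > cfg$rr_gap_factor * rr[i - 1]) {
          # open interval between the two detections, refractory-padded
          a <- r[i] + refr
          b <- r[i + 1] - refr
          if (b - a < 2) next
          seg <- a:b
          thr <- cfg$back_thresh * x[r[i]]
          lm <- seg[local_maxima(pt[seg])]
          lm <- lm[x[lm] > thr]
          new_pk <- c(new_pk, lm)
        }
      }
      if (length(new_pk)) {
        # the padded scan keeps new peaks >= refr away from existing ones,
        # so pruning only has to arbitrate among the new candidates
        new_pk <- prune_refractory(new_pk, x[new_pk], refr)
        new_pk <- new_pk[vapply(new_pk, function(p) all(abs(p - r) >= refr), logical(1))]
        if (length(new_pk)) {
          r <- sort(unique(c(r, new_pk)))
          inserted <- TRUE
        }
      }
    }
    if (!inserted) break
  }
  beat_set(r, fs)
}
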