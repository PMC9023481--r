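#' @name pwave
#' @title Normal and dissociated P wave detection and verification
#'
#' @description
#' The core of the method. For a beat that passes the pathology gate, the
#' conducted (normal) P candidate is the maximum of the phasor-transformed
#' (`rv_p = 0.05`) cleaned signal in the window `R(i-1) + 0.71 * RR(i)` to
#' `R(i) - 0.07 * RR(i) - 60 ms` (first beat: the fixed window `R - 300 ms` to
#' `R - 80 ms`). A dissociated P (AV block) is searched inside long pauses:
#' when the previous interval had no dissociated P the gate requires
#' `RR(i) > 1.6 * RR(i-1)`, `RR(i) > 1.6 s` and the beat not to be a PVC;
#' once a dissociated P has been found, a follow-up interval only needs
#' `RR(i) > 0.8 * RR(i-1)`. The dissociated candidate is the phase maximum in
#' `T(i-1) + 200 ms` to `P(i) - 400 ms`. Every candidate must finally pass two
#' verification criteria: its amplitude must exceed 5% of the QRS amplitude
#' (both measured as absolute values on the cleaned signal), and it must lie
#' after the previous T wave (otherwise it is that T wave, not a P).
NULL

#' Normal P search window for one beat
#'
#' Offset arithmetic around the R position with the shared rounding rule.
#' `rr_prev` is the interval ending at `R(i)`; when `NA` (first beat) the
#' fixed fallback window `[R - 300 ms, R - 80 ms]` is used.
#'
#' @param r R position of the beat (sample index)
#' @param rr_prev RR interval ending at this beat, seconds, or `NA`
#' @param fs sampling frequency, Hz
#' @param cfg a [detector_config()]
#' @param sig_len clip bound (optional)
#' @return `c(left, right)` sample interval, or `NULL` when degenerate
#' @export
p_search_window <- function(r, rr_prev, fs, cfg = detector_config(),
                            sig_len = NULL) {
  if (is.na(rr_prev)) {
    a <- r - sec_to_samples(cfg$first_p_win[1], fs)
    b <- r - sec_to_samples(cfg$first_p_win[2], fs)
  } else {
    if (rr_prev <= 0) return(NULL)
    r_prev <- r - sec_to_samples(rr_prev, fs)
    a <- r_prev + sec_to_samples(cfg$p_win[1] * rr_prev, fs)
    b <- r - sec_to_samples(cfg$p_win[2] * rr_prev + cfg$p_win[3], fs)
  }
  if (!is.null(sig_len)) {
    a <- max(a, 1L)
    b <- min(b, sig_len)
  }
  if (a > b) return(NULL)
  c(as.integer(a), as.integer(b))
}

p_candidate <- function(beat_index, position, amplitude, kind,
                        accepted = FALSE, rejection_reason = "none") {
  data.frame(beat_index = beat_index,
             position = position,
             amplitude = amplitude,
             kind = kind,
             accepted = accepted,
             rejection_reason = rejection_reason,
             stringsAsFactors = FALSE)
}

#' Detect the conducted P candidate of one beat
#'
#' Maximum of the phasor transform (`rv_p`) of the cleaned signal inside
#' [p_search_window()]; the amplitude is read off the cleaned signal at the
#' candidate position. Ties break toward the earliest sample.
#'
#' @param cleaned a `filtered_signal` of kind `"cleaned"`
#' @param beats a `beat_set`
#' @param i beat index
#' @param cfg a [detector_config()]
#' @return a one-row candidate data frame, or `NULL` when the window is empty
#' @export
detect_normal_p <- function(cleaned, beats, i, cfg = detector_config()) {
  stopifnot(inherits(cleaned, "filtered_signal"), inherits(beats, "beat_set"))
  x <- cleaned$samples
  w <- p_search_window(beats$r_peaks[i], beats$rr[i], cleaned$fs, cfg,
                       sig_len = length(x))
  if (is.null(w)) return(NULL)
  seg <- w[1]:w[2]
  pt <- phasor_transform(x[seg], cfg$rv_p)
  pos <- seg[arg_max_first(pt)]
  p_candidate(i, pos, x[pos], "normal")
}

#' Dissociation gate
#'
#' Decides whether a dissociated P wave may be present in the interval ending
#' at beat `i`. With no dissociated P in the previous interval all three
#' criteria must hold: `RR(i) > 1.6 * RR(i-1)`, `RR(i) > 1.6 s`, and the beat
#' is not a PVC. If the previous interval did contain one, a single criterion
#' applies: `RR(i) > 0.8 * RR(i-1)`.
#'
#' @param rr_cur current RR interval, seconds
#' @param rr_prev previous RR interval, seconds
#' @param is_pvc is the current beat flagged PVC?
#' @param prev_had_dissociated did the previous interval contain a dissociated P?
#' @param cfg a [detector_config()]
#' @return logical
#' @export
dissociation_gate <- function(rr_cur, rr_prev, is_pvc,
                              prev_had_dissociated = FALSE,
                              cfg = detector_config()) {
  if (is.na(rr_cur) || is.na(rr_prev)) return(FALSE)
  if (prev_had_dissociated) {
    rr_cur > cfg$diss[3] * rr_prev
  } else {
    (rr_cur > cfg$diss[1] * rr_prev) && (rr_cur > cfg$diss[2]) && !is_pvc
  }
}

#' Detect a dissociated P candidate inside a pause
#'
#' Phase maximum (`rv_p`) in the window `T(i-1) + 200 ms` to
#' `Pref(i) - 400 ms`, where `Pref(i)` is the accepted conducted P of beat
#' `i`; when beat `i` has no accepted P, the left edge of its normal search
#' window stands in, which keeps the dissociated search strictly left of any
#' plausible conducted-P territory.
#'
#' @param cleaned a `filtered_signal` of kind `"cleaned"`
#' @param t_prev T position of the previous beat (sample index)
#' @param p_ref right reference position (sample index)
#' @param i beat index (recorded in the candidate)
#' @param cfg a [detector_config()]
#' @return a one-row candidate data frame, or `NULL` when the window is empty
#' @export
detect_dissociated_p <- function(cleaned, t_prev, p_ref, i,
                                 cfg = detector_config()) {
  stopifnot(inherits(cleaned, "filtered_signal"))
  if (is.na(t_prev) || is.na(p_ref)) return(NULL)
  x <- cleaned$samples
  fs <- cleaned$fs
  a <- max(1L, t_prev + sec_to_samples(cfg$diss[4], fs))
  b <- min(length(x), p_ref - sec_to_samples(cfg$diss[5], fs))
  if (a > b) return(NULL)
  seg <- a:b
  pt <- phasor_transform(x[seg], cfg$rv_p)
  pos <- seg[arg_max_first(pt)]
  p_candidate(i, pos, x[pos], "dissociated")
}

#' Verify a P wave candidate
#'
#' Two criteria, checked in order. Voltage: `|U_P| > up_factor * |U_QRS|`,
#' with both amplitudes read from the cleaned signal at the candidate and R
#' positions (a candidate failing this is likely no P at all, as in nodal or
#' idioventricular rhythm). Position: the candidate must lie strictly after
#' the previous beat's T wave, otherwise it is that T wave. A candidate in
#' the first beat (no previous T) passes the position criterion vacuously.
#'
#' @param cand one-row candidate data frame
#' @param u_qrs QRS amplitude of the current beat (cleaned signal, mV)
#' @param t_prev T position of the previous beat, or `NA`
#' @param cfg a [detector_config()]
#' @return the candidate with `accepted` and `rejection_reason` set
#' @export
verify_p <- function(cand, u_qrs, t_prev, cfg = detector_config()) {
  if (is.null(cand)) return(NULL)
  if (abs(cand$amplitude) <= cfg$up_factor * abs(u_qrs)) {
    cand$accepted <- FALSE
    cand$rejection_reason <- "low_voltage"
  } else if (!is.na(t_prev) && cand$position <= t_prev) {
    cand$accepted <- FALSE
    cand$rejection_reason <- "behind_T"
  } else {
    cand$accepted <- TRUE
    cand$rejection_reason <- "none"
  }
  cand
}
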