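#' @name rhythm
#' @title Rhythm context: PVC and AFIB flagging
#'
#' @description
#' Two per-beat pathology flags steer the P wave search. PVC beats are
#' recognized by the area under the QRS: the absolute integral of the
#' baseline-free signal over `R(i) - 150 ms` to `R(i) + 150 ms`. A beat is a
#' PVC when its area exceeds 1.3 times the median area of all previous beats;
#' if more than 75% of all beats end up flagged, the morphology change is
#' reinterpreted as a bundle branch block and all flags are cleared. AFIB is
#' recognized from heart-rate dynamics: the heart-rate sequence is quantized
#' into symbols, 3-symbol words are formed, and the normalized Shannon entropy
#' of the word distribution over a 59-beat window is thresholded at 0.737;
#' when more than 30 PVCs fall inside the window the entropy rise is blamed on
#' the PVCs and the AFIB flag is withheld.
NULL

#' QRS area per beat
#'
#' `auc(i) = sum(|x(n)|) / fs` over `R(i) +/- 150 ms` on the baseline-free
#' (Lynn high-passed) signal, windows clipped at the record edges. Also
#' returns the running median of all strictly previous areas (NA for the
#' first beat).
#'
#' @param baseline_free a `filtered_signal` of kind `"baseline_free"`
#'   (see [highpass_lynn()])
#' @param beats a `beat_set`
#' @param cfg a [detector_config()]
#' @return a list of class `auc_series` with `auc` and `running_median`
#' @export
compute_auc <- function(baseline_free, beats, cfg = detector_config()) {
  stopifnot(inherits(baseline_free, "filtered_signal"),
            inherits(beats, "beat_set"))
  x <- baseline_free$samples
  fs <- baseline_free$fs
  half <- sec_to_samples(cfg$pvc_win, fs)
  auc <- vapply(beats$r_peaks, function(r) {
    lo <- max(1L, r - half)
    hi <- min(length(x), r + half)
    sum(abs(x[lo:hi])) / fs
  }, numeric(1))
  run_med <- rep(NA_real_, length(auc))
  if (length(auc) >= 2) {
    for (i in 2:length(auc)) run_med[i] <- median(auc[seq_len(i - 1)])
  }
  structure(list(auc = auc, running_median = run_med), class = "auc_series")
}

#' Flag PVC beats from the QRS-area series
#'
#' `pvc(i) = auc(i) > pvc_factor * median of the areas of all previous
#' non-ectopic beats`; the first beat is never a PVC (no prior median). Beats
#' already flagged are excluded from the running median so that runs of
#' ectopy (bigeminy, couplets) cannot drag the normal-beat reference upward
#' and mask later PVCs. If the flagged fraction over all beats exceeds
#' `pvc_reset_frac` (strictly), all flags are cleared: a morphology change
#' affecting nearly every beat is a bundle branch block, not ectopy. The rule
#' is scale-free: rescaling all areas by a positive constant leaves the flags
#' unchanged.
#'
#' @param auc an `auc_series` from [compute_auc()]
#' @param cfg a [detector_config()]
#' @return logical vector of per-beat PVC flags
#' @export
detect_pvc <- function(auc, cfg = detector_config()) {
  stopifnot(inherits(auc, "auc_series"))
  a <- auc$auc
  n <- length(a)
  flags <- rep(FALSE, n)
  normal <- numeric(0)
  for (i in seq_len(n)) {
    if (length(normal) && a[i] > cfg$pvc_factor * median(normal)) {
      flags[i] <- TRUE
    } else {
      normal <- c(normal, a[i])
    }
  }
  if (n > 0 && mean(flags) > cfg$pvc_reset_frac) {
    flags[] <- FALSE
  }
  flags
}

#' Symbolic dynamics and Shannon entropy of the heart-rate sequence
#'
#' The per-beat heart rate `hr(i) = 60 / RR(i)` (RR ending at beat i, NA for
#' the first beat) is quantized into symbols of 15 bpm width (clipped to
#' 0-315 bpm); a word encodes three consecutive symbols
#' `(Sy(i), Sy(i+1), Sy(i+2))` in base 64. The entropy assigned to beat `i`
#' is the Shannon entropy of the empirical word distribution over the 59-word
#' window `wv(i-29) .. wv(i+29)`, normalized by `ln(59)` so it lies in [0, 1].
#' Beats whose window would leave the record (or touch undefined words at the
#' record edges) get `NA` - such beats are never flagged as AFIB.
#'
#' @param beats a `beat_set`
#' @param cfg a [detector_config()]
#' @return a list of class `entropy_series` with `hr`, `symbols`, `words`, `sh`
#' @export
symbolic_entropy <- function(beats, cfg = detector_config()) {
  stopifnot(inherits(beats, "beat_set"))
  nb <- length(beats$r_peaks)
  hr <- 60 / beats$rr                      # rr[1] is NA by construction
  sy <- hr_symbols(hr)
  wv <- rep(NA_integer_, nb)
  if (nb >= 4) {
    for (i in 2:(nb - 2)) {
      wv[i] <- sy[i] * 4096L + sy[i + 1] * 64L + sy[i + 2]
    }
  }
  half <- (cfg$sh_window - 1L) %/% 2L
  sh <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    lo <- i - half
    hi <- i + half
    if (lo < 1L || hi > nb) next
    w <- wv[lo:hi]
    if (anyNA(w)) next
    sh[i] <- shannon_entropy_norm(w, cfg$sh_window)
  }
  structure(list(hr = hr, symbols = sy, words = wv, sh = sh),
            class = "entropy_series")
}

# 15 bpm bins over 0-315 bpm (22 symbols). Calibrated against the 0.737
# entropy threshold on synthetic rhythms: sinus with up to ~5% RR jitter at
# rates up to ~120 bpm stays well below the threshold, while RR jitter of
# 25% or more (AFIB-like) exceeds it by a wide margin.
hr_symbols <- function(hr) {
  s <- floor(pmin(pmax(hr, 0), 315) / 15)
  as.integer(s)
}

# normalized Shannon entropy of a word window: -sum p ln p / ln(n)
shannon_entropy_norm <- function(words, n) {
  p <- tabulate(match(words, unique(words)))
  p <- p / length(words)
  -sum(p * log(p)) / log(n)
}

#' Flag AFIB beats from the entropy series
#'
#' `afib(i)` is set when `sh(i) > sh_thresh`; the flag is withheld when more
#' than `sh_pvc_override` PVC-flagged beats fall inside the same 59-beat
#' window (the entropy rise is then attributed to the ectopy, not to AFIB).
#' With fewer beats than the window length no entropy exists and no beat is
#' ever flagged.
#'
#' @param ent an `entropy_series` from [symbolic_entropy()]
#' @param pvc_flags logical per-beat PVC flags
#' @param cfg a [detector_config()]
#' @return logical vector of per-beat AFIB flags
#' @export
detect_afib <- function(ent, pvc_flags, cfg = detector_config()) {
  stopifnot(inherits(ent, "entropy_series"))
  nb <- length(ent$sh)
  stopifnot(length(pvc_flags) == nb)
  half <- (cfg$sh_window - 1L) %/% 2L
  flags <- rep(FALSE, nb)
  for (i in seq_len(nb)) {
    if (is.na(ent$sh[i]) || ent$sh[i] <= cfg$sh_thresh) next
    lo <- max(1L, i - half)
    hi <- min(nb, i + half)
    if (sum(pvc_flags[lo:hi]) > cfg$sh_pvc_override) next
    flags[i] <- TRUE
  }
  flags
}

#' Per-beat pathology gate
#'
#' Decides whether the P wave search proceeds for beat `i`. AFIB is checked
#' first: an AFIB-flagged beat has no P wave at all, so the search is
#' skipped entirely. Otherwise a PVC-flagged beat skips the search before its
#' QRS (a PVC has no conducted P). Otherwise the search proceeds.
#'
#' @param beats a `beat_set` with `pvc` and `afib` flags populated
#' @param i beat index
#' @return one of `"skip_afib"`, `"skip_pvc"`, `"proceed"`
#' @export
pathology_check <- function(beats, i) {
  stopifnot(inherits(beats, "beat_set"), i >= 1, i <= length(beats$r_peaks))
  if (beats$afib[i]) return("skip_afib")
  if (beats$pvc[i]) return("skip_pvc")
  "proceed"
}
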