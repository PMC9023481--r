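#' @name synthetic
#' @title Synthetic ECG generator with exact ground truth
#'
#' @description
#' Builds single-lead ECG as a sum of parametric waves on a zero baseline -
#' per beat a Gaussian P bump, a Ricker (Mexican-hat) QRS whose negative
#' lobes mimic the Q and S deflections and keep the net QRS area near zero,
#' and a Gaussian T bump - so the position, amplitude and area of every wave
#' are known exactly. Rhythm events emulate the pathologies the decision
#' rules target: wide, high-area PVC beats without a P wave; highly irregular
#' RR stretches with absent P waves (an AFIB surrogate); dropped QRS+T with a
#' retained P (a second-degree AV block surrogate); and globally widened QRS
#' (a bundle-branch-block surrogate). Wave timings scale with the local RR
#' interval so every wave stays inside its detector search window for heart
#' rates between 40 and 180 bpm. Bump centers are snapped to the sample grid,
#' so the returned truth indices are exact.
NULL

#' Specify a synthetic ECG
#'
#' @param fs sampling frequency, Hz
#' @param duration record length, seconds
#' @param hr_bpm mean heart rate, beats/min
#' @param rr_jitter fractional standard deviation of the RR intervals (0 for a
#'   metronomic rhythm)
#' @param p_amp,qrs_amp,t_amp wave amplitudes, mV
#' @param p_sd,qrs_sd,t_sd Gaussian widths (standard deviation), seconds
#' @param events list of event descriptors; each is a list with `type` one of
#'   `"pvc"`, `"afib_segment"`, `"avb2_drop"`, `"rbbb_widen"` and
#'   `beats` (integer beat indices for `pvc`/`avb2_drop`, an inclusive
#'   range `c(from, to)` for `afib_segment`). Optional event parameters:
#'   `width_factor`/`amp_factor` for `pvc` (defaults 2.5 / 1.8),
#'   `rr_jitter` for `afib_segment` (default 0.30, must be >= 0.25),
#'   `width_factor` for `rbbb_widen` (default 1.8).
#' @param seed integer seed; the same spec always produces the same record
#' @return a list of class `synth_spec`
#' @export
synth_ecg <- function(fs = 360, duration = 60, hr_bpm = 60, rr_jitter = 0,
                      p_amp = 0.15, qrs_amp = 1.0, t_amp = 0.30,
                      p_sd = 0.020, qrs_sd = 0.012, t_sd = 0.040,
                      events = list(), seed = 1L) {
  stopifnot(fs > 0, duration > 0, hr_bpm >= 20, hr_bpm <= 250,
            rr_jitter >= 0, rr_jitter < 1,
            p_amp >= 0, qrs_amp >= 0, t_amp >= 0,
            p_sd > 0, qrs_sd > 0, t_sd > 0)
  for (ev in events) {
    if (!ev$type %in% c("pvc", "afib_segment", "avb2_drop", "rbbb_widen")) {
      stop("unknown event type: ", ev$type)
    }
  }
  structure(list(fs = fs, duration = duration, hr_bpm = hr_bpm,
                 rr_jitter = rr_jitter, p_amp = p_amp, qrs_amp = qrs_amp,
                 t_amp = t_amp, p_sd = p_sd, qrs_sd = qrs_sd, t_sd = t_sd,
                 events = events, seed = as.integer(seed)),
            class = "synth_spec")
}

# biphasic wave (derivative of a Gaussian, peak amplitude +/- amp at one sd
# from the center): near-zero net area but a large absolute area, like the
# broad slurred component of a real ventricular ectopic
add_biphasic <- function(x, center, amp, sd_samp) {
  if (amp == 0) return(x)
  span <- ceiling(6 * sd_samp)
  lo <- max(1L, as.integer(center) - span)
  hi <- min(length(x), as.integer(center) + span)
  if (lo > hi) return(x)
  idx <- lo:hi
  u <- (idx - center) / sd_samp
  x[idx] <- x[idx] + amp * u * exp(0.5 - u^2 / 2)
  x
}

add_bump <- function(x, center, amp, sd_samp) {
  if (amp == 0) return(x)
  span <- ceiling(5 * sd_samp)
  lo <- max(1L, as.integer(center) - span)
  hi <- min(length(x), as.integer(center) + span)
  if (lo > hi) return(x)
  idx <- lo:hi
  x[idx] <- x[idx] + amp * exp(-((idx - center)^2) / (2 * sd_samp^2))
  x
}

# Ricker (Mexican-hat) wave: a sharp positive apex flanked by two shallow
# negative lobes, like the Q and S deflections around a real R peak. Its net
# area is near zero, so baseline removal does not shift the neighbourhood.
add_qrs_wave <- function(x, center, amp, sd_samp) {
  if (amp == 0) return(x)
  span <- ceiling(6 * sd_samp)
  lo <- max(1L, as.integer(center) - span)
  hi <- min(length(x), as.integer(center) + span)
  if (lo > hi) return(x)
  idx <- lo:hi
  u <- (idx - center) / sd_samp
  x[idx] <- x[idx] + amp * (1 - u^2) * exp(-u^2 / 2)
  x
}

#' Generate a synthetic ECG record and its ground truth
#'
#' Wave placement per beat: the QRS apex defines `R(i)`; the P apex sits at
#' `R(i) - (0.18 * RR(i) + 0.030 s)` (the midpoint of the conducted-P
#' territory, with the PR interval shortening at fast rates as it does
#' physiologically) and the T apex at `R(i) + (0.345 * RR(i+1) + 0.030 s)`.
#'
#' @param spec a [synth_ecg()] spec
#' @return a list with `record` (an [ecg_record()]), `truth` (a
#'   [wave_annotations()] with exact P/T/R indices) and `beats` (a data frame
#'   with one row per generated beat: `r`, `p`, `t` sample indices, NA where
#'   the wave is absent, and `label` in normal/pvc/afib/dropped)
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  set.seed(spec$seed)
  rr_mean <- 60 / spec$hr_bpm

  # beat times: first R at ~0.5 s, last at least 0.5 s before the end
  r_times <- numeric(0)
  t_cur <- 0.5
  while (t_cur <= spec$duration - 0.5) {
    r_times <- c(r_times, t_cur)
    rr <- rr_mean * (1 + spec$rr_jitter * rnorm(1))
    t_cur <- t_cur + max(rr, 0.3 * rr_mean)
  }
  nb <- length(r_times)
  label <- rep("normal", nb)
  qrs_w <- rep(spec$qrs_sd, nb)
  qrs_a <- rep(spec$qrs_amp, nb)
  has_p <- rep(TRUE, nb)
  has_qrs <- rep(TRUE, nb)

  for (ev in spec$events) {
    if (ev$type == "afib_segment") {
      rng <- ev$beats
      jit <- ev$rr_jitter %||% 0.30
      stopifnot(jit >= 0.25)
      idx <- rng[1]:min(rng[2], nb)
      # redraw the RR intervals inside the segment i.i.d.
      for (i in idx) {
        if (i > 1 && i <= nb) {
          rr <- rr_mean * max(1 + jit * rnorm(1), 0.3)
          shift <- (r_times[i - 1] + rr) - r_times[i]
          r_times[i:nb] <- r_times[i:nb] + shift
        }
      }
      label[idx] <- "afib"
      has_p[idx] <- FALSE
    }
  }
  # drop beats that jitter pushed past the record end
  keep <- r_times <= spec$duration - 0.5
  r_times <- r_times[keep]; label <- label[keep]; qrs_w <- qrs_w[keep]
  qrs_a <- qrs_a[keep]; has_p <- has_p[keep]; has_qrs <- has_qrs[keep]
  nb <- length(r_times)

  pvc_wide_w <- rep(NA_real_, nb)
  for (ev in spec$events) {
    if (ev$type == "pvc") {
      idx <- ev$beats[ev$beats <= nb]
      # a PVC keeps a sharp intrinsicoid deflection (narrow component, so the
      # band-pass detector still sees it) and adds a broad hump that carries
      # the large QRS area the PVC rule keys on
      qrs_a[idx] <- qrs_a[idx] * (ev$amp_factor %||% 1.8)
      pvc_wide_w[idx] <- spec$qrs_sd * (ev$width_factor %||% 2.5)
      has_p[idx] <- FALSE
      label[idx] <- "pvc"
    } else if (ev$type == "avb2_drop") {
      idx <- ev$beats[ev$beats <= nb]
      has_qrs[idx] <- FALSE
      label[idx] <- "dropped"
    } else if (ev$type == "rbbb_widen") {
      qrs_w <- qrs_w * (ev$width_factor %||% 1.8)
    }
  }

  # snap R to the sample grid; derive per-beat wave positions from local RR
  r_idx <- as.integer(round(r_times * fs)) + 1L
  rr_prev <- c(rr_mean, diff(r_times))          # RR ending at beat i
  rr_next <- c(diff(r_times), rr_mean)          # RR following beat i
  p_idx <- r_idx - sec_to_samples(0.18 * rr_prev + 0.030, fs)
  t_idx <- r_idx + sec_to_samples(0.345 * rr_next + 0.030, fs)

  n <- as.integer(round(spec$duration * fs))
  # drop any trailing/leading beat whose waves would leave the record
  margin <- ceiling(5 * max(spec$p_sd, spec$t_sd, max(qrs_w)) * fs)
  ok <- (p_idx - margin >= 1L) & (t_idx + margin <= n)
  r_idx <- r_idx[ok]; p_idx <- p_idx[ok]; t_idx <- t_idx[ok]
  label <- label[ok]; qrs_w <- qrs_w[ok]; qrs_a <- qrs_a[ok]
  has_p <- has_p[ok]; has_qrs <- has_qrs[ok]; pvc_wide_w <- pvc_wide_w[ok]
  nb <- length(r_idx)
  x <- numeric(n)
  for (i in seq_len(nb)) {
    if (has_p[i]) x <- add_bump(x, p_idx[i], spec$p_amp, spec$p_sd * fs)
    if (has_qrs[i]) {
      x <- add_qrs_wave(x, r_idx[i], qrs_a[i], qrs_w[i] * fs)
      if (!is.na(pvc_wide_w[i])) {
        x <- add_biphasic(x, r_idx[i], qrs_a[i], pvc_wide_w[i] * fs)
      }
      x <- add_bump(x, t_idx[i], spec$t_amp, spec$t_sd * fs)
    }
  }

  beats <- data.frame(
    r = ifelse(has_qrs, r_idx, NA_integer_),
    p = ifelse(has_p, p_idx, NA_integer_),
    t = ifelse(has_qrs, t_idx, NA_integer_),
    label = label,
    stringsAsFactors = FALSE
  )
  truth <- wave_annotations(
    p_peaks = sort(p_idx[has_p]),
    t_peaks = sort(t_idx[has_qrs]),
    r_peaks = sort(r_idx[has_qrs]),
    source = "reference", sig_len = n
  )
  list(
    record = ecg_record(x, fs, lead = "synthetic", record_id = "synthetic"),
    truth = truth,
    beats = beats
  )
}

#' Add reproducible noise to a record
#'
#' @param rec an [ecg_record()]
#' @param kind `"gaussian"` (white noise, `level` = sd in mV),
#'   `"baseline_drift"` (sinusoidal drift, `level` = amplitude in mV) or
#'   `"powerline"` (`level` = amplitude in mV)
#' @param level noise level, >= 0; 0 returns the record unchanged
#' @param freq drift or powerline frequency in Hz
#' @param seed integer seed (used by `"gaussian"`)
#' @return a new [ecg_record()]
#' @export
add_noise <- function(rec, kind = c("gaussian", "baseline_drift", "powerline"),
                      level, freq = NULL, seed = 1L) {
  stopifnot(inherits(rec, "ecg_record"), level >= 0)
  kind <- match.arg(kind)
  if (level == 0) return(rec)
  n <- length(rec$samples)
  tt <- (seq_len(n) - 1) / rec$fs
  noise <- switch(kind,
    gaussian = { set.seed(as.integer(seed)); rnorm(n, sd = level) },
    baseline_drift = level * sin(2 * pi * (freq %||% 0.2) * tt),
    powerline = level * sin(2 * pi * (freq %||% 50) * tt)
  )
  ecg_record(rec$samples + noise, rec$fs, rec$lead, rec$record_id)
}
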