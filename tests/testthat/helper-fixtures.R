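# shared fixture builders (everything generated in code; no stored data)

# sinus record plus pipeline-ready filtered views
sinus_fixture <- function(fs = 360, duration = 60, hr = 60, seed = 1,
                          rr_jitter = 0, events = list()) {
  generate_ecg(synth_ecg(fs = fs, duration = duration, hr_bpm = hr,
                         rr_jitter = rr_jitter, events = events, seed = seed))
}

# band-passed view of a record, as detect_qrs expects it
qrs_view <- function(rec, cfg = detector_config()) {
  xc <- clean_ecg(rec, cfg)
  bandpass_qrs(ecg_record(xc$samples, rec$fs, rec$lead, rec$record_id),
               cfg$qrs_band)
}

# max |detected - nearest truth| over detections; Inf when counts differ
localization_error <- function(detected, truth) {
  if (!length(detected) || !length(truth)) return(Inf)
  max(vapply(detected, function(p) min(abs(p - truth)), numeric(1)))
}

# brute-force maximum-cardinality matching between two sorted index sets
# within +/- tol samples (oracle for match_peaks, feasible for <= 10 peaks)
brute_force_match <- function(detected, reference, tol) {
  best <- 0L
  recurse <- function(k, used) {
    if (k > length(detected)) {
      best <<- max(best, sum(used))
      return(invisible(NULL))
    }
    # prune: even matching everything remaining cannot beat best
    if (sum(used) + (length(detected) - k + 1) <= best) return(invisible(NULL))
    for (j in seq_along(reference)) {
      if (!used[j] && abs(detected[k] - reference[j]) <= tol) {
        used[j] <- TRUE
        recurse(k + 1L, used)
        used[j] <- FALSE
      }
    }
    recurse(k + 1L, used)
  }
  recurse(1L, rep(FALSE, length(reference)))
  best
}

# beat_set built directly from R positions (for unit tests below the pipeline)
beats_from_r <- function(r, fs) {
  r <- as.integer(sort(r))
  structure(list(r_peaks = r, fs = fs,
                 rr = c(NA_real_, diff(r) / fs),
                 pvc = rep(FALSE, length(r)),
                 afib = rep(FALSE, length(r)),
                 t_peaks = rep(NA_integer_, length(r)),
                 p_peaks = rep(NA_integer_, length(r))),
            class = "beat_set")
}

# auc_series built directly from a numeric vector
auc_from_values <- function(a) {
  rm <- rep(NA_real_, length(a))
  if (length(a) >= 2) for (i in 2:length(a)) rm[i] <- median(a[seq_len(i - 1)])
  structure(list(auc = a, running_median = rm), class = "auc_series")
}

# entropy_series with a given sh vector (for detect_afib unit tests)
entropy_from_sh <- function(sh) {
  structure(list(hr = rep(NA_real_, length(sh)),
                 symbols = rep(NA_integer_, length(sh)),
                 words = rep(NA_integer_, length(sh)), sh = sh),
            class = "entropy_series")
}
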