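#' Construct an ECG record
#'
#' The universal input of the package: one channel of ECG in physical units
#' (millivolts) plus its sampling frequency. Sample index `i` (1-based) always
#' means time `(i - 1) / fs` seconds; no function in the package rescales time.
#'
#' @param samples numeric vector, finite values, physical units (mV)
#' @param fs sampling frequency in Hz, positive
#' @param lead lead label, e.g. `"MLII"`
#' @param record_id record identifier
#' @return an object of class `ecg_record`
#' @export
ecg_record <- function(samples, fs, lead = "I", record_id = "record") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite")
  }
  structure(
    list(samples = samples, fs = fs, lead = as.character(lead),
         record_id = as.character(record_id)),
    class = "ecg_record"
  )
}

# detectors refuse records shorter than 2 s
assert_detectable <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (length(rec$samples) < 2 * rec$fs) {
    stop("record too short: detectors need at least 2 s of signal")
  }
  invisible(rec)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s lead %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a set of wave annotations
#'
#' Carrier for reference or detected peak positions. Indices are 1-based
#' sample positions; each series must be strictly increasing, and when
#' `sig_len` is given every index must lie in `[1, sig_len]`.
#'
#' @param p_peaks P peak sample indices
#' @param t_peaks T peak sample indices (optional)
#' @param r_peaks R peak sample indices (optional)
#' @param source `"reference"` or `"detected"`
#' @param sig_len signal length used for bounds checking (optional)
#' @return an object of class `wave_annotations`
#' @export
wave_annotations <- function(p_peaks = integer(0), t_peaks = integer(0),
                             r_peaks = integer(0),
                             source = c("reference", "detected"),
                             sig_len = NULL) {
  source <- match.arg(source)
  chk <- function(v, nm) {
    v <- as.integer(v)
    if (anyNA(v)) stop(nm, " contains NA")
    if (is.unsorted(v, strictly = TRUE)) stop(nm, " must be strictly increasing")
    if (!is.null(sig_len) && length(v) && (min(v) < 1L || max(v) > sig_len)) {
      stop(nm, " indices outside [1, sig_len]")
    }
    v
  }
  structure(
    list(p_peaks = chk(p_peaks, "p_peaks"),
         t_peaks = chk(t_peaks, "t_peaks"),
         r_peaks = chk(r_peaks, "r_peaks"),
         source = source),
    class = "wave_annotations"
  )
}

#' @export
print.wave_annotations <- function(x, ...) {
  cat(sprintf("<wave_annotations> (%s) P: %d, T: %d, R: %d\n",
              x$source, length(x$p_peaks), length(x$t_peaks),
              length(x$r_peaks)))
  invisible(x)
}
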