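#' Detector configuration
#'
#' Collects every constant of the detection algorithm in one place. Defaults
#' are the published operating point of the method; each can be overridden,
#' either here or through a flat `key = value` config file (see
#' [read_config()]).
#'
#' @param rv_qrs phasor constant for QRS enhancement (dimensionless, in (0,1])
#' @param rv_t phasor constant for T wave search
#' @param rv_p phasor constant for P wave search
#' @param qrs_band QRS band-pass passband in Hz, length 2
#' @param slide_window sliding-maxima window for QRS candidates, seconds
#' @param std_window moving window for the adaptive threshold, seconds
#' @param rr_gap_factor RR ratio that triggers the backward search
#' @param back_thresh backward-search threshold as a fraction of the last
#'   detected QRS amplitude
#' @param refractory minimum distance between distinct QRS detections, seconds
#' @param t_win T search window coefficients `(a, b, c)`: the window is
#'   `R + a*RR` to `R + b*RR + c` seconds
#' @param pvc_win half-width of the QRS-area window, seconds
#' @param pvc_factor PVC rule: AUC must exceed this multiple of the running
#'   median of all previous beats
#' @param pvc_reset_frac if more than this fraction of all beats is flagged
#'   PVC, the flags are cleared (bundle-branch-block interpretation)
#' @param lynn_fc cut-off of the Lynn baseline-removal high-pass, Hz
#' @param sh_window word-window length (beats) for the Shannon entropy
#' @param sh_thresh normalized Shannon entropy threshold for AFIB
#' @param sh_pvc_override AFIB is suppressed when more than this many PVCs
#'   fall inside the entropy window
#' @param diss dissociated-P gate and window constants
#'   `(rr_ratio, rr_abs_s, rr_ratio_repeat, after_t_s, before_p_s)`
#' @param p_win normal P window coefficients `(a, b, c)`: the window is
#'   `R(i-1) + a*RR` to `R(i) - b*RR - c` seconds
#' @param first_p_win window for the first beat, seconds before R: `(left, right)`
#' @param up_factor voltage criterion: the P amplitude must exceed this
#'   fraction of the QRS amplitude
#' @param eval_tolerance beat-matching tolerance for evaluation, seconds
#' @param notch_hz powerline frequencies removed by [clean_ecg()], Hz
#' @param clean_enabled logical; set `FALSE` to bypass the generic
#'   pre-cleaning stage (Lynn high-pass + notch) entirely
#' @param seed integer seed used by stochastic helpers
#' @return a list of class `detector_config`
#' @export
detector_config <- function(rv_qrs = 0.001,
                            rv_t = 0.1,
                            rv_p = 0.05,
                            qrs_band = c(12, 19),
                            slide_window = 0.3,
                            std_window = 2,
                            rr_gap_factor = 1.75,
                            back_thresh = 0.3,
                            refractory = 0.2,
                            t_win = c(0.12, 0.57, 0.060),
                            pvc_win = 0.150,
                            pvc_factor = 1.3,
                            pvc_reset_frac = 0.75,
                            lynn_fc = 0.67,
                            sh_window = 59,
                            sh_thresh = 0.737,
                            sh_pvc_override = 30,
                            diss = c(1.6, 1.6, 0.8, 0.200, 0.400),
                            p_win = c(0.71, 0.07, 0.060),
                            first_p_win = c(0.300, 0.080),
                            up_factor = 0.05,
                            eval_tolerance = 0.100,
                            notch_hz = c(50, 60),
                            clean_enabled = TRUE,
                            seed = 1L) {
  cfg <- list(
    rv_qrs = rv_qrs, rv_t = rv_t, rv_p = rv_p,
    qrs_band = qrs_band, slide_window = slide_window, std_window = std_window,
    rr_gap_factor = rr_gap_factor, back_thresh = back_thresh,
    refractory = refractory,
    t_win = t_win, pvc_win = pvc_win, pvc_factor = pvc_factor,
    pvc_reset_frac = pvc_reset_frac, lynn_fc = lynn_fc,
    sh_window = sh_window, sh_thresh = sh_thresh,
    sh_pvc_override = sh_pvc_override,
    diss = diss, p_win = p_win, first_p_win = first_p_win,
    up_factor = up_factor, eval_tolerance = eval_tolerance,
    notch_hz = notch_hz, clean_enabled = clean_enabled,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$rv_qrs > 0, cfg$rv_qrs <= 1,
    cfg$rv_t > 0, cfg$rv_t <= 1,
    cfg$rv_p > 0, cfg$rv_p <= 1,
    length(cfg$qrs_band) == 2, all(cfg$qrs_band > 0), diff(cfg$qrs_band) > 0,
    cfg$slide_window > 0, cfg$std_window > 0,
    cfg$rr_gap_factor > 1, cfg$back_thresh > 0, cfg$refractory > 0,
    length(cfg$t_win) == 3, length(cfg$p_win) == 3,
    cfg$pvc_win > 0, cfg$pvc_factor > 0,
    cfg$pvc_reset_frac > 0, cfg$pvc_reset_frac <= 1,
    cfg$lynn_fc > 0, cfg$sh_window >= 3, cfg$sh_thresh > 0,
    length(cfg$diss) == 5, length(cfg$first_p_win) == 2,
    cfg$up_factor > 0, cfg$eval_tolerance > 0
  )
  class(cfg) <- "detector_config"
  cfg
}

#' Read a detector configuration from a flat key = value file
#'
#' Lines have the form `name = value` (`#` starts a comment). Vector-valued
#' keys use comma-separated values, e.g. `qrs_band = 12, 19`. Unknown keys
#' are an error; missing keys keep their defaults.
#'
#' @param path file path
#' @return a `detector_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- detector_config()
  over <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse config line: ", ln)
    key <- trimws(parts[1])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    val <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    if (key == "clean_enabled") {
      over[[key]] <- as.logical(val)
    } else {
      over[[key]] <- as.numeric(val)
    }
  }
  do.call(detector_config, over)
}

#' Write a detector configuration to a flat key = value file
#'
#' Round-trips through [read_config()].
#'
#' @param cfg a `detector_config`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "detector_config"))
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
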