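#' Phasor transform
#'
#' Maps each sample to the phase of the complex value `rv + 1i * x(n)`, i.e.
#' `PT(n) = atan(x(n) / rv)`. With `rv` well below the wave amplitudes the
#' transform strongly magnifies low-amplitude deflections while bounding the
#' output to (-pi/2, pi/2); because `atan` is strictly increasing, peak
#' positions are exactly preserved. Smaller `rv` means stronger enhancement.
#' The complex intermediate is never materialized.
#'
#' Stage-specific values live in [detector_config()]: `rv_qrs = 0.001` for QRS
#' detection, `rv_t = 0.1` for T waves and `rv_p = 0.05` for P waves.
#'
#' @param x numeric vector (finite)
#' @param rv phasor constant, in (0, 1]
#' @return phase signal in radians, same length as `x`
#' @export
phasor_transform <- function(x, rv) {
  if (!is.numeric(rv) || length(rv) != 1 || !is.finite(rv) || rv <= 0 || rv > 1) {
    stop("rv must be a single value in (0, 1]")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  atan(x / rv)
}
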