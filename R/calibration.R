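# Digital level calibration.
#
# A digital waveform carries no absolute sound pressure; the package fixes
# one convention — a digital RMS of 1.0 corresponds to `full_scale_spl`
# dB SPL (default 100) — and expresses every stimulus level against it.
# All level assertions in the package are then bit-testable.

#' Calibration convention
#'
#' @param full_scale_spl dB SPL assigned to a digital RMS of 1.0.
#' @return An object of class `calibration`.
#' @export
#' @examples
#' cal <- calibration()
#' measure_level(rep(1, 100), cal) # 100 dB SPL
calibration <- function(full_scale_spl = 100) {
  stopifnot(is.numeric(full_scale_spl), length(full_scale_spl) == 1)
  structure(list(full_scale_spl = full_scale_spl), class = "calibration")
}

#' Measure the level of a waveform in dB SPL
#'
#' `20 * log10(RMS(x)) + full_scale_spl`. An all-zero vector reports `-Inf`.
#'
#' @param x Numeric sample vector.
#' @param cal A [calibration()] object.
#' @return Level in dB SPL.
#' @export
measure_level <- function(x, cal = calibration()) {
  stopifnot(length(x) > 0)
  r <- sqrt(mean(x^2))
  if (r == 0) return(-Inf)
  20 * log10(r) + cal$full_scale_spl
}

# Target digital RMS for a level in dB SPL under `cal`.
level_to_rms <- function(level, cal = calibration()) {
  10^((level - cal$full_scale_spl) / 20)
}

# Scale a waveform so that its measured level equals `level` exactly.
scale_to_level <- function(x, level, cal = calibration()) {
  r <- sqrt(mean(x^2))
  if (r == 0) stop("cannot scale an all-zero waveform to a target level")
  x * level_to_rms(level, cal) / r
}
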