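#' Waveform container
#'
#' A mono audio waveform with phoneme-boundary marks and the four syllable
#' consonant/vowel (CV) spectral-transition reference points used as timing
#' anchors throughout the pipeline.
#'
#' @param samples numeric vector of pressure samples (arbitrary linear units).
#' @param rate_hz sampling rate in samples/second.
#' @param boundaries data.frame with columns `time_s` (strictly increasing,
#'   within the waveform) and `label` (phoneme label at that onset).
#' @param syllable_onsets numeric vector of exactly 4 ascending times (s); the
#'   first must be 0 (word-initial vowel onset).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz, boundaries = NULL, syllable_onsets = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate_hz > 0)
  rate_hz <- as.numeric(rate_hz)
  dur <- length(samples) / rate_hz
  if (is.null(boundaries)) {
    boundaries <- data.frame(time_s = numeric(0), label = character(0),
                             stringsAsFactors = FALSE)
  }
  if (nrow(boundaries) > 0) {
    if (any(diff(boundaries$time_s) <= 0))
      stop("phoneme boundaries must be strictly increasing")
    if (any(boundaries$time_s < 0) || any(boundaries$time_s > dur + 1 / rate_hz))
      stop("phoneme boundaries must lie within [0, duration]")
  }
  if (!is.null(syllable_onsets)) {
    if (length(syllable_onsets) != 4L)
      stop("exactly 4 syllable onsets are required")
    if (abs(syllable_onsets[1]) > 1 / rate_hz)
      stop("first syllable onset must be 0 (word-initial vowel onset)")
    if (any(diff(syllable_onsets) <= 0))
      stop("syllable onsets must be ascending")
  }
  structure(
    list(samples = as.numeric(samples), rate_hz = rate_hz,
         boundaries = boundaries, syllable_onsets = syllable_onsets),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f ms), %d boundaries\n",
              length(x$samples), x$rate_hz, 1000 * wave_duration(x),
              nrow(x$boundaries)))
  if (!is.null(x$syllable_onsets))
    cat("  syllable onsets (ms):",
        paste(sprintf("%.2f", 1000 * x$syllable_onsets), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate_hz

#' Root-mean-square level of a waveform
#' @param w a `waveform`.
#' @return RMS of the samples.
#' @export
wave_rms <- function(w) sqrt(mean(w$samples^2))

#' Mean inter-syllable-onset spacing
#'
#' The average syllable length of a stimulus, defined as the span from the
#' first to the fourth CV-transition reference point divided by the three
#' intervals. For the 375- and 300-ms stimuli this is 93.75 and 75.00 ms.
#'
#' @param w a `waveform` with syllable onsets.
#' @return mean spacing in milliseconds.
#' @export
syllable_spacing_ms <- function(w) {
  if (is.null(w$syllable_onsets)) stop("waveform carries no syllable onsets")
  1000 * (w$syllable_onsets[4] - w$syllable_onsets[1]) / 3
}

#' Scale a waveform to a target RMS level
#'
#' Applies a single positive gain so the output RMS equals `target_rms`;
#' used to keep all stimuli at a consistent average sound pressure.
#'
#' @param w a `waveform`; must not be all-zero.
#' @param target_rms desired RMS (> 0).
#' @return the rescaled `waveform` (metadata unchanged).
#' @export
normalize_level <- function(w, target_rms) {
  stopifnot(inherits(w, "waveform"), target_rms > 0)
  r <- wave_rms(w)
  if (r == 0) stop("cannot normalize an all-zero waveform (undefined gain)")
  w$samples <- w$samples * (target_rms / r)
  w
}

#' Acoustic delay of a sound-delivery tube
#'
#' Delay of sound travelling through a tube of given length, using the
#' linear approximation of sound speed in air, y = 331.5 + 0.6 x (m/s) with
#' x the temperature in degrees Celsius.
#'
#' @param tube_length_m tube length in meters (>= 0).
#' @param temperature_c air temperature in Celsius, within -40..60.
#' @return delay in milliseconds.
#' @export
tube_delay_ms <- function(tube_length_m, temperature_c = 20) {
  if (tube_length_m < 0) stop("tube length must be non-negative")
  if (temperature_c < -40 || temperature_c > 60)
    stop("temperature outside physical range (-40..60 C)")
  1000 * tube_length_m / (331.5 + 0.6 * temperature_c)
}
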