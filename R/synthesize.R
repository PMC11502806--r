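#' Synthesize the four-syllable VCVCVCV test word
#'
#' Formant-synthesizes a /atataka/-like word: voiced /a/ segments are a glottal
#' impulse train shaped by cascaded formant resonators; the plosives /t/ and
#' /k/ are a closure silence followed by a short band-passed noise burst. The
#' word is laid out as seven phonemes (V,C,V,C,V,C,V) grouped into four
#' syllables (V, CV, CV, CV) whose vowel onsets -- the CV spectral-transition
#' reference points -- fall at exact quarters of the word, so the mean
#' inter-onset spacing of a word of duration d is d/4.
#'
#' Within each of the first three quarters the vowel occupies the leading
#' portion and the following plosive (closure then burst) the tail, so the
#' next quarter opens with the burst-to-vowel transition. At the 600-ms base
#' duration the closure is 60 ms (40% of the 150-ms syllable period) and the
#' burst 10 ms. The vowel is faded into the closure so the strongest spectral
#' transition is the consonant-to-vowel one.
#'
#' @param rate_hz audio sampling rate (default 16000).
#' @param duration_s total word duration in seconds (> 0; default 0.6).
#' @param f0_hz fundamental frequency of voicing (> 0; default 120).
#' @param formants formant frequencies in Hz for /a/ (all below Nyquist).
#' @param murmur closure voice-bar level relative to the vowel (default 0.15):
#'   the closure keeps the vowel's spectral envelope at low amplitude, so the
#'   strong spectral transitions are confined to the consonant releases.
#' @return a `waveform` with 7 phoneme boundaries and 4 syllable onsets.
#' @export
synthesize_base_word <- function(rate_hz = 16000, duration_s = 0.6,
                                 f0_hz = 120,
                                 formants = c(800, 1200, 2600),
                                 murmur = 0.15) {
  if (rate_hz <= 0) stop("invalid sampling rate")
  if (duration_s <= 0) stop("duration must be positive")
  if (f0_hz <= 0) stop("voicing requires f0 > 0")
  if (any(formants >= rate_hz / 2)) stop("formant frequency at or above Nyquist")

  L <- duration_s / 4                      # syllable period
  n <- round(duration_s * rate_hz)
  x <- numeric(n)
  at <- function(t) pmin(pmax(round(t * rate_hz) + 1L, 1L), n)

  # phoneme layout (fractions of the syllable period): vowel 8/15,
  # closure 6/15 (40%), burst 1/15 (10 ms at the 600-ms base)
  vow_frac <- 8 / 15; clo_frac <- 6 / 15; bur_frac <- 1 / 15
  consonants <- c("t", "t", "k")
  bounds <- data.frame(time_s = numeric(0), label = character(0),
                       stringsAsFactors = FALSE)
  add_bound <- function(t, lab)
    rbind(bounds, data.frame(time_s = t, label = lab, stringsAsFactors = FALSE))

  for (k in 1:4) {
    syl0 <- (k - 1) * L
    v_end <- if (k < 4) syl0 + vow_frac * L else 4 * L
    # voiced segment runs through the following closure as a low-level
    # voice-bar murmur: the spectral envelope shape is continuous across the
    # vowel offset (amplitude alone carries no envelope change), so the only
    # sharp spectral transitions are the consonant-release-to-vowel ones
    seg_end <- if (k < 4) k * L - bur_frac * L else 4 * L
    seg <- vowel_segment(seg_end - syl0, rate_hz, f0_hz, formants,
                         sustain_s = v_end - syl0,
                         murmur = if (k < 4) murmur else 0)
    idx <- at(syl0):(at(syl0) + length(seg) - 1L)
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + seg[seq_along(idx)]
    bounds <- add_bound(syl0, "a")
    if (k < 4) {
      c_start <- v_end                      # closure onset
      b_start <- syl0 + (vow_frac + clo_frac) * L
      b_end <- k * L
      band <- if (consonants[k] == "t") c(2500, 4500) else c(1000, 2500)
      burst <- burst_segment(b_end - b_start, rate_hz, band)
      idx <- at(b_start):(at(b_start) + length(burst) - 1L)
      idx <- idx[idx <= n]
      x[idx] <- x[idx] + burst[seq_along(idx)]
      bounds <- add_bound(c_start, consonants[k])
    }
  }

  onsets <- (0:3) * L
  waveform(x, rate_hz, boundaries = bounds, syllable_onsets = onsets)
}

# Voiced /a/: impulse train through cascaded 2nd-order formant resonators.
# The segment sustains at full level for sustain_s, then fades over ~10 ms to
# `murmur` (a voice-bar level held through the closure; 0 = fade to silence).
vowel_segment <- function(dur_s, rate_hz, f0_hz, formants,
                          sustain_s = dur_s, murmur = 0) {
  n <- max(round(dur_s * rate_hz), 1L)
  period <- max(round(rate_hz / f0_hz), 1L)
  src <- numeric(n)
  src[seq(1L, n, by = period)] <- 1
  bw <- c(80, 90, 120)[seq_along(formants)]
  y <- src
  for (j in seq_along(formants)) {
    r <- exp(-pi * bw[j] / rate_hz)
    th <- 2 * pi * formants[j] / rate_hz
    y <- stats::filter(y, c(2 * r * cos(th), -r^2), method = "recursive")
    y <- as.numeric(y)
  }
  env <- rep(1, n)
  n_att <- min(round(0.010 * rate_hz), n)
  env[seq_len(n_att)] <- seq(0, 1, length.out = n_att)
  n_sus <- min(max(round(sustain_s * rate_hz), n_att), n)
  n_fade <- min(round(0.010 * rate_hz), n - n_sus)
  if (n_sus < n) {
    if (n_fade > 0)
      env[(n_sus + 1L):(n_sus + n_fade)] <- seq(1, murmur, length.out = n_fade)
    if (n_sus + n_fade < n) env[(n_sus + n_fade + 1L):n] <- murmur
  } else {
    n_dec <- min(round(0.040 * rate_hz), n)
    env[(n - n_dec + 1L):n] <- env[(n - n_dec + 1L):n] * seq(1, 0, length.out = n_dec)
  }
  y <- y * env
  y / max(abs(y), .Machine$double.eps)
}

# Plosive release burst: band-passed white noise with a fast decay envelope.
burst_segment <- function(dur_s, rate_hz, band_hz) {
  n <- max(round(dur_s * rate_hz), 4L)
  # fixed noise texture, without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(sum(band_hz))
  noise <- stats::rnorm(n + 64)
  bf <- signal::butter(2, band_hz / (rate_hz / 2), type = "pass")
  y <- signal::filter(bf, noise)
  y <- as.numeric(y)[-(1:64)]
  env <- exp(-seq(0, 5, length.out = n))
  y <- y[seq_len(n)] * env
  0.5 * y / max(abs(y), .Machine$double.eps)
}

#' Time-stretch a waveform, preserving its spectral envelope
#'
#' Waveform-similarity overlap-add (WSOLA) time-scale modification: output
#' frames are copied from input positions advanced at the reciprocal rate,
#' with each copy position refined within a small tolerance to maximize
#' waveform continuity with the frame already laid down. Local waveform shape
#' -- hence the short-time spectral envelope and formant structure -- is
#' preserved while the duration changes. Boundary and syllable-onset metadata
#' are scaled exactly by the stretch factor.
#'
#' @param w a `waveform`.
#' @param target_duration_s desired output duration (> 0).
#' @param frame_len overlap-add window length in samples (default 240, i.e.
#'   15 ms at 16 kHz; the synthesis hop is `frame_len / 2`).
#' @param tol_s search tolerance for the similarity alignment, in seconds
#'   (default 0.0045, about half a fundamental period).
#' @return the stretched `waveform`; output length equals
#'   `round(target_duration_s * rate_hz)`.
#' @export
time_stretch <- function(w, target_duration_s, frame_len = 240, tol_s = 0.0045) {
  stopifnot(inherits(w, "waveform"))
  if (target_duration_s <= 0) stop("target duration must be positive")
  src_dur <- wave_duration(w)
  alpha <- target_duration_s / src_dur
  scale_meta <- function(w2) {
    if (nrow(w2$boundaries) > 0) w2$boundaries$time_s <- w2$boundaries$time_s * alpha
    if (!is.null(w2$syllable_onsets)) w2$syllable_onsets <- w2$syllable_onsets * alpha
    w2
  }
  n_out <- round(target_duration_s * w$rate_hz)
  if (abs(alpha - 1) < 1e-12) return(scale_meta(w))

  hop_s <- frame_len %/% 2L
  tol <- max(round(tol_s * w$rate_hz), 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))  # Hann
  x <- c(w$samples, numeric(frame_len + tol))
  n_in <- length(w$samples)
  n_frames <- ceiling(n_out / hop_s) + 1L
  y <- numeric(n_out + 2L * frame_len)
  wsum <- numeric(length(y))
  prev_start <- NA_integer_
  for (k in seq_len(n_frames)) {
    out0 <- (k - 1L) * hop_s                      # 0-based output start
    target <- round(out0 / alpha) + 1L            # natural input position
    target <- min(max(target, 1L), n_in)
    if (k == 1L || is.na(prev_start)) {
      start <- target
    } else {
      # natural continuation of the previous copied frame
      natural <- prev_start + hop_s
      lo <- max(target - tol, 1L)
      hi <- min(target + tol, n_in)
      ref <- x[natural:(natural + hop_s - 1L)]
      best <- lo; best_cc <- -Inf
      for (cand in seq(lo, hi, by = max(1L, tol %/% 24L))) {
        cc <- sum(ref * x[cand:(cand + hop_s - 1L)])
        if (cc > best_cc) { best_cc <- cc; best <- cand }
      }
      start <- best
    }
    idx_out <- (out0 + 1L):(out0 + frame_len)
    y[idx_out] <- y[idx_out] + x[start:(start + frame_len - 1L)] * win
    wsum[idx_out] <- wsum[idx_out] + win
    prev_start <- start
  }
  y <- y / pmax(wsum, 1e-6)
  y <- if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))

  w2 <- w
  w2$samples <- y
  scale_meta(w2)
}

#' Generate the full time-stretched stimulus set
#'
#' Synthesizes the base word at the longest requested duration and
#' time-stretches it down to every other duration (increasing the speech
#' rate while preserving the phonological structure), then normalizes all
#' stimuli to the same RMS level.
#'
#' @param durations_ms positive, distinct durations in ms; the default eight
#'   span 75 to 600 ms in steps of 75.
#' @param rate_hz audio sampling rate.
#' @param target_rms common RMS level for all stimuli.
#' @param ... further arguments to [synthesize_base_word()].
#' @return a named list of `waveform`s (names are the durations in ms).
#' @export
generate_stimulus_set <- function(durations_ms = seq(75, 600, by = 75),
                                  rate_hz = 16000, target_rms = 0.1, ...) {
  if (length(durations_ms) == 0) stop("empty duration list")
  if (any(durations_ms <= 0)) stop("durations must be positive")
  if (anyDuplicated(durations_ms)) stop("durations must be distinct")
  base_ms <- max(durations_ms)
  base <- synthesize_base_word(rate_hz = rate_hz, duration_s = base_ms / 1000, ...)
  out <- lapply(durations_ms, function(d) {
    s <- if (d == base_ms) base else time_stretch(base, d / 1000)
    normalize_level(s, target_rms)
  })
  names(out) <- as.character(durations_ms)
  out
}
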