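#' Framewise real-cepstrum analysis of a waveform
#'
#' Computes, for Hamming-windowed frames at a fixed hop, the real cepstrum
#' (inverse DFT of the log magnitude spectrum) and keeps coefficients
#' C_1..C_N; the 0th (energy) coefficient is excluded. Low-order coefficients
#' encode the spectral envelope, so their trajectory tracks formant structure
#' through the word.
#'
#' @param w a `waveform`.
#' @param frame_ms frame length in ms (default 25).
#' @param hop_ms hop between frame starts in ms (default 5).
#' @param n_coeffs number of cepstral coefficients N (default 12).
#' @return a `cepstral_track`: list with `frame_times` (s, frame centers),
#'   `coeffs` (frames x N matrix), `n_coeffs`, `hop_s`, and `dynamic`
#'   (NULL until [dynamic_measure()] is applied).
#' @export
cepstral_analysis <- function(w, frame_ms = 25, hop_ms = 5, n_coeffs = 12) {
  stopifnot(inherits(w, "waveform"))
  if (frame_ms <= 0 || hop_ms <= 0) stop("frame and hop must be positive")
  if (n_coeffs < 1) stop("need at least one cepstral coefficient")
  flen <- round(frame_ms / 1000 * w$rate_hz)
  hop <- max(round(hop_ms / 1000 * w$rate_hz), 1L)
  x <- w$samples
  if (length(x) < flen) stop("waveform shorter than one analysis frame")
  nfft <- 2^ceiling(log2(flen))
  if (n_coeffs >= nfft) stop("too many coefficients for the frame length")
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))  # Hamming
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  floor_mag <- 1e-8 * max(abs(x), .Machine$double.eps)
  coeffs <- matrix(0, nrow = length(starts), ncol = n_coeffs)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + flen - 1L)] * win
    mag <- Mod(stats::fft(c(fr, numeric(nfft - flen))))
    cep <- Re(stats::fft(log(pmax(mag, floor_mag)), inverse = TRUE)) / nfft
    coeffs[i, ] <- cep[2:(n_coeffs + 1L)]
  }
  structure(
    list(frame_times = (starts - 1L + flen / 2) / w$rate_hz,
         coeffs = coeffs, n_coeffs = n_coeffs, hop_s = hop / w$rate_hz,
         dynamic = NULL),
    class = "cepstral_track")
}

#' @export
print.cepstral_track <- function(x, ...) {
  cat(sprintf("<cepstral_track> %d frames x %d coefficients, hop %.1f ms%s\n",
              nrow(x$coeffs), x$n_coeffs, 1000 * x$hop_s,
              if (is.null(x$dynamic)) "" else sprintf(", dynamic (%s)", x$variant)))
  invisible(x)
}

#' Dynamic measure D(t) of a cepstral track
#'
#' Two variants are provided. `"as_printed"` is the sum of the squared
#' cepstral coefficients themselves, D(t) = sum_i C_i(t)^2 -- a static
#' envelope-magnitude quantity. `"delta"` (the default for transition
#' detection) squares and sums the least-squares regression slopes of each
#' C_i over a centered window -- the classical spectral-transition measure,
#' which peaks where the spectral envelope changes fastest, i.e. at
#' consonant/vowel transitions.
#'
#' @param track a `cepstral_track` from [cepstral_analysis()].
#' @param variant `"delta"` or `"as_printed"`.
#' @param reg_halfwidth half-width (frames) of the delta regression window.
#' @return the track with `dynamic` populated (non-negative per frame).
#' @export
dynamic_measure <- function(track, variant = c("delta", "as_printed"),
                            reg_halfwidth = 2L) {
  stopifnot(inherits(track, "cepstral_track"))
  variant <- match.arg(variant)
  C <- track$coeffs
  if (variant == "as_printed") {
    track$dynamic <- rowSums(C^2)
  } else {
    K <- reg_halfwidth
    n <- nrow(C)
    # pad by edge replication so slopes are defined at the ends
    Cp <- rbind(C[rep(1L, K), , drop = FALSE], C, C[rep(n, K), , drop = FALSE])
    denom <- sum((-K:K)^2)
    slopes <- matrix(0, n, ncol(C))
    for (k in -K:K) {
      if (k == 0) next
      slopes <- slopes + k * Cp[(K + 1 + k):(K + n + k), , drop = FALSE]
    }
    slopes <- slopes / denom
    track$dynamic <- rowSums(slopes^2)
  }
  track$variant <- variant
  track
}

#' Locate spectral-transition time references from the dynamic measure
#'
#' Lightly smooths D(t) (3-frame moving average), finds local maxima, and
#' greedily keeps the `n_expected` highest subject to a minimum separation.
#' These serve as the syllable CV-transition reference points from which
#' expected M100 latencies are derived.
#'
#' @param track a `cepstral_track` with `dynamic` populated.
#' @param n_expected number of transitions to return (>= 1).
#' @param min_separation_ms minimum spacing between accepted peaks (default
#'   30; callers analyzing a stretched stimulus should scale it by the
#'   stretch factor).
#' @return ascending vector of `n_expected` transition times (s).
#' @export
find_transitions <- function(track, n_expected, min_separation_ms = 30) {
  stopifnot(inherits(track, "cepstral_track"))
  if (is.null(track$dynamic)) stop("dynamic measure not computed; call dynamic_measure()")
  if (n_expected < 1) stop("n_expected must be >= 1")
  d <- track$dynamic
  n <- length(d)
  if (n_expected > n) stop(sprintf("requested %d transitions but only %d frames", n_expected, n))
  ds <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  ds[1] <- d[1]; ds[n] <- d[n]
  ds <- as.numeric(ds)
  is_peak <- which(ds[2:(n - 1)] > ds[1:(n - 2)] & ds[2:(n - 1)] >= ds[3:n]) + 1L
  if (length(is_peak) == 0) stop("no local maxima found in the dynamic measure")
  ord <- is_peak[order(ds[is_peak], decreasing = TRUE)]
  min_sep_s <- min_separation_ms / 1000
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == n_expected) break
    if (all(abs(track$frame_times[i] - track$frame_times[picked]) >= min_sep_s))
      picked <- c(picked, i)
  }
  if (length(picked) < n_expected)
    stop(sprintf("found only %d qualifying transition peaks (%d requested)",
                 length(picked), n_expected))
  sort(track$frame_times[picked])
}
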