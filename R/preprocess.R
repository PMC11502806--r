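#' Reject artifact epochs by amplitude threshold
#'
#' Removes every epoch whose maximum absolute value over all channels and
#' samples exceeds the threshold (default 3000 fT/cm), preserving order.
#'
#' @param e an `epoch_set`.
#' @param threshold_ft_cm rejection threshold (> 0, default 3000).
#' @return the `epoch_set` with offending epochs removed; the number removed
#'   is stored in `attr(, "n_rejected")`.
#' @export
reject_epochs <- function(e, threshold_ft_cm = 3000) {
  stopifnot(inherits(e, "epoch_set"), threshold_ft_cm > 0)
  ne <- dim(e$data)[1]
  peak <- vapply(seq_len(ne), function(i) max(abs(e$data[i, , ])), numeric(1))
  keep <- peak <= threshold_ft_cm
  if (!any(keep)) stop("all epochs exceed the rejection threshold")
  e$data <- e$data[keep, , , drop = FALSE]
  attr(e, "n_rejected") <- sum(!keep)
  e
}

#' Average epochs into an evoked response
#'
#' Pointwise mean across epochs. A warning is logged (not raised as an error)
#' when fewer than `min_epochs` survivors are averaged, reflecting the
#' at-least-100-artifact-free-epochs acquisition requirement.
#'
#' @param e an `epoch_set` with at least one epoch.
#' @param min_epochs minimum expected epoch count (default 100).
#' @return an `evoked`: list with `data` (n_channels x n_times, fT/cm),
#'   `times_ms`, `rate_hz`, `t0_ms`, `n_epochs_averaged`, `processing_log`.
#' @export
average_epochs <- function(e, min_epochs = 100) {
  stopifnot(inherits(e, "epoch_set"))
  ne <- dim(e$data)[1]
  if (ne < 1) stop("cannot average an empty epoch set")
  avg <- colMeans(e$data, dims = 1)
  log <- c(sprintf("reject: %d epochs removed",
                   if (is.null(attr(e, "n_rejected"))) 0L else attr(e, "n_rejected")),
           sprintf("average: %d epochs", ne))
  if (ne < min_epochs) {
    warning(sprintf("only %d artifact-free epochs averaged (< %d)", ne, min_epochs))
    log <- c(log, sprintf("warning: below the %d-epoch requirement", min_epochs))
  }
  structure(list(data = avg, times_ms = e$times_ms, rate_hz = e$rate_hz,
                 t0_ms = e$t0_ms, n_epochs_averaged = ne,
                 processing_log = log),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %d channels x %d samples, %d epochs averaged\n",
              nrow(x$data), ncol(x$data), x$n_epochs_averaged))
  for (s in x$processing_log) cat("  -", s, "\n")
  invisible(x)
}

#' Band-pass and notch filter an evoked response
#'
#' Zero-phase filtering per channel: the channel mean is removed, then a
#' 4th-order Butterworth band-pass (default 1.0-75 Hz) is applied
#' forward-backward, then a biquad notch (default 60 Hz, Q = 10) likewise.
#' Zero phase preserves the peak latencies the detection stage depends on.
#' Channels are reflect-padded to suppress edge transients; the notch Q is
#' chosen so its ringing decays well within the epoch.
#'
#' @param ev an `evoked`.
#' @param band_hz length-2 band edges, 0 < low < high < rate/2.
#' @param notch_hz notch center (NULL to skip).
#' @param notch_q notch quality factor.
#' @return the filtered `evoked`.
#' @export
filter_evoked <- function(ev, band_hz = c(1, 75), notch_hz = 60, notch_q = 10) {
  stopifnot(inherits(ev, "evoked"))
  ny <- ev$rate_hz / 2
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= ny)
    stop("invalid band: need 0 < low < high < rate/2")
  bp <- signal::butter(4, band_hz / ny, type = "pass")
  filters <- list(list(b = bp$b, a = bp$a))
  if (!is.null(notch_hz)) {
    w0 <- 2 * pi * notch_hz / ev$rate_hz
    alp <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alp)
    a <- c(1, -2 * cos(w0) / (1 + alp), (1 - alp) / (1 + alp))
    filters <- c(filters, list(list(b = b, a = a)))
  }
  npad <- min(500L, ncol(ev$data) - 1L)
  ev$data <- t(apply(ev$data, 1, function(x) {
    x <- x - mean(x)          # the band-pass has zero DC gain; remove it up front
    xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(length(x) - npad):(length(x) - 1)]))
    for (f in filters) xp <- zero_phase(f$b, f$a, xp)
    xp[(npad + 1):(npad + length(x))]
  }))
  ev$processing_log <- c(ev$processing_log,
                         sprintf("filter: band-pass %g-%g Hz%s, zero phase",
                                 band_hz[1], band_hz[2],
                                 if (is.null(notch_hz)) ""
                                 else sprintf(" + %g Hz notch (Q=%g)", notch_hz, notch_q)))
  ev
}

# forward-backward IIR pass (classic zero-phase realization)
zero_phase <- function(b, a, x) {
  y <- signal::filter(b, a, x)
  rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
}

#' Baseline-correct an evoked response
#'
#' Subtracts, per channel, the mean over the pre-stimulus DC baseline window
#' (default -100..0 ms).
#'
#' @param ev an `evoked`.
#' @param window_ms length-2 baseline window (must lie inside the epoch).
#' @return the baselined `evoked`.
#' @export
baseline_correct <- function(ev, window_ms = c(-100, 0)) {
  stopifnot(inherits(ev, "evoked"))
  if (window_ms[1] < min(ev$times_ms) || window_ms[2] > max(ev$times_ms) ||
      window_ms[2] <= window_ms[1])
    stop("baseline window outside the epoch span")
  sel <- ev$times_ms >= window_ms[1] & ev$times_ms <= window_ms[2]
  ev$data <- ev$data - rowMeans(ev$data[, sel, drop = FALSE])
  ev$processing_log <- c(ev$processing_log,
                         sprintf("baseline: DC over %g..%g ms removed",
                                 window_ms[1], window_ms[2]))
  ev
}

#' Canonical preprocessing chain
#'
#' Applies the analysis pipeline in its fixed order: epoch rejection,
#' selective averaging, zero-phase band-pass + notch filtering of the
#' average, DC baseline correction.
#'
#' @param e an `epoch_set`.
#' @param threshold_ft_cm rejection threshold.
#' @param min_epochs expected artifact-free epoch count.
#' @param band_hz,notch_hz filter settings.
#' @param baseline_ms baseline window.
#' @return an `evoked`.
#' @export
preprocess_epochs <- function(e, threshold_ft_cm = 3000, min_epochs = 100,
                              band_hz = c(1, 75), notch_hz = 60,
                              baseline_ms = c(-100, 0)) {
  ev <- average_epochs(reject_epochs(e, threshold_ft_cm), min_epochs)
  baseline_correct(filter_evoked(ev, band_hz, notch_hz), baseline_ms)
}
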