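#' Select the channel with the largest response in a hemisphere
#'
#' Returns the channel of the given hemisphere maximizing peak-to-peak
#' amplitude within the search window (default 50-150 ms, bracketing the
#' first M50/M100 complex). Ties break to the lowest channel index.
#'
#' @param ev an `evoked`.
#' @param array the `sensor_array` the evoked was recorded with.
#' @param hemisphere `"left"` or `"right"`.
#' @param window_ms length-2 search window (ms).
#' @return the selected channel index (into `array$channels`).
#' @export
select_channel <- function(ev, array, hemisphere = c("left", "right"),
                           window_ms = c(50, 150)) {
  stopifnot(inherits(ev, "evoked"), inherits(array, "sensor_array"))
  hemisphere <- match.arg(hemisphere)
  chans <- which(array$channels$hemisphere == hemisphere)
  if (length(chans) == 0) stop("no channels in that hemisphere")
  sel <- ev$times_ms >= window_ms[1] & ev$times_ms <= window_ms[2]
  ptp <- apply(ev$data[chans, sel, drop = FALSE], 1, function(x) max(x) - min(x))
  chans[which.max(ptp)]    # which.max returns the first (lowest-index) tie
}

#' Find the first M100 component on a channel
#'
#' The M100 to the word onset: the extremum of largest absolute amplitude in
#' the search window (default 60-160 ms). The preceding opposite-polarity
#' extremum (M50) is sought up to 60 ms before the peak; if none exists, the
#' amplitude difference falls back to the peak amplitude alone (logged via
#' `m50_found`). Significance is not assessed here (see
#' [test_significance()]).
#'
#' @param ev an `evoked`.
#' @param channel channel row index.
#' @param search_ms length-2 search window (ms).
#' @return a one-row data.frame (an M100 component record): `index`,
#'   `channel_id`, `peak_latency_ms`, `peak_amplitude_ft_cm`,
#'   `m50_latency_ms`, `m50_amplitude_ft_cm`, `delta_amplitude`, `m50_found`,
#'   `expected_latency_ms`, `window_lo_ms`, `window_hi_ms`, `significant`.
#' @export
find_m100_1 <- function(ev, channel, search_ms = c(60, 160)) {
  stopifnot(inherits(ev, "evoked"))
  x <- ev$data[channel, ]
  t <- ev$times_ms
  sel <- which(t >= search_ms[1] & t <= search_ms[2])
  if (length(sel) < 3) stop("search window outside the epoch")
  if (all(abs(x[sel]) < .Machine$double.eps))
    stop("flat signal in the M100 search window")
  i_pk <- sel[which.max(abs(x[sel]))]
  pol <- sign(x[i_pk])
  m50 <- find_m50(x, t, i_pk, pol, lo_ms = t[i_pk] - 60)
  delta <- if (!is.na(m50$amp)) abs(x[i_pk] - m50$amp) else abs(x[i_pk])
  data.frame(index = 1L, channel_id = channel,
             peak_latency_ms = t[i_pk], peak_amplitude_ft_cm = x[i_pk],
             m50_latency_ms = m50$lat, m50_amplitude_ft_cm = m50$amp,
             delta_amplitude = delta, m50_found = m50$found,
             expected_latency_ms = mean(search_ms),
             window_lo_ms = search_ms[1], window_hi_ms = search_ms[2],
             significant = NA)
}

# Preceding M50 reference in [lo_ms, peak): the deepest excursion away from
# the peak's polarity (the valley between this peak and what precedes it).
# When that valley crosses zero it is a genuine polarity-reversed M50
# (found = TRUE); otherwise it is the preceding trough, so a deflection
# riding on another component's flank has only its own wiggle as
# peak-to-reference difference and is not counted as a distinct component.
find_m50 <- function(x, t, i_pk, pol, lo_ms) {
  sel <- which(t >= lo_ms & t < t[i_pk])
  if (length(sel) == 0)
    return(list(found = FALSE, lat = NA_real_, amp = NA_real_))
  i_tr <- sel[which.min(x[sel] * pol)]
  list(found = x[i_tr] * pol < 0, lat = t[i_tr], amp = x[i_tr])
}

#' Expected M100 latencies for syllables 2-4
#'
#' With the first M100 latency as reference, the expected peak latency of the
#' k-th syllable's M100 is the syllable's CV-transition time plus that
#' reference latency; search windows are the expectation +/- 20 ms.
#'
#' @param m100_1_latency_ms latency of the first M100 (ms).
#' @param syllable_onsets_ms 4 ascending onset times (ms), first 0.
#' @return numeric vector of 3 expected latencies (syllables 2-4).
#' @export
expected_latencies <- function(m100_1_latency_ms, syllable_onsets_ms) {
  if (length(syllable_onsets_ms) != 4) stop("need 4 syllable onsets")
  if (any(diff(syllable_onsets_ms) <= 0)) stop("syllable onsets must be ascending")
  if (abs(syllable_onsets_ms[1]) > 1e-9) stop("first syllable onset must be 0")
  syllable_onsets_ms[2:4] + m100_1_latency_ms
}

#' Apply the 4-SD significance rule to a component
#'
#' A component is significant when (a) the amplitude difference between its
#' peak and the preceding polarity-reversed (M50) deflection strictly exceeds
#' `k_sd` standard deviations of the pre-stimulus baseline, and (b) the peak
#' amplitude itself also exceeds `k_sd` baseline SDs. Both conditions come
#' from the component definition (the M50-difference criterion and the
#' amplitude-from-baseline criterion); requiring both keeps the
#' false-positive rate of the rule on source-free data low, because a
#' peak-to-trough difference of band-limited noise spans 4 SD far more
#' easily than a single noise peak does.
#'
#' @param comp a component record (one-row data.frame).
#' @param baseline_sd_ft_cm baseline SD (> 0).
#' @param k_sd multiplier (default 4).
#' @return the record with `significant` set and `baseline_sd`, `k_sd` stored.
#' @export
test_significance <- function(comp, baseline_sd_ft_cm, k_sd = 4) {
  stopifnot(baseline_sd_ft_cm > 0)
  comp$baseline_sd <- baseline_sd_ft_cm
  comp$k_sd <- k_sd
  comp$significant <- !is.na(comp$delta_amplitude) &
    comp$delta_amplitude > k_sd * baseline_sd_ft_cm &
    (is.na(comp$peak_amplitude_ft_cm) |
       abs(comp$peak_amplitude_ft_cm) > k_sd * baseline_sd_ft_cm)
  comp
}

#' Detect and count the M100 components on one channel
#'
#' Finds M100_1 in its search window, derives the expected latencies of
#' M100_2..4 from the syllable CV-transition times, and within each +/- 20 ms
#' window searches for a genuine local extremum of the same polarity as
#' M100_1 (later responses go in the same direction as the first). Because
#' the later components are defined with reference to M100_1, they are only
#' eligible for significance when M100_1 itself is significant. Each
#' component's M50 reference is the deepest opposite-direction excursion
#' between the previous counted peak and this one (at most 60 ms back), so
#' consecutive components are separated by their intervening valley.
#' Significance uses the `k_sd` x baseline SD rule with the SD of the
#' channel's pre-stimulus samples.
#'
#' @param ev an `evoked` (filtered and baselined).
#' @param channel channel row index.
#' @param syllable_onsets_ms 4 ascending onset times (ms), first 0.
#' @param search_ms M100_1 search window.
#' @param window_halfwidth_ms half-width of the M100_2..4 windows (default 20).
#' @param k_sd significance multiplier (default 4).
#' @param baseline_ms baseline window for the SD (default -100..0).
#' @param baseline_sd pre-computed baseline SD (fT/cm); when NULL (default)
#'   the SD of the channel's own pre-stimulus samples is used. Passing a
#'   hemisphere-pooled SD gives a more stable noise estimate when channels
#'   share a common noise level.
#' @return list with `components` (4-row data.frame), `n_significant`,
#'   `baseline_sd`, `channel`.
#' @export
count_m100 <- function(ev, channel, syllable_onsets_ms, search_ms = c(60, 160),
                       window_halfwidth_ms = 20, k_sd = 4,
                       baseline_ms = c(-100, 0), baseline_sd = NULL) {
  stopifnot(inherits(ev, "evoked"))
  t <- ev$times_ms
  x <- ev$data[channel, ]
  bsel <- t >= baseline_ms[1] & t <= baseline_ms[2]
  if (is.null(baseline_sd)) baseline_sd <- stats::sd(x[bsel])
  c1 <- find_m100_1(ev, channel, search_ms)
  c1 <- test_significance(c1, baseline_sd, k_sd)
  pol <- sign(c1$peak_amplitude_ft_cm)
  expected <- expected_latencies(c1$peak_latency_ms, syllable_onsets_ms)
  comps <- c1
  claimed <- which(t == c1$peak_latency_ms)   # peaks already attributed
  for (k in 2:4) {
    exp_k <- expected[k - 1]
    wlo <- exp_k - window_halfwidth_ms
    whi <- min(exp_k + window_halfwidth_ms, max(t))
    sel <- which(t >= wlo & t <= whi)
    sel <- sel[sel > 1 & sel < length(x)]
    # same-polarity local extrema only: a merged ridge without its own peak
    # does not count as a component
    cand <- sel[x[sel] * pol > 0 &
                  ((x[sel] - x[sel - 1]) * (x[sel + 1] - x[sel]) <= 0)]
    # a peak already attributed to an earlier component is not a new one
    cand <- cand[!cand %in% claimed]
    if (length(cand) == 0) {
      ck <- data.frame(index = k, channel_id = channel,
                       peak_latency_ms = NA_real_, peak_amplitude_ft_cm = NA_real_,
                       m50_latency_ms = NA_real_, m50_amplitude_ft_cm = NA_real_,
                       delta_amplitude = NA_real_, m50_found = FALSE,
                       expected_latency_ms = exp_k,
                       window_lo_ms = wlo, window_hi_ms = whi,
                       significant = FALSE, baseline_sd = baseline_sd, k_sd = k_sd)
      comps <- rbind(comps, ck)
      next
    }
    i_pk <- cand[which.max(abs(x[cand]))]
    # M50 search floor: just after the last counted peak, so the reference
    # valley separates this component from the previous one
    prev_t <- t[claimed[length(claimed)]]
    m50_lo <- max(t[i_pk] - 60, prev_t + 1)
    m50 <- find_m50(x, t, i_pk, pol, m50_lo)
    delta <- if (!is.na(m50$amp)) abs(x[i_pk] - m50$amp) else abs(x[i_pk])
    claimed <- c(claimed, i_pk)
    ck <- data.frame(index = k, channel_id = channel,
                     peak_latency_ms = t[i_pk], peak_amplitude_ft_cm = x[i_pk],
                     m50_latency_ms = m50$lat, m50_amplitude_ft_cm = m50$amp,
                     delta_amplitude = delta, m50_found = m50$found,
                     expected_latency_ms = exp_k,
                     window_lo_ms = wlo, window_hi_ms = whi,
                     significant = NA)
    ck <- test_significance(ck, baseline_sd, k_sd)
    if (!c1$significant) ck$significant <- FALSE   # no reference response
    comps <- rbind(comps, ck)
  }
  list(components = comps, n_significant = sum(comps$significant),
       baseline_sd = baseline_sd, channel = channel)
}

#' Detect M100 counts for both hemispheres
#'
#' Runs [select_channel()] and [count_m100()] per hemisphere and combines the
#' two counts as their maximum (a component is counted if either hemisphere
#' resolves it). The baseline SD is pooled over the hemisphere's channels
#' (the array's channels share a common noise level, and the pooled estimate
#' is far more stable than 101 samples of a single channel).
#'
#' @param ev an `evoked`.
#' @param array the `sensor_array`.
#' @param syllable_onsets_ms 4 ascending onset times (ms).
#' @param baseline_ms baseline window (default -100..0 ms).
#' @param ... passed to [count_m100()].
#' @return list with per-hemisphere results (`left`, `right`) and
#'   `n_combined`.
#' @export
detect_counts <- function(ev, array, syllable_onsets_ms,
                          baseline_ms = c(-100, 0), ...) {
  bsel <- ev$times_ms >= baseline_ms[1] & ev$times_ms <= baseline_ms[2]
  res <- lapply(c(left = "left", right = "right"), function(h) {
    ch <- select_channel(ev, array, h)
    hsel <- array$channels$hemisphere == h
    sd_pool <- stats::sd(as.numeric(ev$data[hsel, bsel]))
    count_m100(ev, ch, syllable_onsets_ms, baseline_ms = baseline_ms,
               baseline_sd = sd_pool, ...)
  })
  res$n_combined <- max(res$left$n_significant, res$right$n_significant)
  res
}
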