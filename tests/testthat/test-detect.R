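onsets4 <- c(0, 0.15, 0.30, 0.45)
onsets_ms4 <- onsets4 * 1000

# noiseless bilateral evoked at a given duration, small array
noiseless_evoked <- function(arr, onsets = onsets4, ...) {
  cfg <- quick_cfg(noise_white_sd = 0, noise_pink_sd = 0,
                   jitter_lat_sd_ms = 0, jitter_amp_sd = 0, n_epochs = 1, ...)
  e <- simulate_epochs(onsets, arr, cfg, seed = 1)
  ev <- suppressWarnings(preprocess_epochs(e, min_epochs = 1))
  list(ev = ev, e = e)
}

test_that("channel selection finds the ground-truth maximum", {
  arr <- tiny_array(24)
  ne <- noiseless_evoked(arr)
  gt <- ne$e$ground_truth$noiseless
  sel <- ne$ev$times_ms >= 50 & ne$ev$times_ms <= 150
  for (h in c("left", "right")) {
    chans <- which(arr$channels$hemisphere == h)
    truth <- chans[which.max(apply(gt[chans, sel], 1, function(x) max(x) - min(x)))]
    expect_identical(select_channel(ne$ev, arr, h), truth)
  }
})

test_that("channel selection prefers signal and breaks ties low", {
  arr <- tiny_array(4)
  ev <- make_evoked(matrix(0, nrow(arr$channels), 1001))
  lch <- which(arr$channels$hemisphere == "left")
  ev$data[lch[2], 200:210] <- 5
  expect_identical(select_channel(ev, arr, "left"), lch[2])
  ev$data[lch[3], 200:210] <- 5                  # tie with lch[2]
  expect_identical(select_channel(ev, arr, "left"), lch[2])
})

test_that("the first M100 is found at its generative latency", {
  arr <- tiny_array(24)
  ne <- noiseless_evoked(arr)
  ch <- select_channel(ne$ev, arr, "left")
  c1 <- find_m100_1(ne$ev, ch)
  expect_true(abs(c1$peak_latency_ms - 100) <= 2)
  expect_true(c1$m50_latency_ms < c1$peak_latency_ms)
  flat <- make_evoked(matrix(0, 2, 1001))
  expect_error(find_m100_1(flat, 1), "flat")
})

test_that("an injected biphasic deflection yields its M50-to-M100 difference", {
  t <- seq(-100, 900)
  s <- component_timecourse(0, 50, 100, 40, -100, 12, t)
  ev <- baseline_correct(filter_evoked(make_evoked(rbind(s, 0))))
  c1 <- find_m100_1(ev, 1)
  expect_lt(abs(c1$delta_amplitude - 140) / 140, 0.10)   # within filter distortion
  expect_true(c1$m50_found)
})

test_that("expected latencies are onset-shifted copies of the M100_1 latency", {
  expect_equal(expected_latencies(100, c(0, 150, 300, 450)), c(250, 400, 550))
  expect_equal(expected_latencies(100, c(0, 93.75, 187.5, 281.25)),
               c(193.75, 287.5, 381.25))
  expect_error(expected_latencies(100, c(0, 300, 150, 450)), "ascending")
  expect_error(expected_latencies(100, c(10, 150, 300, 450)), "0")
})

test_that("the 4-SD rule is a strict threshold on both printed conditions", {
  comp <- data.frame(index = 1L, channel_id = 1L, peak_latency_ms = 100,
                     peak_amplitude_ft_cm = -50, m50_latency_ms = 60,
                     m50_amplitude_ft_cm = 10, delta_amplitude = NA,
                     m50_found = TRUE, expected_latency_ms = 100,
                     window_lo_ms = 60, window_hi_ms = 160, significant = NA)
  comp$delta_amplitude <- 4.01 * 10
  expect_true(test_significance(comp, 10)$significant)
  comp$delta_amplitude <- 4.00 * 10
  expect_false(test_significance(comp, 10)$significant)
  comp$delta_amplitude <- 0
  expect_false(test_significance(comp, 10)$significant)
  # a large difference whose peak stays within 4 SD of baseline is not counted
  comp$delta_amplitude <- 100; comp$peak_amplitude_ft_cm <- -39
  expect_false(test_significance(comp, 10)$significant)
  expect_error(test_significance(comp, 0))
})

test_that("a four-syllable noiseless word yields four significant components", {
  arr <- tiny_array(24)
  ne <- noiseless_evoked(arr)
  dc <- detect_counts(ne$ev, arr, onsets_ms4)
  # noiseless: baseline SD is the tiny filter residue, every component clears it
  expect_identical(dc$n_combined, 4L)
  cc <- dc$left$components
  expect_true(all(cc$peak_latency_ms >= cc$window_lo_ms &
                    cc$peak_latency_ms <= cc$window_hi_ms))
  expect_true(all(cc$m50_latency_ms < cc$peak_latency_ms, na.rm = TRUE))
  # stored fields reproduce every significance flag
  expect_identical(cc$significant,
                   cc$delta_amplitude > cc$k_sd * cc$baseline_sd &
                     abs(cc$peak_amplitude_ft_cm) > cc$k_sd * cc$baseline_sd)
})

test_that("only active sources produce significant components", {
  arr <- tiny_array(24)
  ne <- noiseless_evoked(arr, later_scale = 0)     # syllable-1 source only
  dc <- detect_counts(ne$ev, arr, onsets_ms4)
  expect_identical(dc$left$n_significant, 1L)
  expect_identical(dc$right$n_significant, 1L)
})

test_that("later components are only counted when M100_1 itself is significant", {
  t <- seq(-100, 900)
  set.seed(55)
  noise <- stats::rnorm(length(t))
  weak1 <- component_timecourse(0, 50, 100, 0, 2, 12, t)      # ~2 SD word onset
  big234 <- Reduce(`+`, lapply(c(150, 300, 450), function(o)
    component_timecourse(o, 50, 100, -20, 50, 12, t)))
  ev <- make_evoked(rbind(noise + weak1 + big234, 0), t)
  res <- count_m100(ev, 1, c(0, 150, 300, 450))
  expect_false(res$components$significant[1])
  expect_identical(res$n_significant, 0L)
})

test_that("detected count recovers monotonically with later-syllable amplitude", {
  arr <- tiny_array(24)
  counts <- vapply(c(0, 0.25, 0.6), function(sc) {
    med <- vapply(1:3, function(s) {
      cfg <- default_sim_config(n_epochs = 40, artifact_fraction = 0,
                                later_scale = sc)
      e <- simulate_epochs(onsets4, arr, cfg, seed = 800 + s)
      ev <- suppressWarnings(preprocess_epochs(e))
      detect_counts(ev, arr, onsets_ms4)$n_combined
    }, numeric(1))
    stats::median(med)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 1)
})
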