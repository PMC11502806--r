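onsets4 <- c(0, 0.15, 0.30, 0.45)

test_that("epoch rejection removes exactly the above-threshold epochs", {
  arr <- tiny_array(8)
  e <- simulate_epochs(onsets4, arr, quick_cfg(), seed = 2)
  expect_identical(dim(reject_epochs(e)$data), dim(e$data))   # none exceed
  e$data[3, 4, 100] <- 3500
  r <- reject_epochs(e)
  expect_identical(dim(r$data)[1], dim(e$data)[1] - 1L)
  expect_identical(attr(r, "n_rejected"), 1L)
  expect_equal(r$data[3, , ], e$data[4, , ])                  # order preserved
  e$data[] <- 5000
  expect_error(reject_epochs(e), "all epochs")
})

test_that("rejection counts match the generator's artifact injections", {
  arr <- tiny_array(8)
  cfg <- default_sim_config(n_epochs = 120, artifact_fraction = 0.1)
  e <- simulate_epochs(onsets4, arr, cfg, seed = 31)
  r <- reject_epochs(e)
  expect_identical(dim(r$data)[1],
                   120L - length(e$ground_truth$artifact_epochs))
})

test_that("averaging is the pointwise mean with a below-minimum warning", {
  arr <- tiny_array(8)
  cfg <- quick_cfg(noise_white_sd = 0, noise_pink_sd = 0,
                   jitter_lat_sd_ms = 0, jitter_amp_sd = 0, n_epochs = 3)
  e <- simulate_epochs(onsets4, arr, cfg, seed = 1)
  expect_warning(ev <- average_epochs(e, min_epochs = 100), "artifact-free")
  expect_equal(ev$data, e$data[1, , ], tolerance = 1e-12)     # identical epochs
  expect_identical(ev$n_epochs_averaged, 3L)
  ev2 <- average_epochs(e, min_epochs = 2)
  expect_identical(sum(grepl("warning", ev2$processing_log)), 0L)
  e$data <- e$data[integer(0), , , drop = FALSE]
  expect_error(average_epochs(e), "empty")
})

test_that("the band-pass and notch meet their frequency-response contracts", {
  t <- seq(-100, 900)
  mk <- function(f) make_evoked(matrix(sin(2 * pi * f * t / 1000), 1))
  amp <- function(ev) max(abs(ev$data[1, t >= 200 & t <= 700]))
  f60 <- filter_evoked(mk(60))
  expect_lt(amp(f60), 0.10)                                   # >= 20 dB notch
  f10 <- filter_evoked(mk(10))
  expect_lt(abs(amp(f10) - 1), 0.12)                          # ~1 dB passband
  fdc <- filter_evoked(make_evoked(matrix(1, 1, length(t))))
  expect_lt(max(abs(fdc$data)), 0.02)                         # DC removed
  expect_error(filter_evoked(mk(10), band_hz = c(75, 1)), "invalid band")
  expect_error(filter_evoked(mk(10), band_hz = c(0, 75)), "invalid band")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  t <- seq(-100, 900)
  ev <- make_evoked(matrix(rep(c(3, -2), each = length(t)), 2, byrow = TRUE))
  b <- baseline_correct(ev)
  expect_identical(max(abs(b$data)), 0)                       # constant removed
  set.seed(4)
  ev2 <- make_evoked(matrix(stats::rnorm(2 * length(t)), 2))
  b2 <- baseline_correct(ev2)
  bm <- rowMeans(b2$data[, t >= -100 & t <= 0])
  expect_lt(max(abs(bm)) / stats::sd(b2$data[1, ]), 1e-12)
  expect_equal(baseline_correct(b2)$data, b2$data)            # idempotent
  expect_error(baseline_correct(ev2, c(-500, 0)), "outside")
})

test_that("the preprocessing chain is linear", {
  arr <- tiny_array(6)
  e1 <- simulate_epochs(onsets4, arr, quick_cfg(n_epochs = 8), seed = 6)
  e2 <- simulate_epochs(onsets4, arr, quick_cfg(n_epochs = 8), seed = 7)
  pp <- function(e) suppressWarnings(preprocess_epochs(e, min_epochs = 1))
  esum <- e1; esum$data <- e1$data + e2$data
  # analytically exact; tolerance covers the ill-conditioned direct-form IIR
  expect_equal(pp(esum)$data, pp(e1)$data + pp(e2)$data, tolerance = 1e-4)
})

test_that("re-filtering an already-filtered passband signal barely changes it", {
  t <- seq(-100, 900)
  ev <- make_evoked(matrix(sin(2 * pi * 10 * t / 1000), 1))
  once <- baseline_correct(filter_evoked(ev))
  twice <- baseline_correct(filter_evoked(once))
  mid <- t >= 100 & t <= 800
  rel <- max(abs(twice$data[1, mid] - once$data[1, mid])) / max(abs(once$data[1, mid]))
  expect_lt(rel, 0.05)
})

test_that("the processing log records the canonical order", {
  arr <- tiny_array(6)
  e <- simulate_epochs(onsets4, arr, quick_cfg(n_epochs = 4), seed = 8)
  ev <- suppressWarnings(preprocess_epochs(e))
  steps <- c("reject", "average", "filter", "baseline")
  hits <- vapply(steps, function(s) grep(s, ev$processing_log)[1], numeric(1))
  expect_true(all(diff(hits) > 0))
})
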