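test_that("base word has the VCVCVCV structure with quarter-spaced syllable onsets", {
  w <- synthesize_base_word()
  expect_length(w$syllable_onsets, 4)
  expect_identical(w$syllable_onsets[1], 0)
  expect_equal(syllable_spacing_ms(w), 150)
  expect_equal(diff(w$syllable_onsets), rep(0.15, 3))
  expect_equal(nrow(w$boundaries), 7)
  expect_identical(w$boundaries$label, c("a", "t", "a", "t", "a", "k", "a"))
  expect_true(all(w$boundaries$time_s <= 0.6))
  expect_true(all(diff(w$boundaries$time_s) > 0))
  # voiced segments louder than closures
  r <- w$rate_hz
  vow <- w$samples[round(0.02 * r):round(0.06 * r)]
  clo <- w$samples[round(0.10 * r):round(0.13 * r)]
  expect_gt(sqrt(mean(vow^2)), sqrt(mean(clo^2)))
})

test_that("degenerate synthesis inputs are rejected", {
  expect_error(synthesize_base_word(f0_hz = 0), "f0")
  expect_error(synthesize_base_word(formants = c(800, 9000)), "Nyquist")
  expect_error(synthesize_base_word(duration_s = 0), "positive")
})

test_that("time stretching scales duration and onset metadata exactly", {
  w <- synthesize_base_word()
  for (target in c(0.375, 0.300)) {
    s <- time_stretch(w, target)
    expect_equal(wave_duration(s), target, tolerance = 1 / w$rate_hz)
    expect_equal(syllable_spacing_ms(s), 1000 * target / 4)
    expect_equal(s$boundaries$time_s, w$boundaries$time_s * target / 0.6)
  }
  expect_equal(syllable_spacing_ms(time_stretch(w, 0.375)), 93.75)
  expect_equal(syllable_spacing_ms(time_stretch(w, 0.300)), 75.00)
  expect_error(time_stretch(w, -0.1), "positive")
})

test_that("identity stretch returns the waveform unchanged", {
  w <- synthesize_base_word()
  s <- time_stretch(w, wave_duration(w))
  expect_identical(s$samples, w$samples)
  expect_identical(s$boundaries, w$boundaries)
})

test_that("stretching preserves the short-time spectral envelope", {
  w <- synthesize_base_word()
  s <- time_stretch(w, 0.375)
  # first-formant peak of the initial vowel, original vs stretched
  f_orig <- spectral_peak(w$samples[300:1200], w$rate_hz, c(500, 1100))
  f_str <- spectral_peak(s$samples[200:750], s$rate_hz, c(500, 1100))
  expect_lt(abs(f_str - f_orig) / f_orig, 0.05)
})

test_that("level normalization applies a pure positive gain", {
  w <- synthesize_base_word()
  n <- normalize_level(w, 0.1)
  expect_equal(wave_rms(n), 0.1, tolerance = 1e-6)
  expect_equal(stats::cor(n$samples, w$samples), 1)
  expect_equal(wave_rms(normalize_level(n, 0.1)), 0.1, tolerance = 1e-9)
  silent <- waveform(numeric(100), 1000)
  expect_error(normalize_level(silent, 0.1), "zero")
})

test_that("the default stimulus set spans 75-600 ms at a common level", {
  set <- generate_stimulus_set()
  expect_length(set, 8)
  durs <- vapply(set, wave_duration, numeric(1))
  expect_equal(min(durs), 0.075)
  expect_equal(max(durs), 0.600)
  rms <- vapply(set, wave_rms, numeric(1))
  expect_true(all(abs(rms - rms[1]) / rms[1] < 1e-6))
  expect_length(generate_stimulus_set(600), 1)
  expect_error(generate_stimulus_set(numeric(0)), "empty")
  expect_error(generate_stimulus_set(c(300, 300)), "distinct")
})

test_that("tube delay follows the linear sound-speed approximation", {
  expect_identical(tube_delay_ms(0), 0)
  expect_equal(tube_delay_ms(0.3435, 20), 1.0)              # 343.5 m/s at 20 C
  expect_equal(tube_delay_ms(0.138, 20), 0.402, tolerance = 1e-3)
  expect_error(tube_delay_ms(-0.1), "non-negative")
  expect_error(tube_delay_ms(0.1, 95), "range")
})

test_that("WAV round trip preserves samples, rate, and sidecar metadata", {
  w <- normalize_level(synthesize_base_word(duration_s = 0.15), 0.1)
  tmp <- tempfile(fileext = ".wav")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  write_wav(w, tmp, format = "float32")
  r <- read_wav(tmp)
  expect_lt(max(abs(r$samples - w$samples)), 1e-6 * max(abs(w$samples)))
  expect_identical(r$rate_hz, w$rate_hz)
  expect_equal(r$syllable_onsets, w$syllable_onsets)
  expect_equal(r$boundaries$time_s, w$boundaries$time_s)
  expect_identical(r$boundaries$label, w$boundaries$label)
  write_wav(w, tmp, format = "pcm16")
  r16 <- read_wav(tmp)
  expect_lt(max(abs(r16$samples - w$samples)), 1.5 / 32767)
})
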