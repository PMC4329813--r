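test_that("stimulus specs validate their physical invariants", {
  expect_s3_class(stimulus_spec("violet_noise", 2, 20, total_duration = 1),
                  "stimulus_spec")
  expect_error(stimulus_spec("violet_noise", 20, 2, total_duration = 1),
               "f_low")
  expect_error(stimulus_spec("violet_noise", 2, 20, total_duration = 0),
               "positive")
  expect_error(stimulus_spec("violet_noise", 2, 60, total_duration = 1),
               "Nyquist")
  expect_error(stimulus_spec("violet_sweep", 2, 20, sweep_duration = 10,
                             total_duration = 5), "sweep_duration")
  expect_error(stimulus_spec("violet_sweep", 2, 20, sweep_duration = -1,
                             total_duration = 5), "sweep_duration")
})

test_that("violet noise has a +6 dB/octave power slope and stays in band", {
  spec <- stimulus_spec("violet_noise", 2, 20, total_duration = 1)
  w <- synth_violet_noise(spec, seed = 1)
  # slope fitted inside the raised-cosine tapers
  expect_equal(estimate_psd_slope(w, c(3.8, 18.2)), 6.02, tolerance = 0.5 / 6.02)
  # power doubles per octave: 16 kHz exceeds 8 kHz by ~6 dB
  psd <- cochleostat:::welch_psd(w)
  p8 <- mean(psd$power[abs(psd$freq_khz - 8) < 0.3])
  p16 <- mean(psd$power[abs(psd$freq_khz - 16) < 0.3])
  expect_equal(10 * log10(p16 / p8), 6.02, tolerance = 1.2 / 6.02)
  # band containment: <= 1% of power outside the widened band
  expect_lt(1 - band_power_fraction(w, c(2 * 0.9, 20 * 1.1)), 0.01)
  expect_gt(waveform_rms(w), 0)
})

test_that("violet noise synthesis is seed-deterministic", {
  spec <- stimulus_spec("violet_noise", 2, 20, total_duration = 1)
  expect_identical(synth_violet_noise(spec, seed = 7)$samples,
                   synth_violet_noise(spec, seed = 7)$samples)
  expect_false(identical(synth_violet_noise(spec, seed = 7)$samples,
                         synth_violet_noise(spec, seed = 8)$samples))
})

test_that("PSD slope estimator recovers flat and mirrored slopes", {
  fs <- 96000
  n <- fs
  white <- structure(list(samples = withr::with_seed(2, stats::rnorm(n)),
                          sample_rate = fs), class = "waveform")
  expect_equal(estimate_psd_slope(white, c(3.8, 18.2)), 0, tolerance = 0.5)
  # amplitude ~ 1/f shaping gives the mirror case, -6 dB/octave
  x <- withr::with_seed(3, stats::rnorm(n))
  fk <- (seq_len(n) - 1) / n * fs / 1000
  fk <- pmin(fk, fs / 1000 - fk)
  g <- ifelse(fk >= 2 & fk <= 20, 1 / pmax(fk, 1e-9), 0)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  pink <- structure(list(samples = y, sample_rate = fs), class = "waveform")
  expect_equal(estimate_psd_slope(pink, c(3.8, 18.2)), -6.02,
               tolerance = 0.5 / 6.02)
  expect_error(estimate_psd_slope(white, c(10, 10)), "empty band")
  expect_error(estimate_psd_slope(white, c(10, 50)), "Nyquist")
})

test_that("sweep instantaneous frequency is linear with the stated endpoints", {
  spec <- vs_spec(2, 20)
  expect_equal(sweep_instantaneous_frequency(spec, 0), 2)
  expect_equal(sweep_instantaneous_frequency(spec, 10), 20)
  expect_equal(sweep_instantaneous_frequency(spec, 5), 11)
  # repeats: 30 min of 10 s sweeps = 180 complete repeats
  expect_identical(n_sweep_repeats(spec), 180L)
  # the sweep restarts after each period
  expect_equal(sweep_instantaneous_frequency(spec, 15), 11)
})

test_that("sweep waveform has a linear spectrogram ridge and violet slope", {
  one <- stimulus_spec("violet_sweep", 2, 20, sweep_duration = 10,
                       total_duration = 10)
  w <- synth_violet_sweep(one)
  ridge <- spectrogram_ridge(w)
  expect_gt(ridge$r_squared, 0.999)
  expect_equal(ridge$slope, (20 - 2) / 10, tolerance = 0.02)
  expect_equal(estimate_psd_slope(w, c(3.8, 18.2)), 6.02,
               tolerance = 0.5 / 6.02)
  expect_lt(1 - band_power_fraction(w, c(2 * 0.9, 20 * 1.1)), 0.01)
  # repeats tile back-to-back and truncate the last repeat
  rep3 <- stimulus_spec("violet_sweep", 2, 20, sweep_duration = 10,
                        total_duration = 25)
  w3 <- synth_violet_sweep(rep3)
  expect_equal(length(w3$samples), 25 * 96000)
  n1 <- 10 * 96000
  expect_equal(w3$samples[seq_len(n1)], w3$samples[n1 + seq_len(n1)])
})

test_that("SPL scaling matches its closed form and is idempotent", {
  spec <- stimulus_spec("violet_noise", 2, 20, total_duration = 0.5)
  w <- synth_violet_noise(spec, seed = 1)
  p_ref <- 20e-6
  s105 <- scale_to_level(w, 105)
  expect_equal(waveform_rms(s105), p_ref * 10^5.25)
  expect_equal(scale_to_level(s105, 105)$samples, s105$samples)
  s120 <- scale_to_level(w, 120)
  expect_equal(waveform_rms(s120) / waveform_rms(s105), 10^(15 / 20))
  # shape unchanged: scalar multiple
  expect_equal(s120$samples / s105$samples,
               rep(10^(15 / 20), length(w$samples)))
  zero <- structure(list(samples = rep(0, 100), sample_rate = 96000),
                    class = "waveform")
  expect_error(scale_to_level(zero, 105), "zero-RMS")
})

test_that("WAV files round-trip", {
  spec <- stimulus_spec("violet_noise", 2, 20, total_duration = 0.1)
  w <- scale_to_level(synth_violet_noise(spec, seed = 4), 60)
  f32 <- tempfile(fileext = ".wav")
  write_wav(w, f32, "float32")
  back <- read_wav(f32)
  expect_equal(back$sample_rate, 96000)
  expect_equal(back$samples, w$samples, tolerance = 1e-6)
  p16 <- tempfile(fileext = ".wav")
  write_wav(w, p16, "pcm16")
  back16 <- read_wav(p16)
  # pcm16 is peak-normalized: compare shapes
  expect_gt(stats::cor(back16$samples, w$samples), 0.9999)
  bad <- tempfile()
  writeLines("not a wav", bad)
  expect_error(read_wav(bad), "RIFF")
})

test_that("verify_stimulus reports the design properties", {
  spec <- stimulus_spec("violet_sweep", 9, 13, 105, sweep_duration = 10,
                        total_duration = 10)
  rep <- verify_stimulus(synth_violet_sweep(spec), spec)
  expect_lt(rep$out_of_band_fraction, 0.01)
  expect_gt(rep$ridge_r_squared, 0.999)
  expect_equal(rep$ridge_slope_khz_per_s, 0.4, tolerance = 0.05)
})
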