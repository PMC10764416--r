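test_that("artifact detection applies the magnitude thresholds with a guard", {
  zeros <- new_imu_recording("S", "T", 60, "lumbar", matrix(0, 600, 3))
  expect_false(any(detect_artifacts(zeros)))

  acc <- matrix(0, 600, 3)
  acc[300, 1] <- 101  # just above 100 m/s^2
  rec <- new_imu_recording("S", "T", 60, "lumbar", acc)
  mask <- detect_artifacts(rec)
  expect_true(all(mask[285:315]))  # +/- 0.25 s = 15 samples at 60 Hz
  expect_false(any(mask[c(284, 316)]))

  acc[300, 1] <- 100  # "greater than": boundary not flagged
  expect_false(any(detect_artifacts(
    new_imu_recording("S", "T", 60, "lumbar", acc))))

  # vector norm matters, not any single axis
  acc <- matrix(0, 600, 3)
  acc[100, ] <- c(60, 60, 60)  # norm 103.9
  expect_true(detect_artifacts(new_imu_recording("S", "T", 60, "lumbar", acc))[100])

  gyr <- matrix(0, 600, 3)
  gyr[50, 2] <- 20.5
  rec <- new_imu_recording("S", "T", 60, "lumbar", matrix(0, 600, 3), gyr)
  expect_true(detect_artifacts(rec)[50])
  gyr[50, 2] <- 19.5
  rec <- new_imu_recording("S", "T", 60, "lumbar", matrix(0, 600, 3), gyr)
  expect_false(any(detect_artifacts(rec)))
})

test_that("band-pass kills DC, passes 5 Hz with zero lag, kills 0.05 Hz", {
  fs <- 60
  n <- 12000
  mid <- 3000:9000

  dc <- bandpass(rep(2, n), fs)
  expect_lt(max(abs(dc[mid])), 2e-6 * 2)

  t <- (0:(n - 1)) / fs
  s5 <- sin(2 * pi * 5 * t)
  o5 <- bandpass(s5, fs)
  co <- gaitfog:::butter_coeffs(fs)
  expect_equal(rms(o5[mid]) / rms(s5[mid]), filter_gain(co$b, co$a, 5, fs)^2,
               tolerance = 0.01)
  cc <- ccf(o5[mid], s5[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  slow <- sin(2 * pi * 0.05 * t)
  expect_lt(max(abs(bandpass(slow, fs)[mid])), 0.1)

  expect_error(bandpass(rnorm(10), fs), class = "gaitfog_validation_error")
  expect_error(bandpass(rnorm(100), 20), class = "gaitfog_validation_error")
})

test_that("measured filter gains match the squared transfer function", {
  fs <- 60
  n <- 18000
  mid <- 5000:13000
  t <- (0:(n - 1)) / fs
  co <- gaitfog:::butter_coeffs(fs)
  for (f in c(0.5, 1, 2.5, 8, 14, 20)) {
    x <- sin(2 * pi * f * t)
    gain <- rms(bandpass(x, fs)[mid]) / rms(x[mid])
    expect_equal(gain, filter_gain(co$b, co$a, f, fs)^2, tolerance = 0.02)
  }
})

test_that("resampling preserves in-band content and maps lengths 5 -> 3", {
  x <- rnorm(480)
  expect_identical(resample_to_60(x, 60), x)
  expect_length(resample_to_60(rnorm(500), 100), 300)
  expect_error(resample_to_60(x, 50), class = "gaitfog_validation_error")

  t <- (0:5999) / 100
  s <- sin(2 * pi * 5 * t)
  y <- resample_to_60(s, 100)
  k <- 600:3000
  expect_equal(rms(y[k]) * sqrt(2), 1, tolerance = 0.01)
  # spectral peak still at 5 Hz
  sp <- Mod(fft(y[601:3000]))^2
  freqs <- (0:2399) * 60 / 2400
  expect_equal(freqs[which.max(sp[freqs > 0 & freqs < 30])], 5, tolerance = 0.1)
  # delay-compensated: aligned with the ideal 60 Hz samples
  expect_lt(rms(y[k + 1] - sin(2 * pi * 5 * k / 60)), 0.02)
})

test_that("preprocessing chains mask, filter and resample correctly", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 60, sensors = "lumbar",
                    sample_rate_hz = 100, seed = 2)
  p <- make_params(noise_sd = 0.1)
  rec <- synth_recording(p, new_fog_annotations("S", "T"), cfg, seed = 3)
  out <- inject_artifacts(rec, 1, seed = 4)

  clean <- preprocess_recording(out$recording)
  expect_equal(clean$sample_rate_hz, 60)
  expect_equal(clean$n_samples, ceiling(rec$n_samples * 3 / 5))
  expect_length(clean$artifact_mask, clean$n_samples)
  expect_true(all(is.finite(clean$accel)))
  # every injected spike lands inside the 60 Hz mask
  spike_60 <- floor(out$artifact_times * 60) + 1
  expect_true(all(clean$artifact_mask[spike_60]))

  clean0 <- preprocess_recording(rec)
  expect_false(any(clean0$artifact_mask))
})

test_that("filtering preserves locomotor-band energy and is near-idempotent", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 60, sensors = "lumbar",
                    seed = 2)
  p <- make_params(noise_sd = 0)
  rec <- synth_recording(p, new_fog_annotations("S", "T"), cfg, seed = 3)
  x <- rec$accel[, 1]
  y1 <- bandpass(x, 60)
  y2 <- bandpass(y1, 60)
  band_rms <- function(v) {
    sp <- Mod(fft(v))^2
    freqs <- (seq_along(v) - 1) * 60 / length(v)
    sqrt(sum(sp[freqs >= 1 & freqs <= 10]))
  }
  expect_equal(band_rms(y1) / band_rms(x), 1, tolerance = 0.05)
  expect_equal(band_rms(y2) / band_rms(y1), 1, tolerance = 0.02)
})
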