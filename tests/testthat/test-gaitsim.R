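test_that("subject parameters are deterministic, in range, and seed-sensitive", {
  cfg <- sim_config(n_subjects = 100, seed = 5)
  p1 <- sample_subject_params(cfg, 3)
  p2 <- sample_subject_params(cfg, 3)
  expect_identical(p1, p2)

  steps <- vapply(1:100, function(i) sample_subject_params(cfg, i)$step_freq_hz,
                  numeric(1))
  expect_true(all(steps >= 1.0 & steps <= 2.5))
  trembles <- vapply(1:100, function(i) sample_subject_params(cfg, i)$tremble_freq_hz,
                     numeric(1))
  expect_true(all(trembles >= 3 & trembles <= 8))

  cfg2 <- sim_config(n_subjects = 100, seed = 6)
  diffs <- vapply(1:100, function(i) {
    !identical(sample_subject_params(cfg, i), sample_subject_params(cfg2, i))
  }, logical(1))
  expect_true(all(diffs))
})

test_that("episode schedules hit the target FOG fraction and mean duration", {
  p <- make_params(fog_time_fraction_target = 0)
  expect_equal(nrow(episode_schedule(600, p, seed = 1)), 0)

  p <- make_params(fog_time_fraction_target = 0.10, mean_episode_s = 5)
  fracs <- vapply(1:50, function(s) {
    fog_total_seconds(episode_schedule(3600, p, seed = s)) / 3600
  }, numeric(1))
  expect_gt(mean(fracs), 0.07)
  expect_lt(mean(fracs), 0.13)

  lens <- unlist(lapply(1:40, function(s) {
    a <- episode_schedule(3600, p, seed = 100 + s)
    a$end_s - a$start_s
  }))
  expect_gt(length(lens), 500)
  expect_lt(abs(mean(lens) - 5) / 5, 0.2)

  expect_error(episode_schedule(2, p, seed = 1), class = "gaitfog_validation_error")
})

test_that("walking signal peaks at the step frequency on leg channels", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 60,
                    sensors = "lower_legs", seed = 2)
  p <- make_params(step_freq_hz = 1.9, noise_sd = 0)
  sched <- new_fog_annotations("S", "T")  # no FOG
  rec <- synth_recording(p, sched, cfg, seed = 4)
  n <- rec$n_samples
  freqs <- (0:(n - 1)) * 60 / n
  for (ch in c("lower_leg_left_x", "lower_leg_right_x")) {
    sp <- Mod(fft(rec$accel[, ch]))^2
    fsel <- freqs > 0.3 & freqs < 30
    peak <- freqs[fsel][which.max(sp[fsel])]
    expect_lt(abs(peak - 1.9), 0.3)
  }
})

test_that("trembling FOG shifts power into the freeze band; akinesia silences", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 40,
                    sensors = "lower_legs", seed = 2)
  all_fog <- new_fog_annotations("S", "T", 0, 40)

  p_trem <- make_params(akinetic_prob = 0, noise_sd = 0.1)
  rec <- synth_recording(p_trem, all_fog, cfg, seed = 9)
  n <- rec$n_samples
  freqs <- (0:(n - 1)) * 60 / n
  for (ch in colnames(rec$accel)) {
    sp <- Mod(fft(rec$accel[, ch]))^2
    freeze <- sum(sp[freqs >= 3 & freqs <= 8])
    loco <- sum(sp[freqs >= 0.5 & freqs < 3])
    expect_gt(freeze / loco, 1)
  }

  p_akin <- make_params(akinetic_prob = 1, noise_sd = 0.1)
  rec_akin <- synth_recording(p_akin, all_fog, cfg, seed = 9)
  rec_walk <- synth_recording(p_akin, new_fog_annotations("S", "T"), cfg, seed = 9)
  mid <- 300:2100  # avoid crossfade ramps
  v_akin <- sum(apply(rec_akin$accel[mid, ], 2, var))
  v_walk <- sum(apply(rec_walk$accel[mid, ], 2, var))
  expect_lt(v_akin / v_walk, 0.10)
})

test_that("left and right legs are anti-phase during walking", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 30,
                    sensors = "lower_legs", seed = 2)
  p <- make_params(noise_sd = 0)
  rec <- synth_recording(p, new_fog_annotations("S", "T"), cfg, seed = 3)
  r <- cor(rec$accel[, "lower_leg_left_x"], rec$accel[, "lower_leg_right_x"])
  expect_lt(r, -0.5)
})

test_that("synthetic recordings are a pure function of the seed", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 20, sensors = "lumbar",
                    seed = 2)
  p <- make_params()
  sched <- episode_schedule(20, p, seed = 7)
  r1 <- synth_recording(p, sched, cfg, seed = 7)
  r2 <- synth_recording(p, sched, cfg, seed = 7)
  expect_identical(r1$accel, r2$accel)
  r3 <- synth_recording(p, sched, cfg, seed = 8)
  expect_false(identical(r1$accel, r3$accel))
})

test_that("schedules beyond the trial duration are rejected", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 20, sensors = "lumbar")
  expect_error(
    synth_recording(make_params(), new_fog_annotations("S", "T", 5, 25), cfg, 1),
    class = "gaitfog_validation_error")
})

test_that("artifact injection hits the detection thresholds at Poisson rate", {
  cfg <- sim_config(n_subjects = 1, trial_duration_s = 600, sensors = "lumbar",
                    with_gyro = TRUE, seed = 2)
  p <- make_params()
  rec <- synth_recording(p, new_fog_annotations("S", "T"), cfg, seed = 5)

  out0 <- inject_artifacts(rec, 0, seed = 1)
  expect_identical(out0$recording$accel, rec$accel)
  expect_length(out0$artifact_times, 0)

  out <- inject_artifacts(rec, 2, seed = 1)  # 10 min at 2/min: lambda = 20
  k <- length(out$artifact_times)
  expect_gte(k, qpois(0.005, 20))
  expect_lte(k, qpois(0.995, 20))

  mask <- detect_artifacts(out$recording)
  spike_idx <- round(out$artifact_times * 60) + 1
  expect_true(all(mask[spike_idx]))
  expect_false(any(detect_artifacts(rec)))
})

test_that("pooled schedule FOG fraction approaches the configured target", {
  cfg <- sim_config(n_subjects = 10, trial_duration_s = 600,
                    fog_time_fraction = 0.105, seed = 21)
  tot <- 0
  for (i in 1:10) {
    p <- sample_subject_params(cfg, i)
    tot <- tot + fog_total_seconds(
      episode_schedule(600, p, derive_seed(cfg$seed, "trial", i, 1)))
  }
  expect_lt(abs(tot / 6000 - 0.105), 0.03)
})

test_that("cohort generation writes a complete, reproducible file set", {
  cfg <- sim_config(n_subjects = 5, trial_duration_s = 30, sensors = "lumbar",
                    seed = 31)
  d1 <- tempfile("cohortA"); d2 <- tempfile("cohortB")
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)
  expect_equal(nrow(m1), 5)
  expect_equal(sum(grepl("_fog", list.files(d1))), 5)
  expect_equal(length(list.files(d1)), 11)  # 5 rec + 5 ann + manifest
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
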