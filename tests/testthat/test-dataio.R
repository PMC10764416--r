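test_that("recordings round-trip bitwise through the CSV container", {
  set.seed(41)
  for (i in 1:100) {
    n_sens <- sample(1:2, 1)
    sensors <- sample(gaitfog:::FOG_SENSORS, n_sens)
    n <- sample(30:60, 1)
    with_gyro <- i %% 3 == 0
    rec <- new_imu_recording(
      sprintf("S%03d", i), "T1", sample(c(60, 100), 1), sensors,
      matrix(rnorm(n * 3 * n_sens, sd = 10), n),
      if (with_gyro) matrix(rnorm(n * 3 * n_sens), n))
    path <- tempfile(fileext = ".csv")
    write_recording(rec, path)
    back <- read_recording(path)
    expect_identical(back$accel, rec$accel)
    expect_identical(back$gyro, rec$gyro)
    expect_identical(back$subject_id, rec$subject_id)
    expect_identical(back$sample_rate_hz, rec$sample_rate_hz)
    expect_identical(back$sensors, rec$sensors)
    unlink(path)
  }
})

test_that("malformed recording files raise format errors naming the line", {
  rec <- new_imu_recording("S1", "T1", 60, "lumbar", matrix(1:30 / 7, 10))
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)

  lines <- readLines(path)
  bad <- lines
  bad[8] <- sub("^[^,]*", "NaN", bad[8])
  writeLines(bad, path)
  expect_error(read_recording(path), "line 8", class = "gaitfog_format_error")

  bad <- lines
  bad[9] <- paste0(bad[9], ",0.5")
  writeLines(bad, path)
  expect_error(read_recording(path), "line 9", class = "gaitfog_format_error")

  bad <- lines[-3]  # drop sample_rate_hz header
  writeLines(bad, path)
  expect_error(read_recording(path), "sample_rate_hz",
               class = "gaitfog_format_error")
  unlink(path)
})

test_that("recording validation rejects bad construction", {
  expect_error(new_imu_recording("S", "T", 60, character(0), matrix(0, 5, 0)),
               class = "gaitfog_validation_error")
  expect_error(new_imu_recording("S", "T", 90, "lumbar", matrix(0, 5, 3)),
               class = "gaitfog_validation_error")
  expect_error(new_imu_recording("S", "T", 60, "hip", matrix(0, 5, 3)),
               class = "gaitfog_validation_error")
  expect_error(new_imu_recording("S", "T", 60, "lumbar", matrix(c(NA, 1:14), 5)),
               class = "gaitfog_validation_error")
})

test_that("annotation intervals sort, merge when touching, and validate", {
  a <- new_fog_annotations("S", "T", c(10, 3), c(12, 5.5))
  expect_equal(a$start_s, c(3, 10))
  expect_equal(fog_total_seconds(a), 4.5)

  merged <- new_fog_annotations("S", "T", c(3, 5), c(5, 6))
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start_s, merged$end_s), c(3, 6))

  expect_error(new_fog_annotations("S", "T", 5, 4),
               class = "gaitfog_validation_error")
  expect_error(new_fog_annotations("S", "T", c(1, 2), c(3, 4)),
               class = "gaitfog_validation_error")  # overlap
})

test_that("annotation merge agrees with a brute-force mask on random sets", {
  set.seed(7)
  for (i in 1:50) {
    # random touching-or-separated intervals inside [0, 60)
    bounds <- sort(sample(seq(0, 60, by = 0.5), 8))
    starts <- bounds[c(1, 3, 5, 7)]
    ends <- bounds[c(2, 4, 6, 8)]
    keep <- starts < ends
    ann <- new_fog_annotations("S", "T", starts[keep], ends[keep])
    # reference: fine-grid occupancy
    grid <- seq(0.0005, 60, by = 0.001)
    occ <- rep(FALSE, length(grid))
    for (j in which(keep)) occ <- occ | (grid >= starts[j] & grid < ends[j])
    expect_equal(fog_total_seconds(ann), sum(occ) * 0.001, tolerance = 0.01)
    # merged intervals never touch
    if (nrow(ann) > 1) {
      expect_true(all(ann$start_s[-1] > ann$end_s[-nrow(ann)]))
    }
  }
})

test_that("annotations round-trip through CSV", {
  a <- new_fog_annotations("S9", "T2", c(1.25, 7), c(2.5, 11))
  path <- tempfile(fileext = ".csv")
  write_annotations(a, path)
  b <- read_annotations(path)
  expect_equal(b$start_s, a$start_s)
  expect_equal(b$end_s, a$end_s)
  expect_identical(b$subject_id[1], "S9")

  empty <- new_fog_annotations("S9", "T3")
  write_annotations(empty, path)
  back <- read_annotations(path, "S9", "T3")
  expect_equal(nrow(back), 0)
  expect_equal(fog_total_seconds(back), 0)
  unlink(path)
})

test_that("total FOG seconds matches a per-sample mask within one period", {
  set.seed(13)
  fs <- 60
  for (i in 1:20) {
    n <- 1200
    s <- sort(runif(3, 0, 15)); e <- s + runif(3, 0.5, 3)
    keep <- c(TRUE, s[-1] > e[-3])
    ann <- suppressWarnings(try(new_fog_annotations("S", "T", s[keep], e[keep]),
                                silent = TRUE))
    if (inherits(ann, "try-error")) next
    mask <- gaitfog:::fog_sample_mask(ann, n, fs)
    expect_lt(abs(fog_total_seconds(ann) - sum(mask) / fs),
              (nrow(ann) + 1) / fs)
  }
})

test_that("manifests validate and resolve relative paths", {
  man <- small_manifest()
  expect_true(all(file.exists(man$recording)))
  expect_true(all(man$role %in% c("train", "holdout", "unseen")))
  expect_equal(sum(man$role == "unseen"), 1)
  expect_equal(nrow(man), 7)

  bad <- man
  bad$subject_id[2] <- bad$subject_id[1]
  bad$trial_id[2] <- bad$trial_id[1]
  expect_error(gaitfog:::validate_manifest(bad), class = "gaitfog_validation_error")
})
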