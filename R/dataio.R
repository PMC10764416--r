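# Data model and file formats: recordings, FOG annotations, cohort manifests.
#
# Recording file format: CSV with a `#`-prefixed metadata header (subject,
# trial, sample rate, sensor list), then one row per sample with columns
# `<sensor>_<axis>` (acceleration, m/s^2) followed by optional
# `<sensor>_gyr_<axis>` columns (angular velocity, rad/s). Values are
# serialized at full double precision so write/read round-trips bitwise.

#' Construct an IMU recording
#'
#' A recording is one subject-trial multichannel sensor stream: a matrix of
#' 3-axis accelerometer samples per sensor (columns `<sensor>_<axis>` in the
#' canonical sensor order, axes x, y, z within each sensor), optionally a
#' matching gyroscope matrix, and identifying metadata.
#'
#' @param subject_id,trial_id Opaque identifier strings.
#' @param sample_rate_hz Sampling rate; 60 or 100 Hz.
#' @param sensors Character vector of body locations, a subset of
#'   `c("lumbar", "upper_leg_left", "upper_leg_right", "lower_leg_left",
#'   "lower_leg_right", "foot_left", "foot_right")`.
#' @param accel Numeric matrix, `n_samples` rows by `3 * length(sensors)`
#'   columns, acceleration in m/s^2.
#' @param gyro Optional numeric matrix of the same shape, angular velocity in
#'   rad/s.
#' @return An object of class `imu_recording`.
#' @export
#' @examples
#' r <- new_imu_recording("S01", "T1", 60, "lumbar", matrix(0, 120, 3))
#' r$n_samples
new_imu_recording <- function(subject_id, trial_id, sample_rate_hz, sensors,
                              accel, gyro = NULL) {
  if (!sample_rate_hz %in% c(60, 100)) {
    abort("`sample_rate_hz` must be 60 or 100", class = "gaitfog_validation_error")
  }
  if (length(sensors) == 0) {
    abort("a recording needs at least one sensor", class = "gaitfog_validation_error")
  }
  sensors <- resolve_sensors(sensors)
  accel <- as.matrix(accel)
  if (ncol(accel) != 3 * length(sensors)) {
    abort(sprintf("`accel` must have %d columns (3 per sensor), got %d",
                  3 * length(sensors), ncol(accel)),
          class = "gaitfog_validation_error")
  }
  if (!all(is.finite(accel))) {
    abort("`accel` contains non-finite values", class = "gaitfog_validation_error")
  }
  colnames(accel) <- channel_names(sensors)
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    if (!identical(dim(gyro), dim(accel))) {
      abort("`gyro` must match `accel` in shape", class = "gaitfog_validation_error")
    }
    if (!all(is.finite(gyro))) {
      abort("`gyro` contains non-finite values", class = "gaitfog_validation_error")
    }
    colnames(gyro) <- paste0(rep(sensors, each = 3), "_gyr_", rep(FOG_AXES, length(sensors)))
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      trial_id = as.character(trial_id),
      sample_rate_hz = sample_rate_hz,
      sensors = sensors,
      accel = accel,
      gyro = gyro,
      n_samples = nrow(accel)
    ),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, trial %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, x$n_samples, x$sample_rate_hz,
              x$n_samples / x$sample_rate_hz))
  cat("  sensors:", paste(x$sensors, collapse = ", "), "\n")
  cat("  gyroscope:", if (is.null(x$gyro)) "absent" else "present", "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.imu_recording <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$accel))
  if (!is.null(x$gyro)) out <- dplyr::bind_cols(out, as_tibble(as.data.frame(x$gyro)))
  dplyr::bind_cols(
    tibble(
      subject_id = x$subject_id, trial_id = x$trial_id,
      time_s = (seq_len(x$n_samples) - 1) / x$sample_rate_hz
    ),
    out
  )
}

#' Write a recording to its CSV container
#'
#' @param recording An `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "imu_recording")) {
    abort("`recording` must be an imu_recording", class = "gaitfog_validation_error")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# subject_id: ", recording$subject_id),
    paste0("# trial_id: ", recording$trial_id),
    paste0("# sample_rate_hz: ", format(recording$sample_rate_hz)),
    paste0("# sensors: ", paste(recording$sensors, collapse = ","))
  ), con)
  m <- recording$accel
  if (!is.null(recording$gyro)) m <- cbind(m, recording$gyro)
  writeLines(paste(colnames(m), collapse = ","), con)
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Read a recording from its CSV container
#'
#' @param path File written by [write_recording()].
#' @return An `imu_recording`. Malformed headers, non-numeric cells or ragged
#'   rows raise a format error naming the offending line.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  needed <- c("subject_id", "trial_id", "sample_rate_hz", "sensors")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(paste0("recording header is missing: ", paste(missing, collapse = ", ")),
          class = "gaitfog_format_error")
  }
  body_idx <- which(!is_meta)
  if (length(body_idx) < 1) {
    abort("recording file has no column header row", class = "gaitfog_format_error")
  }
  header_line <- body_idx[1]
  cols <- strsplit(lines[header_line], ",", fixed = TRUE)[[1]]
  data_idx <- body_idx[-1]
  n <- length(data_idx)
  vals <- matrix(NA_real_, n, length(cols))
  for (i in seq_len(n)) {
    parts <- strsplit(lines[data_idx[i]], ",", fixed = TRUE)[[1]]
    if (length(parts) != length(cols)) {
      abort(sprintf("line %d: expected %d columns, found %d",
                    data_idx[i], length(cols), length(parts)),
            class = "gaitfog_format_error")
    }
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("line %d: non-numeric or non-finite cell", data_idx[i]),
            class = "gaitfog_format_error")
    }
    vals[i, ] <- v
  }
  sensors <- strsplit(meta$sensors, ",", fixed = TRUE)[[1]]
  sensors <- trimws(sensors)
  fs <- suppressWarnings(as.numeric(meta$sample_rate_hz))
  if (is.na(fs)) {
    abort("recording header: sample_rate_hz is not numeric", class = "gaitfog_format_error")
  }
  acc_cols <- channel_names(resolve_sensors(sensors))
  gyr <- NULL
  if (length(cols) == 2 * length(acc_cols)) {
    gyr <- vals[, (length(acc_cols) + 1):(2 * length(acc_cols)), drop = FALSE]
  } else if (length(cols) != length(acc_cols)) {
    abort(sprintf("column count %d does not match sensor list (%d accel channels)",
                  length(cols), length(acc_cols)),
          class = "gaitfog_format_error")
  }
  new_imu_recording(meta$subject_id, meta$trial_id, fs, sensors,
                    vals[, seq_along(acc_cols), drop = FALSE], gyr)
}

#' Construct a FOG annotation track
#'
#' Intervals are half-open `[start_s, end_s)` in seconds; touching intervals
#' (end of one equals start of the next) are merged, since rater exports often
#' split one episode at frame boundaries. Overlapping intervals are rejected.
#'
#' @param subject_id,trial_id Identifier strings.
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @return A tibble of class `fog_annotations` with columns `subject_id`,
#'   `trial_id`, `start_s`, `end_s`, `label` (always `"FOG"`), sorted by
#'   `start_s`.
#' @export
#' @examples
#' new_fog_annotations("S01", "T1", c(3, 5), c(5, 6))  # merged to [3, 6)
new_fog_annotations <- function(subject_id, trial_id,
                                start_s = numeric(), end_s = numeric()) {
  if (length(start_s) != length(end_s)) {
    abort("`start_s` and `end_s` must have equal length", class = "gaitfog_validation_error")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)) || any(start_s < 0)) {
    abort("interval bounds must be finite and nonnegative", class = "gaitfog_validation_error")
  }
  if (any(start_s >= end_s)) {
    abort("every interval needs start_s < end_s", class = "gaitfog_validation_error")
  }
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1 && any(start_s[-1] < end_s[-length(end_s)])) {
    abort("intervals overlap after sorting", class = "gaitfog_validation_error")
  }
  # merge touching intervals
  if (length(start_s) > 1) {
    ks <- numeric(0); ke <- numeric(0)
    cs <- start_s[1]; ce <- end_s[1]
    for (i in 2:length(start_s)) {
      if (start_s[i] <= ce) {
        ce <- max(ce, end_s[i])
      } else {
        ks <- c(ks, cs); ke <- c(ke, ce)
        cs <- start_s[i]; ce <- end_s[i]
      }
    }
    start_s <- c(ks, cs); end_s <- c(ke, ce)
  }
  out <- tibble(
    subject_id = as.character(subject_id),
    trial_id = as.character(trial_id),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    label = if (length(start_s)) "FOG" else character(0)
  )
  if (nrow(out) == 0) {
    out <- tibble(subject_id = character(0), trial_id = character(0),
                  start_s = numeric(0), end_s = numeric(0), label = character(0))
    attr(out, "subject_id") <- as.character(subject_id)
    attr(out, "trial_id") <- as.character(trial_id)
  }
  class(out) <- c("fog_annotations", class(out))
  out
}

#' Total annotated FOG time
#'
#' @param annotations A `fog_annotations` tibble.
#' @return Summed interval length in seconds.
#' @export
fog_total_seconds <- function(annotations) {
  sum(annotations$end_s - annotations$start_s)
}

#' Write FOG annotations to CSV
#'
#' @param annotations A `fog_annotations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations[, c("subject_id", "trial_id", "start_s", "end_s")])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("subject_id,trial_id,start_s,end_s", con)
  if (nrow(df) > 0) {
    writeLines(sprintf("%s,%s,%.17g,%.17g",
                       df$subject_id, df$trial_id, df$start_s, df$end_s), con)
  }
  invisible(path)
}

#' Read FOG annotations from CSV
#'
#' Expects columns `subject_id, trial_id, start_s, end_s` describing one
#' recording. Intervals are sorted and touching intervals merged on read.
#'
#' @param path Annotation CSV path.
#' @param subject_id,trial_id Identifiers to use when the file is empty
#'   (headers only); ignored otherwise.
#' @return A `fog_annotations` tibble.
#' @export
read_annotations <- function(path, subject_id = NA_character_, trial_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    abort("annotation file must have columns subject_id, trial_id, start_s, end_s",
          class = "gaitfog_format_error")
  }
  if (nrow(df) == 0) {
    return(new_fog_annotations(subject_id, trial_id))
  }
  if (length(unique(df$subject_id)) > 1 || length(unique(df$trial_id)) > 1) {
    abort("annotation file mixes multiple subject/trial pairs",
          class = "gaitfog_validation_error")
  }
  new_fog_annotations(df$subject_id[1], df$trial_id[1], df$start_s, df$end_s)
}

#' Write a cohort manifest
#'
#' The manifest is the cohort's table of contents: one row per recording with
#' its annotation file, medication state and split role.
#'
#' @param manifest Tibble with columns `subject_id`, `trial_id`, `recording`,
#'   `annotation`, `medication_state`, `role` (`train`, `holdout` or
#'   `unseen`).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(as.data.frame(manifest), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest JSON written by [write_manifest()].
#' @param check_paths Verify that referenced files exist (relative paths are
#'   resolved against the manifest's directory).
#' @return Manifest tibble.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_manifest(df)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  df$recording <- resolve(df$recording)
  df$annotation <- resolve(df$annotation)
  if (check_paths) {
    miss <- c(df$recording[!file.exists(df$recording)],
              df$annotation[!file.exists(df$annotation)])
    if (length(miss) > 0) {
      abort(paste0("manifest references missing files: ",
                   paste(utils::head(miss, 3), collapse = ", ")),
            class = "gaitfog_validation_error")
    }
  }
  df
}

validate_manifest <- function(manifest) {
  need <- c("subject_id", "trial_id", "recording", "annotation",
            "medication_state", "role")
  if (!all(need %in% names(manifest))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")),
          class = "gaitfog_validation_error")
  }
  if (anyDuplicated(paste(manifest$subject_id, manifest$trial_id))) {
    abort("(subject_id, trial_id) pairs must be unique", class = "gaitfog_validation_error")
  }
  if (!all(manifest$role %in% c("train", "holdout", "unseen"))) {
    abort("manifest roles must be train, holdout or unseen",
          class = "gaitfog_validation_error")
  }
  invisible(manifest)
}
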