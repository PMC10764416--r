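# Epoching: fixed 2-s windows at 75% overlap, FOG-fraction labels, and the
# window-tensor container consumed by every classifier.

WINDOW_S <- 2
WINDOW_OVERLAP <- 0.75
TARGET_FS <- 60
FOG_POS_FRACTION <- 0.25  # >= 25% FOG inside a window => positive label

#' Enumerate window start indices
#'
#' Windows are `window_s` seconds long with the given fractional overlap
#' (default 2 s / 75%, i.e. a 0.5 s hop = 30 samples at 60 Hz). For an
#' unmasked stream of `L` samples the start indices are
#' `0, step, 2*step, ...` while a full window fits:
#' `floor((L - 120) / 30) + 1` windows. Any window covering an
#' artifact-masked sample is dropped whole, so every surviving window is
#' exactly 120 samples of clean signal.
#'
#' @param clean A `clean_recording` (60 Hz).
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return Integer vector of 0-based start sample indices.
#' @export
segment_starts <- function(clean, window_s = WINDOW_S, overlap = WINDOW_OVERLAP) {
  fs <- clean$sample_rate_hz
  win <- round(window_s * fs)
  step <- round(window_s * (1 - overlap) * fs)
  L <- clean$n_samples
  if (L < win) return(integer(0))
  starts <- seq(0L, L - win, by = step)
  if (any(clean$artifact_mask)) {
    bad_idx <- which(clean$artifact_mask)
    keep <- vapply(starts, function(s) !any(bad_idx > s & bad_idx <= s + win),
                   logical(1))
    starts <- starts[keep]
  }
  starts
}

# Per-sample FOG mask at rate fs: sample i (0-based) covers
# [i/fs, (i+1)/fs); it is FOG when its midpoint falls in an episode.
fog_sample_mask <- function(annotations, n_samples, fs) {
  mid <- ((0:(n_samples - 1)) + 0.5) / fs
  mask <- logical(n_samples)
  for (i in seq_len(nrow(annotations))) {
    mask <- mask | (mid >= annotations$start_s[i] & mid < annotations$end_s[i])
  }
  mask
}

#' Label a window from its FOG fraction
#'
#' A window whose FOG fraction is at least 25% is positive (the boundary
#' counts as FOG); a fraction of exactly zero is negative; anything in
#' between is ambiguous and is discarded during training. At evaluation time
#' the same rule applies by default (symmetric semantics), with an option to
#' score ambiguous windows as negative instead.
#'
#' @param fog_fraction Numeric vector in `[0, 1]`.
#' @param role `"train"`, `"validation"`, `"holdout"` or `"unseen"`.
#' @param score_partial_as_neg At evaluation roles, score `0 < fraction <
#'   0.25` windows as `NEG` instead of discarding them.
#' @return Character vector: `"POS"`, `"NEG"` or `"DISCARD"`.
#' @export
#' @examples
#' label_from_fraction(c(0, 29 / 120, 30 / 120), "train")
label_from_fraction <- function(fog_fraction, role = "train",
                                score_partial_as_neg = FALSE) {
  if (any(!is.finite(fog_fraction)) || any(fog_fraction < 0) || any(fog_fraction > 1)) {
    abort("fog_fraction must lie in [0, 1]", class = "gaitfog_validation_error")
  }
  role <- match.arg(role, c("train", "validation", "holdout", "unseen"))
  out <- rep("DISCARD", length(fog_fraction))
  out[fog_fraction >= FOG_POS_FRACTION] <- "POS"
  out[fog_fraction == 0] <- "NEG"
  if (role != "train" && score_partial_as_neg) {
    out[out == "DISCARD"] <- "NEG"
  }
  out
}

new_fog_windows <- function(x, info, channels, role) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == nrow(info),
            dim(x)[2] == length(channels))
  structure(list(x = x, info = info, channels = channels, role = role,
                 window_s = WINDOW_S, sample_rate_hz = TARGET_FS),
            class = "fog_windows")
}

#' Window one cleaned recording
#'
#' @param clean A `clean_recording`.
#' @param annotations Matching `fog_annotations`.
#' @param role Labeling role, see [label_from_fraction()].
#' @param score_partial_as_neg See [label_from_fraction()].
#' @return A `fog_windows` object: tensor `x` of dim `120 x C x n`, a window
#'   `info` tibble (subject, trial, start time, FOG fraction, label), and the
#'   channel descriptor.
#' @export
window_recording <- function(clean, annotations, role = "train",
                             score_partial_as_neg = FALSE) {
  fs <- clean$sample_rate_hz
  win <- round(WINDOW_S * fs)
  starts <- segment_starts(clean)
  mask <- fog_sample_mask(annotations, clean$n_samples, fs)
  C <- ncol(clean$accel)
  x <- array(0, dim = c(win, C, length(starts)))
  rho <- numeric(length(starts))
  for (j in seq_along(starts)) {
    idx <- (starts[j] + 1):(starts[j] + win)
    x[, , j] <- clean$accel[idx, ]
    rho[j] <- mean(mask[idx])
  }
  info <- tibble(
    subject_id = rep(clean$subject_id, length(starts)),
    trial_id = rep(clean$trial_id, length(starts)),
    start_s = starts / fs,
    fog_fraction = rho,
    label = label_from_fraction(rho, role, score_partial_as_neg)
  )
  new_fog_windows(x, info, colnames(clean$accel), role)
}

#' Assemble a labeled window dataset from a cohort manifest
#'
#' Reads, preprocesses and windows every manifest entry with the requested
#' role, restricted to a sensor configuration. Subject and trial provenance
#' is preserved on every window; windows never span trial boundaries.
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param sensor_config A configuration name from [sensor_configs()] or an
#'   explicit sensor vector.
#' @param role Manifest role to assemble (`"train"`, `"holdout"` or
#'   `"unseen"`).
#' @param score_partial_as_neg See [label_from_fraction()].
#' @return A `fog_windows` dataset.
#' @export
assemble_windows <- function(manifest, sensor_config = "seven", role = "train",
                             score_partial_as_neg = FALSE) {
  sensors <- resolve_sensors(sensor_config)
  entries <- manifest[manifest$role == role, , drop = FALSE]
  if (nrow(entries) == 0) {
    abort(sprintf("manifest has no entries with role '%s'", role),
          class = "gaitfog_validation_error")
  }
  parts <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    rec <- read_recording(entries$recording[i])
    missing <- setdiff(sensors, rec$sensors)
    if (length(missing) > 0) {
      abort(sprintf("subject %s trial %s lacks sensor(s): %s",
                    entries$subject_id[i], entries$trial_id[i],
                    paste(missing, collapse = ", ")),
            class = "gaitfog_validation_error")
    }
    ann <- read_annotations(entries$annotation[i],
                            entries$subject_id[i], entries$trial_id[i])
    clean <- preprocess_recording(rec)
    w <- window_recording(clean, ann, role = role,
                          score_partial_as_neg = score_partial_as_neg)
    parts[[i]] <- select_sensors(w, sensors)
  }
  bind_windows(parts, role)
}

# Concatenate fog_windows objects sharing a channel layout.
bind_windows <- function(parts, role) {
  channels <- parts[[1]]$channels
  for (p in parts) {
    if (!identical(p$channels, channels)) {
      abort("cannot bind window sets with different channel layouts",
            class = "gaitfog_validation_error")
    }
  }
  n <- sum(vapply(parts, function(p) dim(p$x)[3], integer(1)))
  win <- dim(parts[[1]]$x)[1]
  x <- array(0, dim = c(win, length(channels), n))
  at <- 0
  for (p in parts) {
    k <- dim(p$x)[3]
    if (k > 0) x[, , (at + 1):(at + k)] <- p$x
    at <- at + k
  }
  new_fog_windows(x, dplyr::bind_rows(lapply(parts, `[[`, "info")), channels, role)
}

#' Restrict a window dataset to a sensor configuration
#'
#' @param windows A `fog_windows` dataset built from a superset of sensors.
#' @param sensor_config Configuration name or sensor vector.
#' @return A `fog_windows` dataset with `3 * n_sensors` channels.
#' @export
select_sensors <- function(windows, sensor_config) {
  sensors <- resolve_sensors(sensor_config)
  chans <- channel_names(sensors)
  idx <- match(chans, windows$channels)
  if (anyNA(idx)) {
    abort(paste0("dataset lacks channels: ",
                 paste(chans[is.na(idx)], collapse = ", ")),
          class = "gaitfog_validation_error")
  }
  new_fog_windows(windows$x[, idx, , drop = FALSE], windows$info, chans, windows$role)
}

#' Drop discarded windows
#'
#' Removes windows labeled `DISCARD` (ambiguous FOG content); training never
#' sees them.
#'
#' @param windows A `fog_windows` dataset.
#' @return Filtered `fog_windows`.
#' @export
drop_discard <- function(windows) {
  keep <- windows$info$label != "DISCARD"
  subset_windows(windows, keep)
}

subset_windows <- function(windows, keep) {
  new_fog_windows(windows$x[, , keep, drop = FALSE],
                  windows$info[keep, , drop = FALSE],
                  windows$channels, windows$role)
}

#' @export
print.fog_windows <- function(x, ...) {
  counts <- table(factor(x$info$label, levels = c("NEG", "POS", "DISCARD")))
  cat(sprintf("<fog_windows> %d windows x %d channels (role %s)\n",
              dim(x$x)[3], length(x$channels), x$role))
  cat(sprintf("  NEG %d | POS %d | DISCARD %d | subjects %d\n",
              counts["NEG"], counts["POS"], counts["DISCARD"],
              length(unique(x$info$subject_id))))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.fog_windows <- function(x, ...) x$info

#' Class counts of a window dataset
#'
#' @param windows A `fog_windows` dataset.
#' @return Tibble with columns `label` and `n`.
#' @export
class_counts <- function(windows) {
  dplyr::count(windows$info, .data$label, name = "n")
}
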