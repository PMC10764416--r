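# Signal conditioning: artifact rejection, zero-phase band-pass filtering,
# and standardization of the sampling rate to 60 Hz.

ACCEL_ARTIFACT_THRESH <- 100  # m/s^2
GYRO_ARTIFACT_THRESH <- 20    # rad/s
ARTIFACT_GUARD_S <- 0.25

#' Detect artifact samples
#'
#' A sample is flagged when the Euclidean norm of any sensor's 3-axis
#' acceleration exceeds 100 m/s^2, or (when a gyroscope stream is present)
#' any sensor's angular-velocity norm exceeds 20 rad/s. Flagged samples are
#' dilated by a +/- 0.25 s guard so that filter ringing around a spike never
#' reaches a window. Detection runs on the raw, unfiltered recording: the
#' band-pass would shrink spikes below threshold.
#'
#' @param recording An `imu_recording` (raw).
#' @param per_axis Apply the thresholds to individual axis values instead of
#'   the per-sensor vector norm.
#' @return Logical vector of length `recording$n_samples`.
#' @export
detect_artifacts <- function(recording, per_axis = FALSE) {
  flag_mat <- function(m, thresh) {
    n_sens <- ncol(m) / 3
    bad <- rep(FALSE, nrow(m))
    for (si in seq_len(n_sens)) {
      block <- m[, (3 * si - 2):(3 * si), drop = FALSE]
      if (per_axis) {
        bad <- bad | apply(abs(block) > thresh, 1, any)
      } else {
        bad <- bad | (sqrt(rowSums(block^2)) > thresh)
      }
    }
    bad
  }
  bad <- flag_mat(recording$accel, ACCEL_ARTIFACT_THRESH)
  if (!is.null(recording$gyro)) {
    bad <- bad | flag_mat(recording$gyro, GYRO_ARTIFACT_THRESH)
  }
  dilate_mask(bad, round(ARTIFACT_GUARD_S * recording$sample_rate_hz))
}

dilate_mask <- function(mask, guard) {
  if (!any(mask) || guard <= 0) return(mask)
  idx <- which(mask)
  out <- rep(FALSE, length(mask))
  for (i in idx) {
    out[max(1, i - guard):min(length(mask), i + guard)] <- TRUE
  }
  out
}

# Cached third-order Butterworth band-pass coefficients per sampling rate.
butter_coeffs <- local({
  cache <- list()
  function(fs, low = 0.3, high = 15, order = 3) {
    key <- paste(fs, low, high, order)
    if (is.null(cache[[key]])) {
      bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
      cache[[key]] <<- list(b = bf$b, a = bf$a)
    }
    cache[[key]]
  }
})

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth band-pass (0.3-15 Hz by default) applied
#' forward-backward, giving zero net phase and a squared (effectively
#' sixth-order) magnitude response. The pass band spans the locomotor
#' (~0.5-3 Hz) and freeze (~3-8 Hz) bands while removing drift. Edges are
#' padded with an odd reflection of three filter lengths before filtering,
#' the standard zero-phase practice to limit edge transients.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (> 30).
#' @param low,high Band edges in Hz.
#' @param order Butterworth prototype order.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 0.3, high = 15, order = 3) {
  if (fs <= 30) abort("bandpass needs fs > 30 Hz", class = "gaitfog_validation_error")
  co <- butter_coeffs(fs, low, high, order)
  pad <- 3 * (max(length(co$a), length(co$b)) - 1)
  if (length(x) <= pad + 1) {
    abort(sprintf("signal too short to filter (need > %d samples)", pad + 1),
          class = "gaitfog_validation_error")
  }
  n <- length(x)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(co$b, co$a, xp)
  y <- rev(as.numeric(signal::filter(co$b, co$a, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

# Delay-compensated polyphase rational resampler (windowed-sinc low-pass),
# up L / down M. Kaiser window, cutoff at the tighter Nyquist.
resample_poly <- function(x, L, M) {
  half_len <- 10L * max(L, M)
  cutoff <- 1 / max(L, M)                 # in units of the upsampled Nyquist
  j <- (-half_len):half_len
  h <- cutoff * sincf(cutoff * j) * signal::kaiser(2 * half_len + 1, 5)
  h <- h * L / sum(h)
  n_out <- ceiling(length(x) * L / M)
  xu <- numeric(length(x) * L)
  xu[seq(1, length(xu), by = L)] <- x
  # zero-pad both ends so the one-sided convolution is defined everywhere,
  # then undo the filter's group delay (half_len upsampled samples)
  n_taps <- length(h)
  xp <- c(numeric(n_taps - 1), xu, numeric(n_taps - 1))
  yf <- as.numeric(stats::filter(xp, h, method = "convolution", sides = 1))
  aligned <- yf[seq_along(xu) + half_len + n_taps - 1]
  aligned[seq(1, by = M, length.out = n_out)]
}

sincf <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Resample a signal to 60 Hz
#'
#' Identity at 60 Hz; polyphase rational 3/5 resampling (windowed-sinc
#' anti-alias filter, group delay compensated) at 100 Hz. In-band sinusoids
#' are preserved in amplitude to well within 1%.
#'
#' @param x Numeric vector.
#' @param fs Source sampling rate; 60 or 100.
#' @return Vector of length `ceiling(length(x) * 60 / fs)`.
#' @export
resample_to_60 <- function(x, fs) {
  if (fs == 60) return(x)
  if (fs != 100) {
    abort("resample_to_60 supports fs = 60 or 100 only", class = "gaitfog_validation_error")
  }
  resample_poly(x, 3L, 5L)
}

# Map a boolean mask at 100 Hz to 60 Hz by logical OR over every source
# sample whose time support overlaps the output sample's.
resample_mask_to_60 <- function(mask, fs) {
  if (fs == 60) return(mask)
  n_out <- ceiling(length(mask) * 60 / fs)
  out <- logical(n_out)
  idx <- which(mask)
  for (j in idx) {
    # source sample j-1 covers [(j-1)/fs, j/fs)
    lo <- floor((j - 1) / fs * 60)
    hi <- ceiling(j / fs * 60) - 1
    lo <- max(0, lo); hi <- min(n_out - 1, hi)
    if (hi >= lo) out[(lo + 1):(hi + 1)] <- TRUE
  }
  out
}

#' Preprocess a recording
#'
#' The full conditioning chain: artifact detection on the raw signal,
#' zero-phase band-pass of every acceleration channel, downsampling to 60 Hz
#' when needed (the artifact mask is resampled by logical OR over
#' contributing source samples), and dropping of the gyroscope stream, which
#' is consumed only for artifact detection.
#'
#' @param recording An `imu_recording`.
#' @param per_axis Passed to [detect_artifacts()].
#' @return An object of class `clean_recording`: identity fields, a filtered
#'   acceleration matrix at 60 Hz, and a per-sample `artifact_mask`.
#' @export
preprocess_recording <- function(recording, per_axis = FALSE) {
  mask <- detect_artifacts(recording, per_axis = per_axis)
  fs <- recording$sample_rate_hz
  filt <- apply(recording$accel, 2, bandpass, fs = fs)
  if (fs != 60) {
    filt <- apply(filt, 2, resample_to_60, fs = fs)
    mask <- resample_mask_to_60(mask, fs)
  }
  colnames(filt) <- colnames(recording$accel)
  structure(list(
    subject_id = recording$subject_id,
    trial_id = recording$trial_id,
    sample_rate_hz = 60,
    sensors = recording$sensors,
    accel = filt,
    artifact_mask = mask,
    n_samples = nrow(filt)
  ), class = "clean_recording")
}

#' @export
print.clean_recording <- function(x, ...) {
  cat(sprintf("<clean_recording> subject %s, trial %s: %d samples @ 60 Hz, %d masked\n",
              x$subject_id, x$trial_id, x$n_samples, sum(x$artifact_mask)))
  invisible(x)
}
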