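# Seeded synthetic gait/FOG cohort generator.
#
# Signal model: walking is a two-harmonic locomotor oscillation at the
# subject's step frequency (left and right legs in anti-phase); trembling
# freezing replaces it with a 3-8 Hz oscillation plus a suppressed locomotor
# residue; akinetic freezing suppresses nearly all movement. Transitions are
# blended with 0.25 s raised-cosine crossfades. Episodes follow an
# alternating renewal process with log-normal episode durations. The model is
# deliberately minimal: it makes FOG windows spectrally separable from gait
# (freeze-band versus locomotor-band power) without being trivially
# amplitude-separable.

#' Simulation configuration
#'
#' @param n_subjects Number of subjects in the main (train + hold-out) cohort.
#' @param n_unseen Number of additional subjects forming the unseen test
#'   cohort (default 0).
#' @param trials_per_subject Recordings per subject.
#' @param trial_duration_s Duration of each recording in seconds (>= 4).
#' @param sample_rate_hz 60 or 100 Hz.
#' @param sensors Sensor subset to simulate (canonical names or a
#'   configuration name understood by [sensor_configs()]).
#' @param with_gyro Also synthesize gyroscope channels (used downstream only
#'   for artifact detection).
#' @param artifact_rate_per_min Poisson rate of injected artifact spikes.
#' @param fog_time_fraction Mean of the per-subject FOG-time fraction
#'   distribution; the default 0.105 reflects cohorts with roughly 9-12%
#'   of walking time spent frozen.
#' @param akinetic_prob Probability that an episode is akinetic rather than
#'   trembling; 0 gives a pure trembling-phenotype cohort.
#' @param fog_affects_lumbar If `FALSE`, the lumbar channels carry on with
#'   normal gait through freezing episodes, so only leg/foot channels carry
#'   FOG information (used for ablation sanity checks).
#' @param holdout_fraction Fraction of main-cohort subjects assigned to the
#'   hold-out role when a cohort is generated.
#' @param seed Integer seed; the entire cohort is a pure function of this
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       n_unseen = 0,
                       trials_per_subject = 1,
                       trial_duration_s = 300,
                       sample_rate_hz = 60,
                       sensors = "seven",
                       with_gyro = FALSE,
                       artifact_rate_per_min = 0,
                       fog_time_fraction = 0.105,
                       akinetic_prob = 0.15,
                       fog_affects_lumbar = TRUE,
                       holdout_fraction = 0.2,
                       seed = 1L) {
  if (n_subjects < 1) abort("need n_subjects >= 1", class = "gaitfog_validation_error")
  if (trial_duration_s < 4) abort("need trial_duration_s >= 4", class = "gaitfog_validation_error")
  if (!sample_rate_hz %in% c(60, 100)) {
    abort("sample_rate_hz must be 60 or 100", class = "gaitfog_validation_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_unseen = as.integer(n_unseen),
    trials_per_subject = as.integer(trials_per_subject),
    trial_duration_s = trial_duration_s,
    sample_rate_hz = sample_rate_hz,
    sensors = resolve_sensors(sensors),
    with_gyro = isTRUE(with_gyro),
    artifact_rate_per_min = artifact_rate_per_min,
    fog_time_fraction = fog_time_fraction,
    akinetic_prob = akinetic_prob,
    fog_affects_lumbar = isTRUE(fog_affects_lumbar),
    holdout_fraction = holdout_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-sensor baseline locomotor amplitudes (m/s^2): distal sensors move more.
LOC_AMP_BASE <- c(
  lumbar = 1.0,
  upper_leg_left = 2.0, upper_leg_right = 2.0,
  lower_leg_left = 3.0, lower_leg_right = 3.0,
  foot_left = 3.5, foot_right = 3.5
)

#' Draw subject-level simulation parameters
#'
#' Deterministic given `(config$seed, subject_index)`: step frequency from a
#' clamped normal around 1.7 Hz, per-sensor locomotor amplitudes around
#' distal-dominant baselines, a trembling frequency in the 3-8 Hz freeze
#' band, a per-subject FOG-time target around `config$fog_time_fraction`,
#' and gait anti-phase close to pi.
#'
#' @param config A [sim_config()].
#' @param subject_index Positive integer.
#' @return A list of class `subject_params`.
#' @export
sample_subject_params <- function(config, subject_index) {
  with_seed(derive_seed(config$seed, "subject_params", subject_index), {
    step <- min(2.5, max(1.0, rnorm(1, 1.7, 0.25)))
    amp_scale <- exp(rnorm(1, 0, 0.2))
    loc_amp <- LOC_AMP_BASE * amp_scale * exp(rnorm(length(LOC_AMP_BASE), 0, 0.1))
    frac <- config$fog_time_fraction
    if (frac > 0) {
      # Beta draw with mean `frac`, concentration 60: subjects differ but the
      # cohort mean stays near the target.
      frac <- stats::rbeta(1, frac * 60, (1 - frac) * 60)
    }
    structure(list(
      step_freq_hz = step,
      loc_amp = loc_amp,
      tremble_freq_hz = runif(1, 3.5, 7.0),
      tremble_amplitude = runif(1, 1.2, 2.2) * amp_scale,
      fog_time_fraction_target = frac,
      mean_episode_s = runif(1, 4, 10),
      akinetic_prob = config$akinetic_prob,
      noise_sd = runif(1, 0.1, 0.3),
      phase_left_right = pi + rnorm(1, 0, 0.15),
      fog_walk_atten = runif(1, 0.15, 0.35),
      axis_weights = c(x = 1, y = runif(1, 0.5, 0.8), z = runif(1, 0.3, 0.6))
    ), class = "subject_params")
  })
}

#' Simulate a freezing-episode schedule
#'
#' Alternating renewal process: walking segments are exponential with mean
#' chosen so the expected FOG fraction matches
#' `params$fog_time_fraction_target`; episode durations are log-normal with
#' mean `params$mean_episode_s` and fixed log-scale sigma 0.5.
#'
#' @param duration_s Trial duration in seconds (>= 4).
#' @param params A [sample_subject_params()] result.
#' @param seed Integer seed.
#' @param subject_id,trial_id Identifiers stamped on the annotation track.
#' @return A `fog_annotations` tibble (empty when the target fraction is 0).
#' @export
episode_schedule <- function(duration_s, params, seed,
                             subject_id = "SIM", trial_id = "T1") {
  if (duration_s < 4) abort("need duration_s >= 4", class = "gaitfog_validation_error")
  f <- params$fog_time_fraction_target
  if (f <= 0) return(new_fog_annotations(subject_id, trial_id))
  mean_ep <- params$mean_episode_s
  mean_walk <- mean_ep * (1 - f) / f
  sdlog <- 0.5
  meanlog <- log(mean_ep) - sdlog^2 / 2   # E[lognormal] = mean_ep
  with_seed(derive_seed(seed, "episodes"), {
    t <- 0
    starts <- numeric(0); ends <- numeric(0)
    repeat {
      t <- t + stats::rexp(1, rate = 1 / mean_walk)
      if (t >= duration_s) break
      len <- rlnorm(1, meanlog, sdlog)
      e <- min(t + len, duration_s)
      if (e > t) { starts <- c(starts, t); ends <- c(ends, e) }
      t <- e
      if (t >= duration_s) break
    }
    new_fog_annotations(subject_id, trial_id, starts, ends)
  })
}

# Raised-cosine FOG weight for one interval set: ramps 0 -> 1 over `ramp_s`
# starting at each episode start and 1 -> 0 ending at each episode end.
episode_weight <- function(tvec, starts, ends, ramp_s = 0.25) {
  w <- numeric(length(tvec))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    r <- min(ramp_s, (e - s) / 2)
    inside <- tvec >= s & tvec < e
    wi <- rep(1, sum(inside))
    ti <- tvec[inside]
    up <- ti < s + r
    wi[up] <- 0.5 * (1 - cos(pi * (ti[up] - s) / r))
    dn <- ti >= e - r
    wi[dn] <- pmin(wi[dn], 0.5 * (1 - cos(pi * (e - ti[dn]) / r)))
    w[inside] <- pmax(w[inside], wi)
  }
  w
}

#' Synthesize a recording for one subject-trial
#'
#' @param params Subject parameters from [sample_subject_params()].
#' @param schedule `fog_annotations` giving FOG episodes; must lie within the
#'   trial duration.
#' @param config A [sim_config()].
#' @param seed Integer seed (noise, phases, per-episode phenotype).
#' @param subject_id,trial_id Identifiers for the recording.
#' @return An `imu_recording`.
#' @export
synth_recording <- function(params, schedule, config, seed,
                            subject_id = "SIM", trial_id = "T1") {
  fs <- config$sample_rate_hz
  dur <- config$trial_duration_s
  if (nrow(schedule) > 0 && max(schedule$end_s) > dur + 1e-9) {
    abort("episode schedule exceeds trial duration", class = "gaitfog_validation_error")
  }
  n <- round(dur * fs)
  tvec <- (0:(n - 1)) / fs
  sensors <- config$sensors
  with_seed(derive_seed(seed, "signal"), {
    # per-episode phenotype
    n_ep <- nrow(schedule)
    akinetic <- if (n_ep > 0) runif(n_ep) < params$akinetic_prob else logical(0)
    w_trem <- episode_weight(tvec, schedule$start_s[!akinetic], schedule$end_s[!akinetic])
    w_akin <- episode_weight(tvec, schedule$start_s[akinetic], schedule$end_s[akinetic])
    w_fog <- pmin(1, w_trem + w_akin)

    accel <- matrix(0, n, 3 * length(sensors))
    gyro <- if (config$with_gyro) matrix(0, n, 3 * length(sensors)) else NULL
    f <- params$step_freq_hz
    # axis phases shared across sensors so that left/right counterparts stay
    # anti-phase by exactly phase_left_right
    ax_phase <- runif(3, 0, 2 * pi)
    for (si in seq_along(sensors)) {
      s <- sensors[si]
      right <- grepl("right$", s)
      ph <- if (right) params$phase_left_right else 0
      amp <- params$loc_amp[[s]]
      trem_amp <- if (s == "lumbar") 0.3 * params$tremble_amplitude else params$tremble_amplitude
      for (ai in 1:3) {
        aw <- params$axis_weights[ai]
        ph_ax <- ax_phase[ai]
        walk <- amp * aw * (sin(2 * pi * f * tvec + ph + ph_ax) +
                              0.4 * sin(4 * pi * f * tvec + 2 * (ph + ph_ax) + 0.5))
        trem <- trem_amp * aw * sin(2 * pi * params$tremble_freq_hz * tvec + runif(1, 0, 2 * pi)) *
          (1 + 0.2 * sin(2 * pi * 0.7 * tvec + runif(1, 0, 2 * pi)))
        if (s == "lumbar" && !config$fog_affects_lumbar) {
          x <- walk
        } else {
          x <- (1 - w_fog) * walk +
            w_trem * (trem + params$fog_walk_atten * walk) +
            w_akin * (0.05 * walk)
        }
        x <- x + rnorm(n, 0, params$noise_sd)
        accel[, 3 * (si - 1) + ai] <- x
        if (!is.null(gyro)) {
          # modest angular velocity tracking the locomotor pattern, well below
          # the 20 rad/s artifact threshold
          gyro[, 3 * (si - 1) + ai] <- 0.15 * x / max(1, amp) * 2 +
            rnorm(n, 0, 0.02)
        }
      }
    }
    new_imu_recording(subject_id, trial_id, fs, sensors, accel, gyro)
  })
}

#' Inject artifact spikes into a recording
#'
#' Inserts isolated single-sample spikes exceeding the artifact thresholds
#' (acceleration magnitude > 100 m/s^2 and, when a gyroscope stream is
#' present, angular velocity > 20 rad/s) at Poisson-distributed times.
#'
#' @param recording An `imu_recording`.
#' @param artifact_rate_per_min Nonnegative Poisson rate.
#' @param seed Integer seed.
#' @return List with elements `recording` (modified copy) and
#'   `artifact_times` (numeric vector of spike times in seconds).
#' @export
inject_artifacts <- function(recording, artifact_rate_per_min, seed) {
  if (artifact_rate_per_min < 0) {
    abort("artifact rate must be >= 0", class = "gaitfog_validation_error")
  }
  fs <- recording$sample_rate_hz
  dur_min <- recording$n_samples / fs / 60
  with_seed(derive_seed(seed, "artifacts"), {
    k <- rpois(1, artifact_rate_per_min * dur_min)
    if (k == 0) {
      return(list(recording = recording, artifact_times = numeric(0)))
    }
    idx <- sort(unique(pmin(recording$n_samples, 1 + floor(runif(k) * recording$n_samples))))
    cols <- 1 + floor(runif(length(idx)) * ncol(recording$accel))
    for (j in seq_along(idx)) {
      cur <- recording$accel[idx[j], cols[j]]
      recording$accel[idx[j], cols[j]] <- cur + sign(cur + 1e-12) * 150
      if (!is.null(recording$gyro)) {
        curg <- recording$gyro[idx[j], cols[j]]
        recording$gyro[idx[j], cols[j]] <- curg + sign(curg + 1e-12) * 25
      }
    }
    list(recording = recording, artifact_times = (idx - 1) / fs)
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Simulates every subject and trial, injects artifacts, writes recordings and
#' annotation tracks in the package CSV formats, assigns main-cohort subjects
#' to train/hold-out roles by a FOG-stratified subject split, and writes a
#' manifest JSON. Byte-reproducible from the configuration alone.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (invisibly also written to
#'   `file.path(dir, "manifest.json")`).
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_subjects = 5, trial_duration_s = 30, seed = 7)
#' man <- generate_cohort(cfg, tempfile("cohort"))
#' table(man$role)
#' }
generate_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- c(sprintf("S%02d", seq_len(config$n_subjects)),
                if (config$n_unseen > 0) sprintf("U%02d", seq_len(config$n_unseen)))
  unseen <- startsWith(subjects, "U")
  rows <- list()
  fog_pct <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    params <- sample_subject_params(config, i)
    tot_fog <- 0; tot <- 0
    for (tr in seq_len(config$trials_per_subject)) {
      tid <- sprintf("T%02d", tr)
      sseed <- derive_seed(config$seed, "trial", i, tr)
      ann <- episode_schedule(config$trial_duration_s, params, sseed, sid, tid)
      rec <- synth_recording(params, ann, config, sseed, sid, tid)
      if (config$artifact_rate_per_min > 0) {
        rec <- inject_artifacts(rec, config$artifact_rate_per_min, sseed)$recording
      }
      rec_path <- file.path(dir, sprintf("%s_%s.csv", sid, tid))
      ann_path <- file.path(dir, sprintf("%s_%s_fog.csv", sid, tid))
      write_recording(rec, rec_path)
      write_annotations(ann, ann_path)
      tot_fog <- tot_fog + fog_total_seconds(ann)
      tot <- tot + config$trial_duration_s
      rows[[length(rows) + 1]] <- tibble(
        subject_id = sid, trial_id = tid,
        recording = basename(rec_path), annotation = basename(ann_path),
        medication_state = if (i %% 2 == 0) "ON" else "OFF",
        role = if (unseen[i]) "unseen" else "train"
      )
    }
    fog_pct[i] <- 100 * tot_fog / tot
  }
  manifest <- dplyr::bind_rows(rows)
  main <- subjects[!unseen]
  if (length(main) >= 5 && config$holdout_fraction > 0) {
    split <- holdout_split(
      tibble(subject_id = main, fog_pct = fog_pct[!unseen]),
      fraction = config$holdout_fraction,
      seed = derive_seed(config$seed, "holdout")
    )
    manifest$role[manifest$subject_id %in% split$holdout_subjects] <- "holdout"
  }
  path <- file.path(dir, "manifest.json")
  write_manifest(manifest, path)
  read_manifest(path)
}
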