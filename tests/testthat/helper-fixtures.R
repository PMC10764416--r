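# Shared fixtures, built once per test run and cached in-session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Hand-built subject parameters for direct control in generator tests.
make_params <- function(step_freq_hz = 1.8,
                        loc_amp = c(lumbar = 1, upper_leg_left = 2,
                                    upper_leg_right = 2, lower_leg_left = 3,
                                    lower_leg_right = 3, foot_left = 3.5,
                                    foot_right = 3.5),
                        tremble_freq_hz = 5,
                        tremble_amplitude = 1.8,
                        fog_time_fraction_target = 0.1,
                        mean_episode_s = 5,
                        akinetic_prob = 0,
                        noise_sd = 0.15,
                        phase_left_right = pi,
                        fog_walk_atten = 0.25,
                        axis_weights = c(x = 1, y = 0.6, z = 0.4)) {
  structure(list(step_freq_hz = step_freq_hz, loc_amp = loc_amp,
                 tremble_freq_hz = tremble_freq_hz,
                 tremble_amplitude = tremble_amplitude,
                 fog_time_fraction_target = fog_time_fraction_target,
                 mean_episode_s = mean_episode_s,
                 akinetic_prob = akinetic_prob, noise_sd = noise_sd,
                 phase_left_right = phase_left_right,
                 fog_walk_atten = fog_walk_atten,
                 axis_weights = axis_weights),
            class = "subject_params")
}

# Small mixed cohort (lumbar + lower legs, gyro, artifacts) used across
# modules: 6 main subjects + 1 unseen, 2-minute trials.
small_manifest <- function() fixture("small_manifest", {
  cfg <- sim_config(n_subjects = 6, n_unseen = 1, trial_duration_s = 120,
                    sensors = c("lumbar", "lower_leg_left", "lower_leg_right"),
                    with_gyro = TRUE, artifact_rate_per_min = 0.5,
                    akinetic_prob = 0.2, seed = 11)
  generate_cohort(cfg, file.path(tempdir(), "gaitfog_small_cohort"))
})

small_windows <- function() fixture("small_windows", {
  assemble_windows(small_manifest(),
                   c("lumbar", "lower_leg_left", "lower_leg_right"),
                   role = "train")
})

# Subject-held-out train/validation split of the small cohort, lower legs.
small_split <- function() fixture("small_split", {
  w <- select_sensors(small_windows(), "lower_legs")
  subj <- sort(unique(w$info$subject_id))
  # validate on a subject that contributes both classes
  ok <- vapply(subj, function(s) {
    lab <- w$info$label[w$info$subject_id == s]
    sum(lab == "POS") >= 10 && sum(lab == "NEG") >= 10
  }, logical(1))
  val <- subj[which(ok)[1]]
  list(train = gaitfog:::subset_windows(w, !(w$info$subject_id %in% val)),
       val = gaitfog:::subset_windows(w, w$info$subject_id %in% val))
})

# Desk-scale experiment configuration: every protocol constant that affects
# model structure is kept, sizes are cut so a full pipeline run stays fast.
tiny_experiment_config <- function(seed = 13) {
  experiment_config(
    sim = sim_config(n_subjects = 6, n_unseen = 1, trial_duration_s = 120,
                     sensors = c("lumbar", "lower_leg_left", "lower_leg_right"),
                     artifact_rate_per_min = 0.2, akinetic_prob = 0.15),
    cnn = cnn_config(epochs = 3L),
    inception = inception_config(n_ensemble = 1L, bottleneck = 8L,
                                 n_filters = 8L, epochs = 2L),
    minirocket = minirocket_config(feature_budget = 840L, head_epochs = 3L),
    k = 5L,
    sensor_ablation = c("lower_legs", "lumbar"),
    seed = seed)
}

# One full pipeline run on the tiny configuration, shared across test files.
tiny_run <- function() fixture("tiny_run", {
  exp1 <- run_experiment(tiny_experiment_config(), dir = tempfile("tiny_run"))
  path <- file.path(tempdir(), "tiny_report.json")
  write_experiment_report(exp1, path)
  list(experiment = exp1, report = path)
})

# Brute-force reference ROC AUC via the Mann-Whitney pair count.
mw_auc <- function(labels, probs) {
  y <- labels == "POS" | labels == TRUE | labels == 1
  pos <- probs[y]; neg <- probs[!y]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Digital magnitude response |H(f)| of a b/a filter at frequency f (Hz).
filter_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  Mod(sum(b * z) / sum(a * za))
}

rms <- function(x) sqrt(mean(x^2))
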