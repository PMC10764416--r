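# Orchestration: one call that reproduces the full experiment on a synthetic
# cohort — simulate, preprocess, window, cross-validate three families,
# pick the best, ablate sensor configurations, choose the operating
# threshold, and score the frozen model on the hold-out and unseen sets.

#' Experiment configuration
#'
#' Bundles the simulation settings, per-family model configurations, the
#' cross-validation layout and the sensor-configuration list. Every modeling
#' constant defaults to the reference protocol; overrides are echoed
#' verbatim in the experiment report.
#'
#' @param sim A [sim_config()].
#' @param cnn,inception,minirocket Family configurations.
#' @param k Number of CV folds.
#' @param families Model families entered into the comparison.
#' @param sensor_ablation Sensor configuration names for the ablation.
#' @param score_partial_as_neg Evaluation handling of ambiguous windows, see
#'   [label_from_fraction()].
#' @param seed Global seed; stage seeds derive from it by name.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(n_subjects = 10, n_unseen = 2),
                              cnn = cnn_config(),
                              inception = inception_config(),
                              minirocket = minirocket_config(),
                              k = 5L,
                              families = c("cnn", "inceptiontime", "minirocket"),
                              sensor_ablation = names(sensor_configs()),
                              score_partial_as_neg = FALSE,
                              seed = 1L) {
  structure(list(sim = sim, cnn = cnn, inception = inception,
                 minirocket = minirocket, k = as.integer(k),
                 families = families, sensor_ablation = sensor_ablation,
                 score_partial_as_neg = score_partial_as_neg,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Highest mean AUC wins; exact ties break toward fewer sensors.
select_best_config <- function(ablation_table) {
  at <- ablation_table
  cand <- at[at$mean_auc >= max(at$mean_auc) - 1e-12, , drop = FALSE]
  cand$sensor_config[order(cand$n_sensors)][1]
}

family_config <- function(config, family) {
  switch(family,
         cnn = config$cnn,
         inceptiontime = config$inception,
         minirocket = config$minirocket)
}

#' Run the full experiment
#'
#' Executes the complete chain on a synthetic cohort: generate, preprocess
#' and window; five-fold subject-grouped CV of every family on the full
#' sensor set; family selection by highest mean CV AUC; sensor ablation of
#' the selected family with identical folds; configuration selection by
#' highest mean AUC with ties broken toward fewer sensors; threshold
#' selection by maximum geometric mean on the selected configuration's
#' pooled out-of-fold predictions; and a single evaluation of the frozen
#' model + threshold on the hold-out and (if simulated) unseen cohorts.
#'
#' @param config An [experiment_config()].
#' @param dir Working directory for the generated cohort (a fresh temporary
#'   directory by default).
#' @return A list of class `fog_experiment`; see [write_experiment_report()].
#' @export
run_experiment <- function(config = experiment_config(), dir = tempfile("fog_cohort")) {
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  manifest <- generate_cohort(sim, dir)

  windows <- assemble_windows(manifest, sim$sensors, role = "train")

  folds <- grouped_kfold(unique(windows$info$subject_id), k = config$k,
                         seed = derive_seed(config$seed, "folds"))

  family_cv <- list()
  for (fam in config$families) {
    family_cv[[fam]] <- run_cv(windows, fam, folds,
                               config = family_config(config, fam),
                               seed = derive_seed(config$seed, "cv"))
  }
  family_table <- dplyr::bind_rows(lapply(family_cv, glance))
  best_family <- family_table$family[which.max(family_table$mean_auc)]

  ablate_names <- config$sensor_ablation[
    vapply(config$sensor_ablation,
           function(nm) all(sensor_configs()[[nm]] %in% sim$sensors), logical(1))]
  ablation <- run_sensor_ablation(windows, best_family, folds,
                                  configs = ablate_names,
                                  config = family_config(config, best_family),
                                  seed = derive_seed(config$seed, "ablate"))
  best_config <- select_best_config(ablation$table)

  sel_cv <- ablation$cv[[best_config]]
  thr <- gmean_threshold(sel_cv$predictions$label, sel_cv$predictions$prob)

  final_model <- train_model_family(
    select_sensors(windows, best_config), best_family,
    family_config(config, best_family),
    derive_seed(config$seed, "final_model"))

  eval_one <- function(role) {
    if (!role %in% manifest$role) return(NULL)
    w <- assemble_windows(manifest, best_config, role = role,
                          score_partial_as_neg = config$score_partial_as_neg)
    p <- predict_proba(final_model, w)
    confusion_metrics(p$label, p$prob, thr$threshold)
  }
  holdout <- eval_one("holdout")
  unseen <- eval_one("unseen")

  structure(list(
    config = config,
    cohort_dir = dir,
    n_windows = nrow(windows$info),
    family_table = family_table,
    family_cv = family_cv,
    selected_family = best_family,
    ablation = ablation,
    selected_sensor_config = best_config,
    threshold = thr,
    holdout_metrics = holdout,
    unseen_metrics = unseen
  ), class = "fog_experiment")
}

#' @export
print.fog_experiment <- function(x, ...) {
  cat("<fog_experiment>\n")
  cat(sprintf("  %d training windows; selected %s on %s at threshold %.3f (g-mean %.3f)\n",
              x$n_windows, x$selected_family, x$selected_sensor_config,
              x$threshold$threshold, x$threshold$gmean))
  print(x$family_table)
  invisible(x)
}

# Strip functions/environments down to plain lists for a stable JSON echo.
config_echo <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), config_echo))
  x
}

#' Write an experiment report as JSON
#'
#' The report contains the full config echo, seeds, per-family CV results,
#' the ablation table, the chosen threshold and the test-set metrics. With a
#' fixed config + seed the file is byte-identical across runs.
#'
#' @param experiment A [run_experiment()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(experiment, path) {
  x <- experiment
  report <- list(
    package_version = as.character(utils::packageVersion("gaitfog")),
    seed = x$config$seed,
    config = config_echo(x$config),
    n_windows = x$n_windows,
    families = lapply(x$family_cv, function(cv) {
      list(mean_auc = cv$summary$mean_auc, sd_auc = cv$summary$sd_auc,
           fold_auc = as.numeric(cv$summary$fold_auc))
    }),
    selected_family = x$selected_family,
    ablation = as.data.frame(x$ablation$table),
    selected_sensor_config = x$selected_sensor_config,
    threshold = as.data.frame(x$threshold),
    holdout_metrics = if (is.null(x$holdout_metrics)) NULL else as.data.frame(x$holdout_metrics),
    unseen_metrics = if (is.null(x$unseen_metrics)) NULL else as.data.frame(x$unseen_metrics)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
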