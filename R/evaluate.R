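# Evaluation: subject-grouped splitting and cross-validation, ROC/AUC,
# geometric-mean threshold selection, confusion metrics, and the
# sensor-configuration ablation.

#' ROC curve and AUC
#'
#' Operating points at every distinct score value (prediction positive when
#' `prob >= threshold`), with the trapezoid-rule area. The AUC equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param labels `"POS"`/`"NEG"`, logical or 0/1 vector; both classes
#'   required.
#' @param probs Numeric scores.
#' @return List of class `fog_roc`: `roc` (tibble `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc  # 0.75
roc_auc <- function(labels, probs) {
  y <- as_binary_labels(labels)
  if (all(y) || !any(y)) {
    abort("ROC needs both classes", class = "gaitfog_validation_error")
  }
  o <- order(probs, decreasing = TRUE)
  y <- y[o]; p <- probs[o]
  n_pos <- sum(y); n_neg <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(p[-1] != p[-length(p)], TRUE)  # last index within each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, p[last])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(roc = tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "fog_roc")
}

#' @export
print.fog_roc <- function(x, ...) {
  cat(sprintf("<fog_roc> AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$roc)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fog_roc <- function(x, ...) x$roc

#' @exportS3Method generics::glance
glance.fog_roc <- function(x, ...) tibble(auc = x$auc)

#' Vertically averaged ROC across folds
#'
#' TPR is linearly interpolated on a common grid of 101 equally spaced FPR
#' points and averaged across folds; the band is the population
#' (ddof = 0) standard deviation. The mean AUC is the arithmetic mean of the
#' per-fold AUCs (not the area under the mean curve).
#'
#' @param rocs List of `fog_roc` objects (>= 2).
#' @param n_grid Number of FPR grid points.
#' @return List of class `fog_mean_roc`: `curve` (tibble `fpr`, `mean_tpr`,
#'   `sd_tpr`), `mean_auc`, `sd_auc`, `fold_auc`.
#' @export
mean_roc <- function(rocs, n_grid = 101) {
  if (length(rocs) < 2) abort("need >= 2 folds", class = "gaitfog_validation_error")
  grid <- seq(0, 1, length.out = n_grid)
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$roc$fpr, r$roc$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(n_grid))
  aucs <- vapply(rocs, `[[`, numeric(1), "auc")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(
    curve = tibble(fpr = grid,
                   mean_tpr = rowMeans(tprs),
                   sd_tpr = apply(tprs, 1, pop_sd)),
    mean_auc = mean(aucs),
    sd_auc = pop_sd(aucs),
    fold_auc = aucs
  ), class = "fog_mean_roc")
}

#' @export
print.fog_mean_roc <- function(x, ...) {
  cat(sprintf("<fog_mean_roc> mean AUC = %.3f (SD %.3f) over %d folds\n",
              x$mean_auc, x$sd_auc, length(x$fold_auc)))
  invisible(x)
}

#' Threshold by maximum geometric mean
#'
#' Evaluates the geometric mean of sensitivity and specificity,
#' `sqrt(TPR * (1 - FPR))`, at every ROC operating point and returns the
#' maximizer; ties break toward the larger threshold.
#'
#' @inheritParams roc_auc
#' @return One-row tibble: `threshold`, `gmean`, `sensitivity`,
#'   `specificity`.
#' @export
gmean_threshold <- function(labels, probs) {
  r <- roc_auc(labels, probs)$roc
  g <- sqrt(r$tpr * (1 - r$fpr))
  best <- max(g)
  cand <- which(g >= best - 1e-15)
  pick <- cand[which.max(r$threshold[cand])]
  thr <- r$threshold[pick]
  if (!is.finite(thr)) thr <- 1
  tibble(threshold = thr, gmean = g[pick],
         sensitivity = r$tpr[pick], specificity = 1 - r$fpr[pick])
}

#' Confusion metrics at a threshold
#'
#' Predictions are positive when `prob >= threshold`. Precision and F-score
#' are `NA` when no window is predicted positive.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold in `[0, 1]`.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `f_score`, `auc`.
#' @export
confusion_metrics <- function(labels, probs, threshold) {
  y <- as_binary_labels(labels)
  pred <- probs >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  auc <- if (any(y) && !all(y)) roc_auc(y, probs)$auc else NA_real_
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         precision = prec, f_score = f, auc = auc)
}

#' Stratified 80/20 subject split
#'
#' Subjects are binned by their FOG-time percentage (quartile bins among
#' subjects with any FOG; subjects with none form their own bin) and the
#' hold-out fraction is drawn from every bin, so the hold-out set mirrors
#' the cohort's FOG occurrence.
#'
#' @param subject_table Tibble with columns `subject_id` and `fog_pct`
#'   (percentage of recorded time spent frozen); >= 5 subjects.
#' @param fraction Hold-out fraction.
#' @param seed Integer seed.
#' @return List of class `subject_split`: `train_subjects`,
#'   `holdout_subjects`, `bins` (tibble subject_id, bin).
#' @export
holdout_split <- function(subject_table, fraction = 0.2, seed = 1L) {
  if (nrow(subject_table) < 5) {
    abort("stratified split needs >= 5 subjects", class = "gaitfog_validation_error")
  }
  df <- subject_table
  nz <- df$fog_pct > 0
  bin <- rep("none", nrow(df))
  if (sum(nz) > 0) {
    qs <- unique(quantile(df$fog_pct[nz], probs = c(0.25, 0.5, 0.75)))
    bin[nz] <- paste0("q", 1 + findInterval(df$fog_pct[nz], qs, left.open = TRUE))
  }
  n_hold <- max(1, round(nrow(df) * fraction))
  bins <- split(df$subject_id, bin)
  holdout <- with_seed(derive_seed(seed, "holdout_split"), {
    # largest-remainder allocation of n_hold across bins; fractional
    # remainders are assigned at random (weighted by remainder) so no bin is
    # systematically favored across seeds
    sizes <- vapply(bins, length, integer(1))
    exact <- sizes * n_hold / sum(sizes)
    alloc <- floor(exact)
    rem <- n_hold - sum(alloc)
    if (rem > 0) {
      frac <- pmax(exact - alloc, 1e-9)
      frac[alloc >= sizes] <- 1e-12
      extra <- sample(seq_along(bins), rem, prob = frac)
      for (i in extra) alloc[i] <- alloc[i] + 1
    }
    alloc <- pmin(alloc, sizes)
    short <- n_hold - sum(alloc)
    while (short > 0) {  # bins exhausted; spill into bins with room
      room <- which(alloc < sizes)
      alloc[room[1]] <- alloc[room[1]] + 1
      short <- short - 1
    }
    unlist(lapply(seq_along(bins), function(i) {
      if (alloc[i] == 0) return(character(0))
      sample(bins[[i]], alloc[i])
    }), use.names = FALSE)
  })
  structure(list(
    train_subjects = sort(setdiff(df$subject_id, holdout)),
    holdout_subjects = sort(holdout),
    bins = tibble(subject_id = df$subject_id, bin = bin)
  ), class = "subject_split")
}

#' Subject-grouped k-fold assignment
#'
#' Partitions subjects (never windows) into k near-equal validation groups,
#' so no person contributes to both sides of a fold.
#'
#' @param subjects Character vector of subject ids (>= k).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of class `fold_assignment`: k character vectors of
#'   validation subjects.
#' @export
grouped_kfold <- function(subjects, k = 5, seed = 1L) {
  subjects <- unique(subjects)
  if (length(subjects) < k) {
    abort(sprintf("need at least k = %d subjects, have %d", k, length(subjects)),
          class = "gaitfog_validation_error")
  }
  shuffled <- with_seed(derive_seed(seed, "kfold"), sample(subjects))
  folds <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  structure(unname(folds), class = "fold_assignment")
}

train_model_family <- function(windows, family, config = NULL, seed = 1L) {
  switch(family,
    cnn = train_cnn(windows, config %||% cnn_config(), seed),
    inceptiontime = train_inceptiontime(windows, config %||% inception_config(), seed),
    minirocket = train_minirocket(windows, config %||% minirocket_config(), seed),
    abort(paste0("unknown model family: ", family), class = "gaitfog_validation_error")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-grouped cross-validation of one model family
#'
#' Trains on the windows of the subjects outside each validation fold and
#' scores the fold's windows; asserts at window level that no subject ever
#' appears on both sides.
#'
#' @param windows Training-pool `fog_windows` (all subjects).
#' @param family `"cnn"`, `"inceptiontime"` or `"minirocket"`.
#' @param folds A [grouped_kfold()] assignment.
#' @param config Family config (defaults per family).
#' @param seed Integer seed; fold f trains with a seed derived from
#'   `(seed, family, f)`.
#' @return List of class `fog_cv`: `family`, `fold_metrics` tibble,
#'   `rocs`, `summary` ([mean_roc()]), `predictions` (pooled out-of-fold
#'   tibble).
#' @export
run_cv <- function(windows, family, folds, config = NULL, seed = 1L) {
  rocs <- list()
  preds <- list()
  for (f in seq_along(folds)) {
    val_subjects <- folds[[f]]
    in_val <- windows$info$subject_id %in% val_subjects
    train_w <- subset_windows(windows, !in_val)
    val_w <- subset_windows(windows, in_val)
    if (length(intersect(unique(train_w$info$subject_id),
                         unique(val_w$info$subject_id))) > 0) {
      abort("subject leakage across a CV fold", class = "gaitfog_leakage_error")
    }
    model <- train_model_family(train_w, family, config,
                                derive_seed(seed, family, "fold", f))
    p <- predict_proba(model, val_w)
    both <- length(unique(p$label)) == 2
    if (!both) {
      # a small validation fold can lack positives entirely; it contributes
      # predictions but no ROC
      warning(sprintf("fold %d has a single-class validation set; no ROC", f),
              call. = FALSE)
    }
    rocs[f] <- if (both) list(roc_auc(p$label, p$prob)) else list(NULL)
    preds[[f]] <- dplyr::mutate(p, fold = f)
  }
  pred <- dplyr::bind_rows(preds)
  valid <- !vapply(rocs, is.null, logical(1))
  if (sum(valid) < 2) {
    abort("fewer than two folds have both classes; cannot summarize CV",
          class = "gaitfog_validation_error")
  }
  structure(list(
    family = family,
    fold_metrics = tibble(
      fold = seq_along(folds),
      n_val = vapply(preds, nrow, integer(1)),
      auc = vapply(rocs, function(r) if (is.null(r)) NA_real_ else r$auc,
                   numeric(1))
    ),
    rocs = rocs[valid],
    summary = mean_roc(rocs[valid]),
    predictions = pred
  ), class = "fog_cv")
}

#' @export
print.fog_cv <- function(x, ...) {
  cat(sprintf("<fog_cv: %s> mean AUC = %.3f (SD %.3f) over %d of %d folds\n",
              x$family, x$summary$mean_auc, x$summary$sd_auc,
              length(x$rocs), nrow(x$fold_metrics)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fog_cv <- function(x, ...) x$fold_metrics

#' @exportS3Method generics::glance
glance.fog_cv <- function(x, ...) {
  tibble(family = x$family, mean_auc = x$summary$mean_auc,
         sd_auc = x$summary$sd_auc, n_folds = nrow(x$fold_metrics))
}

#' Sensor-configuration ablation
#'
#' Repeats cross-validation of one family over named sensor configurations,
#' reusing the identical fold assignment for a paired comparison.
#'
#' @param windows `fog_windows` built from all seven sensors.
#' @param family Model family.
#' @param folds A [grouped_kfold()] assignment (shared across
#'   configurations).
#' @param configs Character vector of configuration names, see
#'   [sensor_configs()].
#' @param config Family config.
#' @param seed Integer seed (shared across configurations).
#' @return List of class `fog_ablation`: `table` (tibble `sensor_config`,
#'   `n_sensors`, `n_channels`, `mean_auc`, `sd_auc`) and `cv` (per-config
#'   `fog_cv` objects).
#' @export
run_sensor_ablation <- function(windows, family, folds,
                                configs = names(sensor_configs()),
                                config = NULL, seed = 1L) {
  cvs <- list()
  rows <- list()
  for (cf in configs) {
    sub <- select_sensors(windows, cf)
    cv <- run_cv(sub, family, folds, config, seed)
    cvs[[cf]] <- cv
    rows[[cf]] <- tibble(
      sensor_config = cf,
      n_sensors = length(sensor_configs()[[cf]]),
      n_channels = length(sub$channels),
      mean_auc = cv$summary$mean_auc,
      sd_auc = cv$summary$sd_auc
    )
  }
  structure(list(table = dplyr::bind_rows(rows), cv = cvs, family = family),
            class = "fog_ablation")
}

#' @export
print.fog_ablation <- function(x, ...) {
  cat(sprintf("<fog_ablation: %s>\n", x$family))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fog_ablation <- function(x, ...) x$table
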