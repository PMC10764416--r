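# ggplot2 displays for ROC results, CV summaries and the sensor ablation.

#' @exportS3Method ggplot2::autoplot
autoplot.fog_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fog_mean_roc <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$fpr, y = .data$mean_tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_tpr - .data$sd_tpr),
      ymax = pmin(1, .data$mean_tpr + .data$sd_tpr)), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean ROC over %d folds (AUC = %.3f ± %.3f)",
                      length(object$fold_auc), object$mean_auc, object$sd_auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fog_cv <- function(object, ...) {
  p <- autoplot(object$summary)
  p + ggplot2::labs(subtitle = paste("family:", object$family))
}

#' @exportS3Method ggplot2::autoplot
autoplot.fog_ablation <- function(object, ...) {
  tab <- dplyr::arrange(object$table, .data$mean_auc)
  tab$sensor_config <- factor(tab$sensor_config, levels = tab$sensor_config)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_auc, y = .data$sensor_config)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$mean_auc - .data$sd_auc,
      xmax = .data$mean_auc + .data$sd_auc)) +
    ggplot2::labs(x = "Mean AUC (± SD over folds)", y = NULL,
                  title = paste("Sensor ablation:", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot a recording excerpt with FOG episodes shaded
#'
#' @param recording An `imu_recording` or `clean_recording`.
#' @param annotations Matching `fog_annotations` (optional).
#' @param channels Channel names to draw (default: first three).
#' @param t_max Truncate the display after this many seconds.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, annotations = NULL, channels = NULL,
                           t_max = Inf) {
  m <- recording$accel
  channels <- channels %||% head(colnames(m), 3)
  fs <- recording$sample_rate_hz
  df <- tibble(
    time_s = rep((seq_len(nrow(m)) - 1) / fs, length(channels)),
    channel = rep(channels, each = nrow(m)),
    value = as.vector(m[, channels])
  )
  df <- df[df$time_s <= t_max, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- annotations[annotations$start_s <= t_max, , drop = FALSE]
    if (nrow(ann) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tibble(xmin = ann$start_s, xmax = pmin(ann$end_s, t_max)),
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "firebrick", alpha = 0.15)
    }
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Acceleration (m/s²)") +
    ggplot2::theme_minimal()
}
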