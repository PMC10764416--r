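# Spectral band-power baseline: the classical freeze-index style score.
# Trembling FOG concentrates power in the 3-8 Hz freeze band while normal
# gait concentrates it in the 0.5-3 Hz locomotor band, so the log ratio of
# the two band powers separates the classes without any learning. The
# pipeline uses it as a floor for what the trained models must beat, and as
# the guarantee that the synthetic task is learnable at all.

#' Band power of a window tensor
#'
#' Mean periodogram power per window in a frequency band, summed over
#' channels.
#'
#' @param windows A `fog_windows` dataset.
#' @param band Numeric length-2 vector `(low, high)` in Hz (inclusive).
#' @return Numeric vector, one power per window.
#' @export
band_power <- function(windows, band) {
  x <- windows$x
  T_len <- dim(x)[1]
  fs <- windows$sample_rate_hz
  freqs <- (0:(T_len - 1)) * fs / T_len
  sel <- freqs >= band[1] & freqs <= band[2]
  n <- dim(x)[3]
  out <- numeric(n)
  for (i in seq_len(n)) {
    sp <- Mod(stats::mvfft(x[, , i, drop = TRUE]))^2 / T_len
    if (is.null(dim(sp))) sp <- matrix(sp, ncol = 1)
    out[i] <- sum(sp[sel, ])
  }
  out
}

#' Freeze-band / locomotor-band score
#'
#' Log ratio of 3-8 Hz to 0.5-3 Hz band power, squashed to `[0, 1]` by a
#' logistic so it is comparable with model probabilities.
#'
#' @param windows A `fog_windows` dataset.
#' @return Tibble: the window `info` columns plus `prob`.
#' @export
bandpower_score <- function(windows) {
  w <- drop_discard(windows)
  freeze <- band_power(w, c(3, 8))
  loco <- band_power(w, c(0.5, 3))
  score <- log((freeze + 1e-12) / (loco + 1e-12))
  dplyr::mutate(w$info, prob = 1 / (1 + exp(-score)))
}
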