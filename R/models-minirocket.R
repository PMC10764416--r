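# MiniRocket: a fixed bank of 84 two-valued convolution kernels of length 9
# (weights -1 with three taps of +2, one kernel per choice of the three high
# taps), dilated over an exponential schedule capped at 32 dilations per
# kernel, pooled by the proportion of positive values (PPV) against bias
# quantiles fitted on training-data convolutions. A logistic head trained by
# minibatch gradient descent turns the ~10,000 features into a probability.

MR_KERNEL_LENGTH <- 9L
MR_N_KERNELS <- 84L  # choose(9, 3) two-valued kernels

#' MiniRocket configuration
#'
#' Defaults: all 84 two-valued kernels of length 9, at most 32 dilations per
#' kernel, a feature budget of 10,000 (rounded down to a multiple of 84,
#' i.e. 9,996 features), and a logistic head trained for 10 epochs at
#' learning rate 0.001 with balanced class weights.
#'
#' @param max_dilations_per_kernel Cap on the dilation schedule.
#' @param feature_budget Target feature count; the realized count is
#'   `84 * floor(feature_budget / 84)`.
#' @param head_epochs,head_learning_rate,head_batch_size Logistic-head
#'   optimizer settings.
#' @param bias_sample_size Training windows subsampled for bias-quantile
#'   fitting (all windows when fewer).
#' @return A list of class `minirocket_config`.
#' @export
minirocket_config <- function(max_dilations_per_kernel = 32L,
                              feature_budget = 10000L,
                              head_epochs = 10L,
                              head_learning_rate = 0.001,
                              head_batch_size = 256L,
                              bias_sample_size = 8192L) {
  structure(list(kernel_length = MR_KERNEL_LENGTH,
                 n_kernels = MR_N_KERNELS,
                 max_dilations_per_kernel = as.integer(max_dilations_per_kernel),
                 feature_budget = as.integer(feature_budget),
                 head_epochs = as.integer(head_epochs),
                 head_learning_rate = head_learning_rate,
                 head_batch_size = as.integer(head_batch_size),
                 bias_sample_size = as.integer(bias_sample_size)),
            class = "minirocket_config")
}

# All 84 kernels: 0-based positions of the three +2 taps among 9.
mr_kernel_positions <- function() {
  t(utils::combn(MR_KERNEL_LENGTH, 3)) - 1L
}

# Exponential dilation schedule for input length `input_length`, with the
# per-kernel feature budget spread over dilations proportionally to how
# often each dilation appears in the exponential grid.
mr_dilation_schedule <- function(input_length, config) {
  nfpk <- config$feature_budget %/% config$n_kernels
  true_max <- min(nfpk, config$max_dilations_per_kernel)
  multiplier <- nfpk / true_max
  max_exponent <- log2((input_length - 1) / (MR_KERNEL_LENGTH - 1))
  grid <- floor(2^seq(0, max_exponent, length.out = true_max))
  tab <- table(grid)
  dilations <- as.integer(names(tab))
  n_feat <- as.integer(floor(as.integer(tab) * multiplier))
  remainder <- nfpk - sum(n_feat)
  i <- 1
  while (remainder > 0) {
    n_feat[i] <- n_feat[i] + 1L
    remainder <- remainder - 1L
    i <- i %% length(n_feat) + 1
  }
  list(dilations = dilations, n_feat_per_dilation = n_feat,
       n_features_per_kernel = nfpk)
}

#' Fit the MiniRocket transform
#'
#' Fixes the dilation schedule from the window length, draws one random
#' channel subset per kernel-dilation pair (multichannel handling), and fits
#' the PPV bias quantiles from convolutions on a seeded subsample of
#' training windows. Quantile levels follow a low-discrepancy (golden
#' ratio) sequence, so biases tile the convolution output distribution.
#'
#' @param windows Training `fog_windows`.
#' @param config A [minirocket_config()].
#' @param seed Integer seed (channel subsets, bias sampling).
#' @return A `minirocket_transformer` with `n_features` total features.
#' @export
minirocket_fit <- function(windows, config = minirocket_config(), seed = 1L) {
  inp <- model_inputs(windows)
  T_len <- dim(inp$x)[1]
  C <- dim(inp$x)[2]
  sched <- mr_dilation_schedule(T_len, config)
  n_dil <- length(sched$dilations)
  positions <- mr_kernel_positions()
  total <- config$n_kernels * sum(sched$n_feat_per_dilation)

  with_seed(derive_seed(seed, "minirocket_fit"), {
    # one channel combination per (dilation, kernel); sizes follow a
    # log-uniform law so small subsets dominate but larger mixes occur
    limit <- min(C, 9)
    n_combo <- n_dil * config$n_kernels
    combo_sizes <- pmin(limit, floor(2^runif(n_combo, 0, log2(limit + 1))))
    combos <- lapply(combo_sizes, function(k) sort(sample.int(C, k)) - 1L)

    n_windows <- dim(inp$x)[3]
    sub <- if (n_windows <= config$bias_sample_size) seq_len(n_windows)
           else sort(sample.int(n_windows, config$bias_sample_size))
    # one designated subsample window per bias slot
    window_choice <- sub[1 + floor(runif(total) * length(sub))] - 1L
    phi <- (sqrt(5) + 1) / 2
    quantiles <- (seq_len(total) * phi) %% 1

    biases <- cpp_mr_fit_biases(inp$x, positions, sched$dilations,
                                sched$n_feat_per_dilation, combos,
                                seq_len(n_combo) - 1L, window_choice, quantiles)
    structure(list(
      positions = positions,
      dilations = sched$dilations,
      n_feat_per_dilation = sched$n_feat_per_dilation,
      combos = combos,
      biases = as.numeric(biases),
      n_features = total,
      channels = windows$channels,
      input_length = T_len,
      config = config
    ), class = "minirocket_transformer")
  })
}

#' Apply the MiniRocket transform
#'
#' @param transformer A fitted `minirocket_transformer`.
#' @param windows A `fog_windows` dataset on the transformer's channel
#'   layout.
#' @return Numeric feature matrix, one row per (non-DISCARD) window, every
#'   value a PPV in `[0, 1]`.
#' @export
minirocket_transform <- function(transformer, windows) {
  if (!inherits(transformer, "minirocket_transformer")) {
    abort("transform applied before fitting: pass a minirocket_transformer",
          class = "gaitfog_state_error")
  }
  inp <- model_inputs(windows, channels = transformer$channels)
  n_combo <- length(transformer$combos)
  cpp_mr_transform(inp$x, transformer$positions, transformer$dilations,
                   transformer$n_feat_per_dilation, transformer$combos,
                   seq_len(n_combo) - 1L, transformer$biases)
}

# Column means/population-SDs without duplicating the feature matrix.
feature_moments <- function(features) {
  mu <- colMeans(features)
  sdv <- sqrt(pmax(0, colMeans(features^2) - mu^2))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

# Minibatch-Adam logistic regression; `Xs` must already be standardized.
train_logistic_head <- function(Xs, y, sample_w, epochs, lr,
                                batch_size, seed) {
  n <- nrow(Xs); F_dim <- ncol(Xs)
  w <- numeric(F_dim); b <- 0
  mw <- numeric(F_dim); vw <- numeric(F_dim); mb <- 0; vb <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  with_seed(derive_seed(seed, "logistic_head"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (lo in seq(1, n, by = batch_size)) {
        hi <- min(n, lo + batch_size - 1)
        idx <- ord[lo:hi]
        Xb <- Xs[idx, , drop = FALSE]
        z <- drop(Xb %*% w) + b
        p <- 1 / (1 + exp(-z))
        dz <- sample_w[idx] * (p - y[idx]) / length(idx)
        gw <- drop(crossprod(Xb, dz))
        gb <- sum(dz)
        t <- t + 1
        mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
        mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
        c1 <- 1 - b1^t; c2 <- 1 - b2^t
        w <- w - lr * (mw / c1) / (sqrt(vw / c2) + eps)
        b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
      }
    }
  })
  list(w = w, b = b)
}

#' Train MiniRocket (transform + logistic head)
#'
#' @param windows Training `fog_windows`.
#' @param config A [minirocket_config()].
#' @param seed Integer seed.
#' @return A fitted `fog_model`; `n_parameters()` counts the logistic
#'   coefficients (one per transform feature) plus intercept.
#' @export
train_minirocket <- function(windows, config = minirocket_config(), seed = 1L) {
  inp <- model_inputs(windows, training = TRUE)
  transformer <- minirocket_fit(windows, config, seed)
  features <- minirocket_transform(transformer, windows)
  cw <- compute_class_weights(inp$y)
  sample_w <- ifelse(inp$y, cw["POS"], cw["NEG"])
  mom <- feature_moments(features)
  cpp_standardize_inplace(features, mom$mu, mom$sd)  # we own the only copy
  head <- train_logistic_head(features, as.numeric(inp$y), sample_w,
                              config$head_epochs, config$head_learning_rate,
                              config$head_batch_size, seed)
  head$mu <- mom$mu
  head$sd <- mom$sd
  new_fog_model("minirocket", list(transformer = transformer, head = head),
                config, windows$channels, as.integer(seed), length(inp$y))
}

#' @export
predict_proba.fog_minirocket <- function(model, windows, ...) {
  inp <- model_inputs(windows, channels = model$channels)
  features <- minirocket_transform(model$state$transformer, windows)
  head <- model$state$head
  cpp_standardize_inplace(features, head$mu, head$sd)
  p <- 1 / (1 + exp(-(drop(features %*% head$w) + head$b)))
  dplyr::mutate(inp$info, prob = as.numeric(p))
}

#' @export
n_parameters.fog_minirocket <- function(model) {
  length(model$state$head$w) + 1L
}

#' @exportS3Method generics::tidy
tidy.fog_minirocket <- function(x, ...) {
  tibble(term = c("(Intercept)", paste0("ppv_", seq_along(x$state$head$w))),
         estimate = c(x$state$head$b, x$state$head$w))
}
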