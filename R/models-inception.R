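# InceptionTime: an ensemble of inception networks. Each network stacks six
# inception modules (1x1 bottleneck, three parallel convolutions with
# reduced kernel sizes 2/4/8, and a max-pool + 1x1 branch, concatenated and
# batch-normalized) with a residual shortcut every three modules, followed
# by global average pooling and a sigmoid unit. The ensemble probability is
# the arithmetic mean of the member sigmoids.

#' InceptionTime configuration
#'
#' Defaults: an ensemble of five independently initialized networks of depth
#' six with kernel sizes (2, 4, 8) — reduced from the reference (10, 20, 40)
#' to limit parameters on 2-s windows — trained for 20 epochs at learning
#' rate 0.001 with balanced class weights and no weight decay. Bottleneck
#' and per-branch filter widths default to 32, the reference architecture's
#' values.
#'
#' @param n_ensemble Number of ensemble members (>= 1).
#' @param kernel_sizes Integer vector of 3 branch kernel sizes.
#' @param depth Number of inception modules; residual shortcuts join every
#'   third module.
#' @param bottleneck Bottleneck width (1x1 conv output channels).
#' @param n_filters Filters per convolution branch.
#' @param epochs,learning_rate,batch_size,weight_decay Optimizer settings.
#' @return A list of class `inception_config`.
#' @export
inception_config <- function(n_ensemble = 5L,
                             kernel_sizes = c(2L, 4L, 8L),
                             depth = 6L,
                             bottleneck = 32L,
                             n_filters = 32L,
                             epochs = 20L,
                             learning_rate = 0.001,
                             batch_size = 32L,
                             weight_decay = 0) {
  if (n_ensemble < 1) abort("need n_ensemble >= 1", class = "gaitfog_validation_error")
  stopifnot(length(kernel_sizes) == 3, depth >= 3)
  structure(list(n_ensemble = as.integer(n_ensemble),
                 kernel_sizes = as.integer(kernel_sizes),
                 depth = as.integer(depth),
                 bottleneck = as.integer(bottleneck),
                 n_filters = as.integer(n_filters),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay),
            class = "inception_config")
}

#' Train an InceptionTime ensemble
#'
#' @param windows Training `fog_windows`.
#' @param config An [inception_config()].
#' @param seed Integer seed; member m trains with a seed derived from
#'   `(seed, m)`.
#' @return A fitted `fog_model` whose state holds all ensemble members.
#' @export
train_inceptiontime <- function(windows, config = inception_config(), seed = 1L) {
  inp <- model_inputs(windows, training = TRUE)
  cw <- compute_class_weights(inp$y)
  sample_w <- ifelse(inp$y, cw["POS"], cw["NEG"])
  members <- vector("list", config$n_ensemble)
  for (m in seq_len(config$n_ensemble)) {
    members[[m]] <- cpp_inception_train(
      inp$x, as.numeric(inp$y), sample_w, config$depth, config$bottleneck,
      config$n_filters, config$kernel_sizes, config$epochs,
      config$learning_rate, config$batch_size, config$weight_decay,
      derive_seed(seed, "inception_member", m))
  }
  new_fog_model("inceptiontime", list(members = members), config,
                windows$channels, as.integer(seed), length(inp$y))
}

# Per-member probabilities, one column per ensemble member.
inception_member_probs <- function(model, windows, batch_size = 256L) {
  inp <- model_inputs(windows, channels = model$channels)
  cfg <- model$config
  vapply(model$state$members, function(st) {
    as.numeric(cpp_inception_predict(st, inp$x, cfg$depth, cfg$bottleneck,
                                     cfg$n_filters, cfg$kernel_sizes,
                                     as.integer(batch_size)))
  }, numeric(dim(inp$x)[3]))
}

#' @export
predict_proba.fog_inceptiontime <- function(model, windows, batch_size = 256L, ...) {
  inp <- model_inputs(windows, channels = model$channels)
  probs <- inception_member_probs(model, windows, batch_size)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  dplyr::mutate(inp$info, prob = rowMeans(probs))
}

#' @export
n_parameters.fog_inceptiontime <- function(model) {
  strip <- function(member) {
    member$modules <- lapply(member$modules, function(m) {
      m$run_mean <- NULL; m$run_var <- NULL; m
    })
    member$bns1$run_mean <- NULL; member$bns1$run_var <- NULL
    member$bns2$run_mean <- NULL; member$bns2$run_var <- NULL
    member
  }
  sum(vapply(model$state$members, function(m) count_params(strip(m)), numeric(1)))
}
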