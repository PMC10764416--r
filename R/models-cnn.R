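# Compact convolutional network: three conv/pool/dropout modules, a 10-unit
# dense layer and a sigmoid output, trained with AdamW and class-weighted
# binary cross-entropy.

#' CNN configuration
#'
#' Defaults follow the reference training protocol: kernel sizes (7, 3, 3),
#' max-pooling of size 2 and dropout 0.2 after each convolution, a 10-unit
#' ReLU dense layer, a single sigmoid output, 30 epochs of AdamW at learning
#' rate 0.001, batch size 32, weight decay 0.001, balanced class weights and
#' no early stopping. Convolutions use "same" padding so the three pool-by-2
#' stages map 120 time steps to 15 regardless of kernel size. Filter counts
#' per block are not pinned by the protocol; (16, 16, 16) is the package
#' default.
#'
#' @param kernel_sizes Integer vector of 3 kernel sizes.
#' @param n_filters Integer vector of 3 filter counts.
#' @param dense_units Units in the penultimate dense layer.
#' @param dropout Dropout rate used after each pool and after flattening.
#' @param epochs,learning_rate,batch_size,weight_decay Optimizer settings.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(kernel_sizes = c(7L, 3L, 3L),
                       n_filters = c(16L, 16L, 16L),
                       dense_units = 10L,
                       dropout = 0.2,
                       epochs = 30L,
                       learning_rate = 0.001,
                       batch_size = 32L,
                       weight_decay = 0.001) {
  stopifnot(length(kernel_sizes) == 3, length(n_filters) == 3)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay),
            class = "cnn_config")
}

#' Train the CNN
#'
#' @param windows Training `fog_windows` (DISCARD windows are removed; both
#'   classes must be present).
#' @param config A [cnn_config()].
#' @param seed Integer seed; training is deterministic given
#'   (data, config, seed).
#' @return A fitted `fog_model`.
#' @export
train_cnn <- function(windows, config = cnn_config(), seed = 1L) {
  inp <- model_inputs(windows, training = TRUE)
  cw <- compute_class_weights(inp$y)
  sample_w <- ifelse(inp$y, cw["POS"], cw["NEG"])
  state <- cpp_cnn_train(inp$x, as.numeric(inp$y), sample_w,
                         config$kernel_sizes, config$n_filters,
                         config$dense_units, config$dropout, config$epochs,
                         config$learning_rate, config$batch_size,
                         config$weight_decay, as.integer(seed))
  new_fog_model("cnn", state, config, windows$channels, as.integer(seed),
                length(inp$y))
}

#' @export
predict_proba.fog_cnn <- function(model, windows, batch_size = 256L, ...) {
  inp <- model_inputs(windows, channels = model$channels)
  p <- cpp_cnn_predict(model$state, inp$x, model$config$kernel_sizes,
                       as.integer(batch_size))
  dplyr::mutate(inp$info, prob = as.numeric(p))
}

#' @export
n_parameters.fog_cnn <- function(model) count_params(model$state)
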