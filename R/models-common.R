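# Common classifier interface: every family trains on a `fog_windows`
# dataset and exposes a per-window FOG probability through predict_proba().

#' Balanced class weights
#'
#' Weight of class c is `N / (2 * N_c)`, so the weighted counts of the two
#' classes are equal.
#'
#' @param labels Character (`"POS"`/`"NEG"`) or logical/0-1 vector.
#' @return Named numeric vector `c(NEG = w_neg, POS = w_pos)`.
#' @export
#' @examples
#' compute_class_weights(rep(c("NEG", "POS"), c(90, 10)))
compute_class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to balance weights",
          class = "gaitfog_validation_error")
  }
  n <- n_pos + n_neg
  c(NEG = n / (2 * n_neg), POS = n / (2 * n_pos))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  if (any(labels == "DISCARD")) {
    abort("DISCARD windows must be removed before training/scoring",
          class = "gaitfog_validation_error")
  }
  labels == "POS"
}

new_fog_model <- function(family, state, config, channels, seed, n_train) {
  structure(list(family = family, state = state, config = config,
                 channels = channels, seed = seed, n_train = n_train),
            class = c(paste0("fog_", family), "fog_model"))
}

# Validate that a dataset matches the channels a model was trained on and
# return the tensor + labels ready for the C++ core.
model_inputs <- function(windows, channels = NULL, training = FALSE) {
  if (!inherits(windows, "fog_windows")) {
    abort("`windows` must be a fog_windows dataset", class = "gaitfog_validation_error")
  }
  if (!is.null(channels) && !identical(windows$channels, channels)) {
    abort(paste0("channel layout mismatch: model was trained on [",
                 paste(channels, collapse = ", "), "]"),
          class = "gaitfog_validation_error")
  }
  w <- drop_discard(windows)
  if (training && dim(w$x)[3] < dim(windows$x)[3]) {
    # silently dropping ambiguous windows is the documented training rule
  }
  y <- as_binary_labels(w$info$label)
  if (training && (sum(y) == 0 || sum(!y) == 0)) {
    abort("training data must contain both classes", class = "gaitfog_validation_error")
  }
  list(x = w$x, y = y, info = w$info)
}

#' Per-window FOG probability
#'
#' Family-agnostic probability interface; the evaluation machinery only ever
#' talks to models through this generic. Output order matches window order
#' and is invariant to batching.
#'
#' @param model A fitted `fog_model`.
#' @param windows A `fog_windows` dataset with the channel layout the model
#'   was trained on. `DISCARD` windows are dropped before scoring.
#' @param ... Passed to methods.
#' @return Tibble: the window `info` columns plus a `prob` column in `[0,1]`.
#' @export
predict_proba <- function(model, windows, ...) {
  UseMethod("predict_proba")
}

#' @export
print.fog_model <- function(x, ...) {
  cat(sprintf("<fog_model: %s> trained on %d windows x %d channels (seed %d)\n",
              x$family, x$n_train, length(x$channels), x$seed))
  invisible(x)
}

#' @rdname glance.fog_model
#' @exportS3Method generics::glance
glance.fog_model <- function(x, ...) {
  tibble(family = x$family, n_train = x$n_train,
         n_channels = length(x$channels),
         n_parameters = n_parameters(x), seed = x$seed)
}

#' Model summaries
#'
#' `glance()` returns a one-row tibble describing a fitted model (family,
#' training size, channel and parameter counts).
#'
#' @param x A `fog_model`.
#' @param ... Unused.
#' @name glance.fog_model
NULL

#' Number of trainable parameters
#'
#' @param model A fitted `fog_model`.
#' @return Integer count of trainable parameters (for the MiniRocket family,
#'   the logistic head's coefficients plus intercept are the trainable part;
#'   `n_features` of the transform equals the coefficient count).
#' @export
n_parameters <- function(model) {
  UseMethod("n_parameters")
}

count_params <- function(lst) {
  if (is.list(lst)) return(sum(vapply(lst, count_params, numeric(1))))
  if (is.numeric(lst)) return(length(lst))
  0
}
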