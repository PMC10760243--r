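#' Configuration of the multi-channel 3D CNN
#'
#' Describes an AlexNet-lineage 3D convolutional classifier: repeated
#' `[conv3d -> batch norm -> ReLU -> (max pool)]` blocks, global adaptive
#' average pooling, then two fully connected layers with ReLU and dropout and
#' a final linear layer emitting one logit per class.  The searched
#' convolution settings are kernel-stride-padding 5-2-0 and 3-2-1; filter
#' counts default to the AlexNet-3D lineage.  Adaptive pooling makes the
#' network accept any grid large enough for the conv/pool stack without
#' reconfiguration.
#'
#' @param n_channels input channels (1-3: unimodal, two-channel, or fused).
#' @param n_classes number of diagnostic classes (2 or 3).
#' @param conv_filters integer vector of filters per conv block.
#' @param kernel_size,stride,padding shared conv settings.
#' @param pool_after indices of conv blocks followed by max pooling.
#' @param pool_kernel,pool_stride,pool_padding max-pool settings.
#' @param dropout_rate dropout probability in the FC head, in `[0, 1)`.
#' @param fc_widths integer pair of hidden fully connected widths.
#' @return An object of class `nf_cnn_config`.
#' @export
cnn_config <- function(n_channels, n_classes,
                       conv_filters = c(64L, 128L, 192L, 192L, 128L),
                       kernel_size = 3L, stride = 2L, padding = 1L,
                       pool_after = c(1L, 2L, 5L),
                       pool_kernel = 3L, pool_stride = 2L, pool_padding = 1L,
                       dropout_rate = 0.5, fc_widths = c(128L, 64L)) {
  n_channels <- as.integer(n_channels)
  n_classes <- as.integer(n_classes)
  stopifnot(n_channels >= 1L, n_channels <= 3L, n_classes >= 2L,
            length(conv_filters) >= 1L, all(conv_filters >= 1L),
            kernel_size >= 1L, stride >= 1L, padding >= 0L,
            dropout_rate >= 0, dropout_rate < 1,
            length(fc_widths) == 2L, all(fc_widths >= 1L))
  pool_after <- intersect(as.integer(pool_after),
                          seq_along(conv_filters))
  structure(list(n_channels = n_channels, n_classes = n_classes,
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), padding = as.integer(padding),
                 pool_after = pool_after,
                 pool_kernel = as.integer(pool_kernel),
                 pool_stride = as.integer(pool_stride),
                 pool_padding = as.integer(pool_padding),
                 dropout_rate = dropout_rate,
                 fc_widths = as.integer(fc_widths)),
            class = "nf_cnn_config")
}

#' @export
print.nf_cnn_config <- function(x, ...) {
  cat(sprintf(
    "<nf_cnn_config> %d channel(s) -> %d class(es)\n  conv %s (k%d/s%d/p%d), pool after %s, fc %s, dropout %.2f\n",
    x$n_channels, x$n_classes,
    paste(x$conv_filters, collapse = "-"),
    x$kernel_size, x$stride, x$padding,
    paste(x$pool_after, collapse = ","),
    paste(x$fc_widths, collapse = "-"), x$dropout_rate))
  invisible(x)
}

#' Build a multi-channel 3D CNN classifier
#'
#' Instantiates the layer stack described by a [cnn_config()] with
#' Kaiming-style (He) normal weight initialization and zero biases, seeded
#' for reproducibility.  Spatial geometry is resolved at the first forward
#' pass, so one model handles any sufficiently large grid.
#'
#' @param config an [cnn_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `nf_cnn` with elements `config`, `layers`,
#'   `seed`, and `n_parameters`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "nf_cnn_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  layers <- list()
  in_ch <- config$n_channels
  for (i in seq_along(config$conv_filters)) {
    f <- config$conv_filters[i]
    layers <- c(layers, list(
      layer_conv3d(in_ch, f, config$kernel_size, config$stride,
                   config$padding),
      layer_batchnorm(f),
      layer_relu()))
    if (i %in% config$pool_after)
      layers <- c(layers, list(layer_maxpool3d(config$pool_kernel,
                                               config$pool_stride,
                                               config$pool_padding)))
    in_ch <- f
  }
  layers <- c(layers, list(layer_avgpool_global()))
  in_f <- in_ch
  for (w in config$fc_widths) {
    layers <- c(layers, list(layer_linear(in_f, w), layer_relu(),
                             layer_dropout(config$dropout_rate)))
    in_f <- w
  }
  layers <- c(layers, list(layer_linear(in_f, config$n_classes)))
  structure(list(config = config, layers = layers, seed = seed,
                 n_parameters = n_parameters(layers)),
            class = "nf_cnn")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Forward pass of a CNN classifier
#'
#' Computes logits for a batch of model inputs.  In eval mode
#' (`training = FALSE`, the default) the pass is deterministic: dropout is
#' disabled and batch normalization uses its running statistics.
#'
#' @param model an `nf_cnn` (or trained `nf_cnn_fit`).
#' @param inputs list of `nf_model_input` objects on a common grid.
#' @param training logical; enables dropout and batch-statistic
#'   normalization.
#' @return A `length(inputs) x n_classes` matrix of logits.
#' @export
forward <- function(model, inputs, training = FALSE) {
  model <- as_nf_cnn(model)
  rep <- batch_to_rep(inputs, model$config$n_channels)
  net_forward(model$layers, rep, training = training)$out
}

as_nf_cnn <- function(model) {
  if (inherits(model, "nf_cnn_fit")) model$model
  else if (inherits(model, "nf_cnn")) model
  else stop("`model` must be an nf_cnn or nf_cnn_fit", call. = FALSE)
}

#' @export
print.nf_cnn <- function(x, ...) {
  cat(sprintf("<nf_cnn> %d-channel 3D CNN, %d classes, %s parameters\n",
              x$config$n_channels, x$config$n_classes,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

#' @export
summary.nf_cnn <- function(object, ...) {
  types <- vapply(object$layers, `[[`, "", "type")
  counts <- vapply(object$layers, function(l) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    sum(vapply(nm, function(p) length(l[[p]]), 0))
  }, 0)
  df <- data.frame(layer = seq_along(types), type = types,
                   parameters = counts)
  cat(sprintf("Multi-channel 3D CNN: %d layers, %s parameters\n",
              length(types), format(object$n_parameters, big.mark = ",")))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Class predictions and probabilities
#'
#' @param object an `nf_cnn` or `nf_cnn_fit`.
#' @param newdata list of `nf_model_input` objects.
#' @param type `"class"` (default), `"prob"` (softmax matrix) or `"logits"`.
#' @param ... unused.
#' @return predicted class labels, a probability matrix, or logits.
#' @export
predict.nf_cnn <- function(object, newdata,
                           type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  model <- as_nf_cnn(object)
  logits <- forward(model, newdata, training = FALSE)
  classes <- attr(model, "class_levels") %||%
    as.character(seq_len(model$config$n_classes))
  colnames(logits) <- classes
  switch(type,
         logits = logits,
         prob = {
           p <- softmax_rows(logits); colnames(p) <- classes; p
         },
         class = classes[max.col(logits, ties.method = "first")])
}

#' @export
predict.nf_cnn_fit <- function(object, newdata,
                               type = c("class", "prob", "logits"), ...) {
  predict.nf_cnn(object$model, newdata, type = type, ...)
}
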