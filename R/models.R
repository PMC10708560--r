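#' Specification of a temporal network
#'
#' Describes one of the four architecture families together with its task
#' head and input representation. Two named size presets are provided:
#' `"full"` carries the reference layer sizes (two 128-filter
#' convolutions with kernel 512 for the CNN, 128-unit Bi-LSTMs, TCN
#' dilations 1--32 with kernel 3) for 5001-sample records, while `"desk"`
#' shrinks widths and record length (10 Hz sampling, 500 samples) so that
#' full training runs complete in CPU-minutes; every size remains
#' individually overridable.
#'
#' @param family `"cnn1d"`, `"tcn"`, `"bilstm"` or `"crnn"`.
#' @param task `"regression"` (2 linear outputs: heart rate, respiration
#'   rate) or `"classification"` (3-class softmax over
#'   drowsiness/normal/stress).
#' @param scale `"full"` or `"desk"` size preset.
#' @param n_samples Input record length.
#' @param input_mode `"iq"` (2 channels: in-phase and quadrature,
#'   jointly normalized per record so the phasor geometry is kept) or
#'   `"phase"` (1 channel: unwrapped detrended baseband phase, z-scored).
#' @param filters,kernel,pool Convolution front-end sizes (CNN and CRNN).
#' @param lstm_units Hidden units per LSTM direction.
#' @param tcn_filters,tcn_dilations,tcn_kernel Residual-block sizes (TCN).
#' @param head Integer vector of hidden dense-layer widths.
#' @param dropout Dropout rate applied after each hidden dense layer and
#'   inside TCN residual blocks.
#' @param seed Seed for weight initialization; identical specs build
#'   identical networks.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("crnn", "regression", scale = "desk")
#' @export
model_spec <- function(family = c("cnn1d", "tcn", "bilstm", "crnn"),
                       task = c("regression", "classification"),
                       scale = c("full", "desk"),
                       n_samples = NULL, input_mode = c("iq", "phase"),
                       filters = NULL, kernel = NULL, pool = 4L,
                       lstm_units = NULL, tcn_filters = NULL,
                       tcn_dilations = c(1L, 2L, 4L, 8L, 16L, 32L),
                       tcn_kernel = 3L, head = NULL, dropout = NULL,
                       seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  scale <- match.arg(scale)
  input_mode <- match.arg(input_mode)
  dflt <- if (scale == "full") {
    list(n_samples = 5001L, filters = 128L, kernel = 512L, lstm_units = 128L,
         tcn_filters = 128L, head = c(64L, 32L), dropout = 0.3)
  } else {
    list(n_samples = 500L, filters = 48L, kernel = 64L, lstm_units = 32L,
         tcn_filters = 32L, head = c(32L, 16L), dropout = 0.15)
  }
  spec <- list(family = family, task = task, scale = scale,
               n_samples = as.integer(n_samples %||% dflt$n_samples),
               channels = if (input_mode == "iq") 2L else 1L,
               input_mode = input_mode,
               filters = as.integer(filters %||% dflt$filters),
               kernel = as.integer(kernel %||% dflt$kernel),
               pool = as.integer(pool),
               lstm_units = as.integer(lstm_units %||% dflt$lstm_units),
               tcn_filters = as.integer(tcn_filters %||% dflt$tcn_filters),
               tcn_dilations = as.integer(tcn_dilations),
               tcn_kernel = as.integer(tcn_kernel),
               head = as.integer(head %||% dflt$head),
               dropout = dropout %||% dflt$dropout,
               out_dim = if (task == "regression") 2L else 3L,
               seed = as.integer(seed))
  if (spec$n_samples < spec$kernel)
    stop("input shorter than the convolution kernel")
  structure(spec, class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

head_layers <- function(spec, in_dim) {
  layers <- list()
  for (w in spec$head) {
    layers <- c(layers, list(nn_dense(in_dim, w), nn_relu(),
                             nn_dropout(spec$dropout)))
    in_dim <- w
  }
  layers <- c(layers, list(nn_dense(in_dim, spec$out_dim)))
  if (spec$task == "classification") layers <- c(layers, list(nn_softmax()))
  layers
}

conv_out_len <- function(t_in, kernel, pool) (t_in - kernel + 1) %/% pool

#' Build a temporal network from its specification
#'
#' Dispatches to the family-specific constructor. All four families share
#' the same input contract (a record as a `(time, channels)` sequence) and
#' task heads (dense layers with dropout, then 2 linear outputs for
#' regression or a 3-class softmax for classification).
#'
#' * `cnn1d`: two valid convolutions (ReLU, max-pool after each), flatten,
#'   dense head. The flattened feature map makes this by far the largest
#'   family in parameters.
#' * `tcn`: a stack of residual blocks of dilated causal convolutions
#'   (kernel 3, dilations 1,2,4,...,32; each block is conv-BN-ReLU-dropout
#'   twice plus a skip path), then global average pooling over time.
#' * `bilstm`: two bidirectional LSTM layers with a batch-normalization
#'   layer between them, global average pooling over time.
#' * `crnn`: one convolution, max-pool and batch norm, a bidirectional
#'   LSTM, global average pooling — the smallest family.
#'
#' @param spec A [model_spec()].
#' @return An object of class `vr_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(spec$seed)
  net <- switch(spec$family,
                cnn1d = build_cnn1d_net(spec),
                tcn = build_tcn_net(spec),
                bilstm = build_bilstm_net(spec),
                crnn = build_crnn_net(spec))
  structure(list(spec = spec, net = net), class = "vr_model")
}

#' @rdname build_model
#' @export
build_cnn1d <- function(spec) {
  stopifnot(spec$family == "cnn1d")
  build_model(spec)
}

#' @rdname build_model
#' @export
build_tcn <- function(spec) {
  stopifnot(spec$family == "tcn")
  build_model(spec)
}

#' @rdname build_model
#' @export
build_bilstm <- function(spec) {
  stopifnot(spec$family == "bilstm")
  build_model(spec)
}

#' @rdname build_model
#' @export
build_crnn <- function(spec) {
  stopifnot(spec$family == "crnn")
  build_model(spec)
}

build_cnn1d_net <- function(spec) {
  t1 <- conv_out_len(spec$n_samples, spec$kernel, spec$pool)
  if (t1 < spec$kernel)
    stop("input too short for the second convolution after pooling")
  t2 <- conv_out_len(t1, spec$kernel, spec$pool)
  do.call(nn_seq, c(
    list(nn_conv1d(spec$channels, spec$filters, spec$kernel), nn_relu(),
         nn_maxpool(spec$pool),
         nn_conv1d(spec$filters, spec$filters, spec$kernel), nn_relu(),
         nn_maxpool(spec$pool),
         nn_flatten()),
    head_layers(spec, t2 * spec$filters)))
}

tcn_block <- function(in_ch, filters, kernel, dilation, dropout) {
  body <- nn_seq(
    nn_conv1d(in_ch, filters, kernel, dilation, padding = "causal"),
    nn_bn_act_drop(filters, dropout),
    nn_conv1d(filters, filters, kernel, dilation, padding = "causal"),
    nn_bn_act_drop(filters, dropout))
  skip <- if (in_ch != filters) nn_conv1d(in_ch, filters, 1L) else NULL
  nn_residual(body, skip)
}

build_tcn_net <- function(spec) {
  blocks <- list()
  in_ch <- spec$channels
  for (d in spec$tcn_dilations) {
    blocks <- c(blocks, list(tcn_block(in_ch, spec$tcn_filters,
                                       spec$tcn_kernel, d, spec$dropout)))
    in_ch <- spec$tcn_filters
  }
  do.call(nn_seq, c(blocks, list(nn_gap()),
                    head_layers(spec, spec$tcn_filters)))
}

build_bilstm_net <- function(spec) {
  do.call(nn_seq, c(
    list(nn_lstm_bi(spec$channels, spec$lstm_units),
         nn_batchnorm(2L * spec$lstm_units),
         nn_lstm_bi(2L * spec$lstm_units, spec$lstm_units),
         nn_gap()),
    head_layers(spec, 2L * spec$lstm_units)))
}

build_crnn_net <- function(spec) {
  do.call(nn_seq, c(
    list(nn_conv1d(spec$channels, spec$filters, spec$kernel), nn_relu(),
         nn_maxpool(spec$pool),
         nn_batchnorm(spec$filters),
         nn_lstm_bi(spec$filters, spec$lstm_units),
         nn_gap()),
    head_layers(spec, 2L * spec$lstm_units)))
}

#' Parameter budget of a model
#'
#' Exact integer parameter counts, partitioned into trainable weights and
#' non-trainable buffers (the running statistics of batch-normalization
#' layers).
#'
#' @param model A `vr_model`.
#' @return List with `total`, `trainable`, `non_trainable`.
#' @examples
#' count_parameters(build_model(model_spec("crnn", "regression",
#'                                         scale = "desk")))
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "vr_model"))
  trainable <- sum(vapply(flatten_params(model$net), length, numeric(1)))
  non_trainable <- count_buffer_params(model$net)
  list(total = trainable + non_trainable, trainable = trainable,
       non_trainable = non_trainable)
}

#' @export
print.vr_model <- function(x, ...) {
  p <- count_parameters(x)
  cat(sprintf("<vr_model> %s / %s (%s scale): %s params (%s trainable)\n",
              x$spec$family, x$spec$task, x$spec$scale,
              format(p$total, big.mark = ","),
              format(p$trainable, big.mark = ",")))
  invisible(x)
}

#' Forward pass of a model
#'
#' Runs the network in inference mode (dropout off, batch norm using its
#' running statistics) over mini-batches.
#'
#' @param object A `vr_model`.
#' @param x Input array `(time, channels, batch)`.
#' @param batch_size Mini-batch size for the forward sweep.
#' @param ... Unused.
#' @return Matrix `(batch, out_dim)`: rates in Hz for regression, class
#'   probabilities for classification.
#' @export
predict.vr_model <- function(object, x, batch_size = 64L, ...) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[3]
  out <- matrix(NA_real_, n, object$spec$out_dim)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    r <- net_forward(object$net, x[, , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- r$y
  }
  out
}
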