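# The gated-attention 1-D CNN base classifier (CNN-S): one model per single
# spectral source. Architecture: attention gate, three 1-D convolutions
# (kernel 3, stride 1, same padding) with one max-pool after the first, then
# dense layers of 512/128/5 units, batch norm before every conv and dense
# layer, softmax output.

#' Attention-layer parameters
#'
#' The trainable weights of the multiplicative attention gate
#' \deqn{Y = \theta_{ReLU}(W_1 \cdot \theta_{ReLU}(W_2 X + b_1) + b_2) \odot X,}
#' where \eqn{X} is the length-`d` input, \eqn{W_2} maps it to a hidden width
#' `h` and \eqn{W_1} maps back to `d`.
#'
#' @param W1 Numeric matrix `d x h`.
#' @param W2 Numeric matrix `h x d`.
#' @param b1 Numeric vector length `h`.
#' @param b2 Numeric vector length `d`.
#' @return An `attention_params` object.
#' @export
attention_params <- function(W1, W2, b1, b2) {
  d <- nrow(W1); h <- ncol(W1)
  if (!all(dim(W2) == c(h, d)) || length(b1) != h || length(b2) != d) {
    stop("attention parameter shapes are inconsistent", call. = FALSE)
  }
  structure(list(W1 = W1, W2 = W2, b1 = b1, b2 = b2, d = d, h = h),
            class = "attention_params")
}

#' Attention gate forward pass
#'
#' Applies the multiplicative attention gate to one input vector or to a
#' batch (rows of a matrix): the gate is
#' `ReLU(W1 %*% ReLU(W2 %*% x + b1) + b2)` and the output is the elementwise
#' product of the gate with the input, so the output keeps the input's length
#' and every zero input coordinate stays zero.
#'
#' @param x Numeric vector of length `d`, or matrix with `d` columns.
#' @param params An [attention_params()].
#' @return Same shape as `x`.
#' @examples
#' p <- attention_params(W1 = diag(2), W2 = diag(2), b1 = c(0, 0), b2 = c(0, 0))
#' attention_forward(c(1, -1), p)
#' @export
attention_forward <- function(x, params) {
  stopifnot(inherits(params, "attention_params"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(xm) != params$d) stop("input length does not match `d`", call. = FALSE)
  lay <- list(type = "attention", W1 = t(params$W1), W2 = t(params$W2),
              b1 = params$b1, b2 = params$b2)
  out <- layer_forward(lay, xm)$out
  if (vec) as.numeric(out) else out
}

#' Base-classifier architecture configuration
#'
#' Hyperparameters of the CNN-S single-source classifier. The convolution
#' kernel (3), stride (1), pool size/stride (2/2) and dense widths
#' (512, 128, 5) follow the reference architecture; channel counts and the
#' attention hidden width are open choices exposed here.
#'
#' @param input_length Length of the input vector (e.g. 396 reflectance bands
#'   or 286 kinetic timepoints).
#' @param conv_channels Filters of the three 1-D convolutions.
#' @param kernel_size,stride Convolution geometry (fixed at 3 and 1).
#' @param pool_size,pool_stride Max-pool geometry (fixed at 2 and 2).
#' @param dense_sizes Dense-layer widths; must end in 5 (the class count).
#' @param attention_hidden Hidden width `h` of the attention gate; default
#'   `NULL` uses `input_length` (square maps).
#' @param batch_norm Insert batch normalization before every convolution and
#'   dense layer (default `TRUE`).
#' @return A `cnn_s_config` object.
#' @export
cnn_s_config <- function(input_length,
                         conv_channels = c(16L, 32L, 32L),
                         kernel_size = 3L, stride = 1L,
                         pool_size = 2L, pool_stride = 2L,
                         dense_sizes = c(512L, 128L, 5L),
                         attention_hidden = NULL,
                         batch_norm = TRUE) {
  if (kernel_size != 3L || stride != 1L || pool_size != 2L || pool_stride != 2L) {
    stop("kernel 3 / stride 1 / pool 2,2 are fixed in this architecture",
         call. = FALSE)
  }
  if (length(dense_sizes) != 3 || dense_sizes[3] != 5L) {
    stop("`dense_sizes` must be three widths ending in 5", call. = FALSE)
  }
  if (length(conv_channels) != 3) stop("three conv layers required", call. = FALSE)
  if (input_length < 4) stop("`input_length` too short", call. = FALSE)
  structure(
    list(input_length = as.integer(input_length),
         conv_channels = as.integer(conv_channels),
         kernel_size = 3L, stride = 1L, pool_size = 2L, pool_stride = 2L,
         dense_sizes = as.integer(dense_sizes),
         attention_hidden = as.integer(attention_hidden %||% input_length),
         batch_norm = isTRUE(batch_norm)),
    class = "cnn_s_config"
  )
}

# layer stack of a CNN-S; `head_from` marks where the final BN+dense head
# starts (everything before it yields the 128-d penultimate features)
build_cnn_s_layers <- function(cfg) {
  d <- cfg$input_length
  ch <- cfg$conv_channels
  l_pooled <- d %/% 2L
  flat <- l_pooled * ch[3]
  bn <- function(c) if (cfg$batch_norm) list(layer_bn(c)) else list()
  layers <- c(
    list(layer_attention(d, cfg$attention_hidden)),
    list(layer_to_conv()),
    bn(1L), list(layer_conv(1L, ch[1]), layer_relu(), layer_maxpool()),
    bn(ch[1]), list(layer_conv(ch[1], ch[2]), layer_relu()),
    bn(ch[2]), list(layer_conv(ch[2], ch[3]), layer_relu()),
    list(layer_flatten()),
    bn(flat), list(layer_dense(flat, cfg$dense_sizes[1]), layer_relu()),
    bn(cfg$dense_sizes[1]),
    list(layer_dense(cfg$dense_sizes[1], cfg$dense_sizes[2]), layer_relu()),
    bn(cfg$dense_sizes[2]),
    list(layer_dense(cfg$dense_sizes[2], cfg$dense_sizes[3]))
  )
  n_head <- if (cfg$batch_norm) 2L else 1L  # final (BN +) dense
  list(layers = layers, penultimate_at = length(layers) - n_head)
}

#' Construct an untrained CNN-S model
#'
#' @param cfg A [cnn_s_config()].
#' @param seed Integer seed for the fan-in-scaled random initialization.
#' @return A `cnn_s` model object.
#' @examples
#' m <- cnn_s(cnn_s_config(input_length = 32), seed = 1)
#' @export
cnn_s <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cnn_s_config"))
  set.seed(seed)
  built <- build_cnn_s_layers(cfg)
  structure(
    list(cfg = cfg, layers = built$layers,
         penultimate_at = built$penultimate_at,
         seed = as.integer(seed), input_mode = "stacked"),
    class = "cnn_s"
  )
}

#' @export
print.cnn_s <- function(x, ...) {
  cat(sprintf("<cnn_s> input %d, conv %s, attention hidden %d, %d layers\n",
              x$cfg$input_length,
              paste(x$cfg$conv_channels, collapse = "/"),
              x$cfg$attention_hidden, length(x$layers)))
  invisible(x)
}

as_input_matrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != d) {
    stop("input length ", ncol(x), " does not match the model's ", d,
         call. = FALSE)
  }
  x
}

#' CNN-S forward pass
#'
#' Runs the full classifier in inference mode and returns class
#' probabilities; each output row is a point on the 5-class probability
#' simplex.
#'
#' @param model A [cnn_s()] model.
#' @param x Input vector of length `input_length`, or a batch matrix with
#'   that many columns.
#' @return Matrix (batch x 5) of class probabilities.
#' @export
cnn_s_forward <- function(model, x) {
  stopifnot(inherits(model, "cnn_s"))
  x <- as_input_matrix(x, model$cfg$input_length)
  softmax_rows(net_forward(model$layers, x)$out)
}

#' Penultimate deep features
#'
#' The 128-unit activation feeding the final dense layer: the deep-feature
#' representation that middle-level fusion concatenates across sources.
#' Applying the model's remaining head (final batch norm + dense + softmax)
#' to these features reproduces [cnn_s_forward()].
#'
#' @inheritParams cnn_s_forward
#' @return Matrix (batch x 128).
#' @export
penultimate_features <- function(model, x) {
  stopifnot(inherits(model, "cnn_s"))
  x <- as_input_matrix(x, model$cfg$input_length)
  net_forward(model$layers, x, upto = model$penultimate_at)$out
}

#' Apply the classification head to penultimate features
#'
#' Completes a [penultimate_features()] call through the final batch norm,
#' dense layer and softmax.
#'
#' @param model A [cnn_s()] model.
#' @param feats Matrix (batch x 128) of penultimate features.
#' @return Matrix (batch x 5) of class probabilities.
#' @export
head_forward <- function(model, feats) {
  stopifnot(inherits(model, "cnn_s"))
  x <- feats
  for (i in (model$penultimate_at + 1L):length(model$layers)) {
    x <- layer_forward(model$layers[[i]], x)$out
  }
  softmax_rows(x)
}

# one SGD step on a minibatch; returns updated model plus batch loss and
# the batch predictions made during the pass
cnn_s_train_batch <- function(model, x, y, lr) {
  fw <- net_forward(model$layers, x, training = TRUE)
  prob <- softmax_rows(fw$out)
  loss <- cross_entropy(prob, y)
  dlogits <- (prob - onehot(y)) / nrow(x)
  model$layers <- net_backward_update(fw$layers, fw$caches, dlogits, lr)$layers
  list(model = model, loss = loss, pred = max.col(prob, ties.method = "first") - 1L)
}

#' Predict from a fitted model
#'
#' @param object A `cnn_s`, `middle_fusion`, `high_fusion`, or
#'   `two_stage_middle` model.
#' @param data Dataset tibble (list-column form) or a prepared feature
#'   matrix/list matching the model's input mode.
#' @param type `"class"` for integer labels 0--4, `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return Integer vector or probability matrix.
#' @export
predict.cnn_s <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- prepare_input(object, data)
  prob <- cnn_s_forward(object, x)
  if (type == "prob") prob else max.col(prob, ties.method = "first") - 1L
}

# resolve a dataset tibble (or raw matrix/list) into the model's input form
prepare_input <- function(model, data) {
  if (is.data.frame(data)) {
    strat <- model$strategy %||% fusion_strategy(model$modality %||% 5)
    assemble(data, strat, mode = model$input_mode)
  } else {
    data
  }
}
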