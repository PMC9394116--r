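# Minibatch SGD training with the stepped learning-rate schedule,
# validation-based snapshot selection, and accuracy / confusion-matrix
# evaluation.

#' Training configuration
#'
#' The reference training schedule: 500 epochs of minibatch SGD at batch
#' size 128, learning rate 0.005 reduced to one tenth every 100 epochs.
#' Shorter schedules are obtained by lowering `epochs`.
#'
#' @param epochs Number of epochs (>= 1).
#' @param base_lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor applied every `lr_step` epochs.
#' @param lr_step Epochs between decays.
#' @param batch_size Minibatch size (shrunk to the training-set size with a
#'   warning when larger).
#' @param seed Seed fixing shuffling and initialization-dependent randomness
#'   inside [train()].
#' @param select_by Snapshot-selection criterion on the validation set:
#'   highest `"accuracy"` (default) or lowest `"loss"`; ties go to the
#'   earliest epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 500L, base_lr = 0.005, lr_decay = 0.1,
                         lr_step = 100L, batch_size = 128L, seed = 1L,
                         select_by = c("accuracy", "loss")) {
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (base_lr <= 0) stop("`base_lr` must be positive", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(
    list(epochs = as.integer(epochs), base_lr = base_lr, lr_decay = lr_decay,
         lr_step = as.integer(lr_step), batch_size = as.integer(batch_size),
         seed = as.integer(seed), select_by = match.arg(select_by)),
    class = "train_config"
  )
}

#' Learning rate at a given epoch
#'
#' The stepped schedule: `base_lr * lr_decay^floor((epoch - 1) / lr_step)`,
#' i.e. 0.005 for epochs 1--100, 0.0005 for 101--200, and so on at the
#' defaults.
#'
#' @param epoch Epoch index (1-based, within `cfg$epochs`).
#' @param cfg A [train_config()].
#' @return The learning rate (scalar).
#' @examples
#' lr_at(150, train_config())
#' @export
lr_at <- function(epoch, cfg = train_config()) {
  if (any(epoch < 1) || any(epoch > cfg$epochs)) {
    stop("`epoch` out of range 1..", cfg$epochs, call. = FALSE)
  }
  cfg$base_lr * cfg$lr_decay^((epoch - 1L) %/% cfg$lr_step)
}

## ---- feature-structure helpers ------------------------------------------

feats_n <- function(x) if (is.list(x)) nrow(x[[1]]) else nrow(x)

feats_subset <- function(x, idx) {
  if (is.list(x)) {
    lapply(x, function(m) m[idx, , drop = FALSE])
  } else {
    x[idx, , drop = FALSE]
  }
}

model_batch_fn <- function(model) {
  switch(class(model)[1],
    cnn_s = cnn_s_train_batch,
    middle_fusion = middle_fusion_train_batch,
    high_fusion = high_fusion_train_batch,
    stop("no training routine for class ", class(model)[1], call. = FALSE)
  )
}

model_prob <- function(model, x) {
  switch(class(model)[1],
    cnn_s = cnn_s_forward(model, x),
    middle_fusion = middle_fusion_forward(model, x),
    high_fusion = high_fusion_forward(model, x)$y_F,
    stop("no forward routine for class ", class(model)[1], call. = FALSE)
  )
}

## ---- training loop -------------------------------------------------------

#' Train a model on a dataset split
#'
#' Minibatch SGD over `cfg$epochs` epochs with the stepped learning-rate
#' schedule. After every epoch the validation accuracy (full inference pass)
#' is recorded together with the running training accuracy and mean batch
#' loss; the returned model is the parameter snapshot with the best
#' validation performance (ties resolved toward the earliest epoch).
#' Deterministic given `cfg$seed` in single-threaded BLAS.
#'
#' @param model A [cnn_s()] (including [single_source_model()] /
#'   [low_level_model()]), [middle_fusion_model()] or [high_fusion_model()].
#' @param split A [stratified_split()], or a list with elements `train` and
#'   `validation` that are either dataset tibbles or `list(x, y)` pairs.
#' @param cfg A [train_config()].
#' @param ... Unused.
#' @return A `trained_model`: list with `model` (best snapshot), `history`
#'   (tibble: epoch, lr, loss, train_accuracy, val_accuracy, val_loss),
#'   `best_epoch`, `config`.
#' @export
train <- function(model, split, cfg = train_config(), ...) {
  UseMethod("train")
}

#' @export
train.default <- function(model, split, cfg = train_config(), ...) {
  tr <- split_part_features(model, split, "train")
  va <- split_part_features(model, split, "validation")
  train_on_matrices(model, tr, va, cfg)
}

split_part_features <- function(model, split, part) {
  d <- split[[part]]
  if (is.null(d)) stop("split lacks a `", part, "` component", call. = FALSE)
  if (is.data.frame(d)) {
    x <- prepare_input(model, d)
    list(x = x, y = d$label)
  } else {
    d
  }
}

# core loop over prepared feature structures: tr/va are list(x, y)
train_on_matrices <- function(model, tr, va, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  n <- feats_n(tr$x)
  if (n < 1 || feats_n(va$x) < 1) {
    stop("training and validation sets must be nonempty", call. = FALSE)
  }
  bs <- cfg$batch_size
  if (bs > n) {
    warning("batch size ", bs, " exceeds training-set size ", n,
            "; shrinking to ", n)
    bs <- n
  }
  set.seed(cfg$seed)
  batch_fn <- model_batch_fn(model)
  hist <- vector("list", cfg$epochs)
  best <- list(score = -Inf, epoch = NA_integer_, model = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at(epoch, cfg)
    ord <- sample.int(n)
    correct <- 0L
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- feats_subset(tr$x, idx)
      yb <- tr$y[idx]
      st <- batch_fn(model, xb, yb, lr)
      model <- st$model
      losses <- c(losses, st$loss)
      correct <- correct + sum(st$pred == yb)
    }
    vp <- model_prob(model, va$x)
    val_pred <- max.col(vp, ties.method = "first") - 1L
    val_acc <- mean(val_pred == va$y)
    val_loss <- cross_entropy(vp, va$y)
    score <- if (cfg$select_by == "accuracy") val_acc else -val_loss
    if (score > best$score) {
      best <- list(score = score, epoch = epoch, model = model)
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = mean(losses),
      train_accuracy = correct / n,
      val_accuracy = val_acc, val_loss = val_loss
    )
  }
  structure(
    list(model = best$model, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, config = cfg),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  last <- x$history[x$best_epoch, ]
  cat(sprintf("<trained_model> %s; best epoch %d/%d (val accuracy %.3f)\n",
              class(x$model)[1], x$best_epoch, x$config$epochs,
              last$val_accuracy))
  invisible(x)
}

#' @rdname predict.cnn_s
#' @export
predict.trained_model <- function(object, data, type = c("class", "prob"), ...) {
  predict(object$model, data, type = match.arg(type), ...)
}

## ---- evaluation ----------------------------------------------------------

#' Evaluate a classifier on labelled data
#'
#' Predicts (argmax of the class probabilities, ties toward the smallest
#' class index) and reports accuracy — the fraction of correctly classified
#' samples — together with the 5 x 5 confusion matrix (rows = true class,
#' columns = predicted).
#'
#' @param model A fitted model (any `predict()`-able model here, or a
#'   `trained_model` wrapper).
#' @param data Dataset tibble with a `label` column, or a `list(x, y)` pair
#'   of prepared features and labels.
#' @return An `eval_report`: list with `accuracy`, `confusion`, `n`.
#' @export
evaluate <- function(model, data) {
  if (inherits(model, "trained_model")) model <- model$model
  if (is.data.frame(data)) {
    if (nrow(data) == 0) stop("empty record list", call. = FALSE)
    y <- data$label
    pred <- predict(model, data, type = "class")
  } else {
    if (feats_n(data$x) == 0) stop("empty record list", call. = FALSE)
    y <- data$y
    prob <- model_prob(model, data$x)
    pred <- max.col(prob, ties.method = "first") - 1L
  }
  confusion <- table(factor(y, levels = 0:4), factor(pred, levels = 0:4))
  confusion <- matrix(as.integer(confusion), 5, 5,
                      dimnames = list(true = stress_classes,
                                      predicted = stress_classes))
  structure(
    list(accuracy = mean(pred == y), confusion = confusion, n = length(y)),
    class = "eval_report"
  )
}

#' Evaluate a model on every partition of a split
#'
#' @param model A fitted model.
#' @param split A [stratified_split()].
#' @return A tibble with one row per partition: `partition`, `n`, `accuracy`.
#' @export
evaluate_split <- function(model, split) {
  stopifnot(inherits(split, "dataset_split"))
  parts <- c("train", "validation", "test")
  dplyr::bind_rows(lapply(parts, function(p) {
    rep <- evaluate(model, split[[p]])
    tibble::tibble(partition = p, n = rep$n, accuracy = rep$accuracy)
  }))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f over %d samples\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}
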