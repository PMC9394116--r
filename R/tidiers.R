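# broom-style tidiers for fitted objects and reports.

#' Tidy a training history
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, lr, loss, train_accuracy,
#'   val_accuracy, val_loss).
#' @method tidy trained_model
#' @export
tidy.trained_model <- function(x, ...) x$history

#' @rdname tidy.trained_model
#' @return For `glance()`: a one-row tibble with the selected epoch and its
#'   validation accuracy/loss.
#' @method glance trained_model
#' @export
glance.trained_model <- function(x, ...) {
  row <- x$history[x$best_epoch, ]
  tibble::tibble(
    model = class(x$model)[1],
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    val_accuracy = row$val_accuracy,
    val_loss = row$val_loss
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [evaluate()].
#' @param ... Unused.
#' @return Long tibble of confusion-matrix cells: `true`, `predicted`, `n`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(df) <- c("true", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname tidy.eval_report
#' @return For `glance()`: one row with `accuracy` and `n`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' Tidy an SVM grid search
#'
#' @param x An `svm_fit` from [svm_train_select()].
#' @param ... Unused.
#' @return The grid-search tibble (`C`, `gamma`, `val_accuracy`).
#' @method tidy svm_fit
#' @export
tidy.svm_fit <- function(x, ...) x$search

#' @rdname tidy.svm_fit
#' @method glance svm_fit
#' @export
glance.svm_fit <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, val_accuracy = x$val_accuracy)
}
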