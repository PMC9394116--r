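# RBF-SVM reference classifier with validation-based grid selection over
# C and gamma, both spanning 10^-8..10^8 by decades.

#' SVM grid-search configuration
#'
#' @param c_grid Candidate values of the cost parameter C.
#' @param g_grid Candidate values of the RBF kernel width gamma.
#' @return An `svm_grid_config` object. The default grids each hold the 17
#'   decades from 1e-8 to 1e8 (289 candidate pairs).
#' @export
svm_grid_config <- function(c_grid = 10^(-8:8), g_grid = 10^(-8:8)) {
  if (length(c_grid) == 0 || length(g_grid) == 0 ||
      any(c_grid <= 0) || any(g_grid <= 0)) {
    stop("grids must be nonempty and positive", call. = FALSE)
  }
  structure(list(c_grid = sort(c_grid), g_grid = sort(g_grid)),
            class = "svm_grid_config")
}

#' Train an RBF-SVM with validation-selected hyperparameters
#'
#' Fits one RBF-kernel support vector machine per `(C, gamma)` pair on the
#' training set, scores each on the validation set, and returns the
#' best-validation-accuracy fit; ties are broken toward the smallest C, then
#' the smallest gamma.
#'
#' @param x_train,y_train Training features (matrix) and labels.
#' @param x_val,y_val Validation features and labels.
#' @param grid An [svm_grid_config()].
#' @return An `svm_fit`: list with the fitted `model` (an [e1071::svm()]
#'   object), chosen `C` and `gamma`, `val_accuracy`, and the full `search`
#'   tibble.
#' @export
svm_train_select <- function(x_train, y_train, x_val, y_val,
                             grid = svm_grid_config()) {
  stopifnot(inherits(grid, "svm_grid_config"))
  if (length(unique(y_train)) < 2) {
    stop("degenerate single-class training set", call. = FALSE)
  }
  if (nrow(x_train) == 0 || nrow(x_val) == 0) {
    stop("training and validation sets must be nonempty", call. = FALSE)
  }
  yf <- factor(y_train, levels = sort(unique(y_train)))
  best <- list(acc = -Inf, model = NULL, C = NA_real_, g = NA_real_)
  rows <- vector("list", length(grid$c_grid) * length(grid$g_grid))
  k <- 0L
  for (C in grid$c_grid) {
    for (g in grid$g_grid) {
      fit <- e1071::svm(x_train, yf, kernel = "radial", cost = C, gamma = g,
                        scale = FALSE)
      pred <- as.character(predict(fit, x_val))
      acc <- mean(pred == as.character(y_val))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(C = C, gamma = g, val_accuracy = acc)
      if (acc > best$acc) {
        best <- list(acc = acc, model = fit, C = C, g = g)
      }
    }
  }
  structure(
    list(model = best$model, C = best$C, gamma = best$g,
         val_accuracy = best$acc, search = dplyr::bind_rows(rows),
         levels = levels(yf)),
    class = "svm_fit"
  )
}

#' @rdname predict.cnn_s
#' @export
predict.svm_fit <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(data)) assemble(data, fusion_strategy(5)) else data
  pred <- as.integer(as.character(predict(object$model, x)))
  if (type == "prob") {
    onehot(pred)  # libsvm decision values are not calibrated; report hard votes
  } else {
    pred
  }
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit> rbf, C = %g, gamma = %g (validation accuracy %.3f)\n",
              x$C, x$gamma, x$val_accuracy))
  invisible(x)
}
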