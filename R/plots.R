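# ggplot2 visualisations: class-mean curves of a dataset, training history,
# confusion matrices, benchmark summaries.

#' Plot class-mean curves of a multimodal dataset
#'
#' Averages each modality's curves per class and draws them in one facetted
#' panel, the quickest check that a generated (or imported) dataset has the
#' intended class structure.
#'
#' @param data Dataset tibble (list-column form).
#' @param modalities Which modalities to draw.
#' @return A ggplot object.
#' @export
plot_class_means <- function(data, modalities = c("l_visnir", "s_visnir",
                                                  "l_fkc", "s_fkc")) {
  modalities <- intersect(modalities, names(data))
  long <- dplyr::bind_rows(lapply(modalities, function(m) {
    mat <- do.call(rbind, data[[m]])
    means <- stats::aggregate(mat, by = list(class = data$class), FUN = mean)
    tidyr::pivot_longer(
      tibble::as_tibble(means),
      cols = -"class", names_to = "index", values_to = "value"
    ) |>
      dplyr::mutate(index = as.integer(factor(.data$index,
                                              levels = unique(.data$index))),
                    modality = m)
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$index, .data$value,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~modality, scales = "free") +
    ggplot2::labs(x = "band / timepoint index", y = "signal",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot method for training histories
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trained_model
#' @export
autoplot.trained_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              cols = c("train_accuracy", "val_accuracy"),
                              names_to = "set", values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$accuracy,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = "Training history",
                  subtitle = "dashed line: selected snapshot") +
    ggplot2::theme_minimal()
}

#' Plot method for evaluation reports (confusion heatmap)
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy.eval_report(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(stress_classes)) +
    ggplot2::scale_x_discrete(limits = stress_classes) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a fusion-benchmark summary
#'
#' @param bench Tibble from [fusion_benchmark()].
#' @return A ggplot object: per-family test accuracies across seeds.
#' @export
plot_benchmark <- function(bench) {
  ggplot2::ggplot(bench, ggplot2::aes(.data$source, .data$test,
                                      colour = .data$family)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4) +
    ggplot2::labs(x = NULL, y = "test accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
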