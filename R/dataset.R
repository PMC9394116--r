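# Dataset assembly: the five modality-subset fusion strategies, stratified
# 4:1:1 splitting, and feature-matrix assembly for the classifiers.

modality_names <- c("l_visnir", "s_visnir", "l_fkc", "s_fkc")

#' The five fusion strategies
#'
#' Which of the four modality vectors each named strategy fuses:
#' Fusion 1 combines the two reflectance sources (leaf + stem VIS/NIR),
#' Fusion 2 the two fluorescence-kinetics sources, Fusion 3 the leaf pair,
#' Fusion 4 the stem pair, and Fusion 5 all four.
#'
#' @return A 5-row tibble with columns `name`, `l_visnir`, `s_visnir`,
#'   `l_fkc`, `s_fkc`.
#' @export
fusion_strategies <- function() {
  tibble::tibble(
    name = paste("Fusion", 1:5),
    l_visnir = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    s_visnir = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    l_fkc = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    s_fkc = c(FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

#' Select a fusion strategy
#'
#' @param strategy An integer 1--5 (row of [fusion_strategies()]), a strategy
#'   name like `"Fusion 5"`, or a character vector of modality names (a subset
#'   of `c("l_visnir", "s_visnir", "l_fkc", "s_fkc")`) for ad-hoc subsets.
#' @return A `fusion_strategy` object: named list with `name` and the vector
#'   of selected `modalities` in the fixed concatenation order.
#' @examples
#' fusion_strategy(5)
#' fusion_strategy(c("l_visnir", "l_fkc"))
#' @export
fusion_strategy <- function(strategy) {
  tab <- fusion_strategies()
  if (is.numeric(strategy) && length(strategy) == 1 && strategy %in% 1:5) {
    row <- tab[strategy, ]
  } else if (is.character(strategy) && length(strategy) == 1 &&
             strategy %in% tab$name) {
    row <- tab[tab$name == strategy, ]
  } else if (is.character(strategy) && all(strategy %in% modality_names)) {
    sel <- modality_names[modality_names %in% strategy]
    return(structure(list(name = paste(sel, collapse = "+"), modalities = sel),
                     class = "fusion_strategy"))
  } else {
    stop("unknown fusion strategy", call. = FALSE)
  }
  sel <- modality_names[unlist(row[modality_names])]
  structure(list(name = row$name, modalities = sel), class = "fusion_strategy")
}

#' @export
print.fusion_strategy <- function(x, ...) {
  cat("<fusion_strategy>", x$name, "->", paste(x$modalities, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified 4:1:1 dataset split
#'
#' Randomly partitions each class into training, validation and test sets in
#' a 4:1:1 ratio: per class of size `n`, validation and test each receive
#' `floor(n / 6)` samples and training the remainder. Classes with fewer than
#' 3 samples go entirely to training, with a warning. Deterministic given
#' `seed`.
#'
#' @param data Dataset tibble with a `label` column (e.g. from
#'   [generate_dataset()]).
#' @param seed Integer seed for the random assignment.
#' @return A `dataset_split` object: list with tibbles `train`, `validation`,
#'   `test`, plus `ratio` and `seed`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_per_class = rep(12, 5)))
#' sp <- stratified_split(d, seed = 7)
#' nrow(sp$train)
#' @export
stratified_split <- function(data, seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  if (anyNA(data$label)) stop("every record must be labelled", call. = FALSE)
  set.seed(seed)
  part <- character(nrow(data))
  for (lab in sort(unique(data$label))) {
    idx <- which(data$label == lab)
    n <- length(idx)
    if (n < 3) {
      warning("class ", lab, " has fewer than 3 samples; all assigned to training")
      part[idx] <- "train"
      next
    }
    n_val <- n %/% 6L
    n_test <- n %/% 6L
    shuffled <- sample(idx)
    part[shuffled[seq_len(n_val)]] <- "validation"
    part[shuffled[n_val + seq_len(n_test)]] <- "test"
    part[shuffled[(n_val + n_test + 1L):n]] <- "train"
  }
  structure(
    list(
      train = data[part == "train", , drop = FALSE],
      validation = data[part == "validation", , drop = FALSE],
      test = data[part == "test", , drop = FALSE],
      ratio = c(4L, 1L, 1L),
      seed = as.integer(seed)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}

#' Assemble model inputs from a dataset
#'
#' Builds the feature structure a model consumes from the list-column dataset
#' tibble, for a given fusion strategy. `mode = "stacked"` concatenates the
#' selected modality vectors per sample into one long row (fixed order:
#' leaf reflectance, stem reflectance, leaf kinetics, stem kinetics), as used
#' by low-level fusion and the SVM. `mode = "per_modality"` returns one
#' matrix per selected modality, as used by the multi-branch fusion models.
#'
#' @param data Dataset tibble.
#' @param strategy A [fusion_strategy()], or anything it accepts.
#' @param mode `"stacked"` or `"per_modality"`.
#' @return For `"stacked"`, a numeric matrix (samples x features) with the
#'   labels in attribute `"label"`; for `"per_modality"`, a named list of
#'   matrices with the same attribute.
#' @examples
#' d <- generate_dataset(synthetic_config(n_per_class = rep(2, 5)))
#' dim(assemble(d, fusion_strategy(5)))
#' @export
assemble <- function(data, strategy = fusion_strategy(5),
                     mode = c("stacked", "per_modality")) {
  mode <- match.arg(mode)
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  missing <- setdiff(strategy$modalities, names(data))
  if (length(missing) > 0) {
    stop("dataset lacks modalities: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- data$label
  mats <- lapply(strategy$modalities, function(m) {
    lens <- lengths(data[[m]])
    if (length(unique(lens)) > 1) {
      stop("inconsistent vector lengths in modality ", m, call. = FALSE)
    }
    mat <- do.call(rbind, data[[m]]) %||% matrix(numeric(0), 0, 0)
    if (nrow(mat) > 0) rownames(mat) <- data$sample_id
    mat
  })
  names(mats) <- strategy$modalities
  if (mode == "stacked") {
    out <- do.call(cbind, mats)
    attr(out, "label") <- labels
    out
  } else {
    attr(mats, "label") <- labels
    mats
  }
}

#' Write and read a multimodal dataset as delimited text
#'
#' One CSV per modality, named `<prefix>_<modality>.csv`, each with columns
#' `sample_id`, `label`, then the feature columns.
#'
#' @param data Dataset tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory path, invisibly (`write_dataset`); the reconstructed
#'   tibble (`read_dataset`).
#' @export
write_dataset <- function(data, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in intersect(modality_names, names(data))) {
    mat <- do.call(rbind, data[[m]])
    df <- data.frame(sample_id = data$sample_id, label = data$label, mat,
                     check.names = FALSE)
    names(df) <- c("sample_id", "label", sprintf("f%04d", seq_len(ncol(mat))))
    write.csv(df, file.path(dir, paste0(prefix, "_", m, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, prefix = "synth") {
  out <- NULL
  for (m in modality_names) {
    path <- file.path(dir, paste0(prefix, "_", m, ".csv"))
    if (!file.exists(path)) next
    df <- read.csv(path, check.names = FALSE)
    vecs <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, -(1:2)]))
    if (is.null(out)) {
      out <- tibble::tibble(
        sample_id = as.character(df$sample_id),
        label = as.integer(df$label),
        class = factor(stress_classes[df$label + 1], levels = stress_classes)
      )
    }
    out[[m]] <- vecs
  }
  if (is.null(out)) stop("no modality files found under ", dir, call. = FALSE)
  out
}

#' Split manifest I/O
#'
#' Records which partition each sample belongs to, as a two-column CSV
#' (`sample_id`, `partition`), so a split can be reproduced elsewhere.
#'
#' @param split A [stratified_split()] result.
#' @param path Output CSV path.
#' @return `path` invisibly (`write_split_manifest`); a tibble
#'   (`read_split_manifest`).
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  one <- function(part) {
    ids <- split[[part]]$sample_id
    data.frame(sample_id = ids, partition = rep(part, length(ids)))
  }
  df <- rbind(one("train"), one("validation"), one("test"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
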