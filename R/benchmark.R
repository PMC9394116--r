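# The synthetic complementarity benchmark: train single-source and fusion
# models on generated data and compare test accuracies. At complementarity 1
# each single source is blind to one class pair by construction (the
# herbicide pair collapses in reflectance, the heavy-metal pair in kinetics),
# so no single modality can exceed 80% on a balanced set while the fused
# sources can; at complementarity 0 every family should solve the task.

#' Fusion-versus-single-source benchmark on synthetic data
#'
#' Generates a multimodal dataset, splits it 4:1:1, trains the requested
#' model families and reports per-family test accuracy, one run per seed.
#' Families: `"single"` (one CNN-S per modality), `"low"`, `"middle"`,
#' `"high"` (the three end-to-end fusion levels on `strategy`).
#'
#' @param seeds Integer vector; one dataset/split/training replicate per
#'   seed.
#' @param n_per_class Samples per class for the generated datasets.
#' @param complementarity,noise_sd,class_effect_scale Generator conditions
#'   (see [synthetic_config()]).
#' @param n_bands,n_timepoints Curve lengths.
#' @param families Which model families to train.
#' @param strategy Fusion strategy for the fusion families (default all four
#'   modalities).
#' @param train_cfg A [train_config()]; the per-seed configs derive their
#'   seeds from it.
#' @param ... Passed to [cnn_s_config()] for every model.
#' @return Tibble with columns `seed`, `family`, `source` (modality or
#'   strategy name), and `train`/`validation`/`test` accuracies.
#' @export
fusion_benchmark <- function(seeds = 1:3,
                             n_per_class = rep(200L, 5),
                             complementarity = 1,
                             noise_sd = 0.02,
                             class_effect_scale = 1,
                             n_bands = 396L, n_timepoints = 286L,
                             families = c("single", "high"),
                             strategy = fusion_strategy(5),
                             train_cfg = train_config(epochs = 100L),
                             ...) {
  families <- match.arg(families, c("single", "low", "middle", "high"),
                        several.ok = TRUE)
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  out <- list()
  for (sd_i in seeds) {
    gen <- synthetic_config(
      n_per_class = n_per_class, n_bands = n_bands,
      n_timepoints = n_timepoints, class_effect_scale = class_effect_scale,
      noise_sd = noise_sd, complementarity = complementarity, seed = sd_i
    )
    split <- stratified_split(generate_dataset(gen), seed = sd_i)
    mats <- lapply(c("train", "validation", "test"), function(p) {
      assemble(split[[p]], fusion_strategy(5), mode = "per_modality")
    })
    names(mats) <- c("train", "validation", "test")
    labels <- lapply(split[c("train", "validation", "test")], `[[`, "label")
    part <- function(p, mods) {
      x <- mats[[p]][mods]
      if (length(mods) == 1) x <- x[[1]] else x
      list(x = x, y = labels[[p]])
    }
    stacked_part <- function(p, mods) {
      list(x = do.call(cbind, mats[[p]][mods]), y = labels[[p]])
    }
    cfg_i <- train_cfg
    cfg_i$seed <- sd_i
    accs <- function(fit, featfun) {
      vapply(c("train", "validation", "test"),
             function(p) evaluate(fit$model, featfun(p))$accuracy, numeric(1))
    }
    if ("single" %in% families) {
      for (mod in names(default_modality_lengths)) {
        model <- cnn_s(cnn_s_config(input_length = ncol(mats$train[[mod]]), ...),
                       seed = sd_i)
        fit <- train_on_matrices(model, part("train", mod),
                                 part("validation", mod), cfg_i)
        a <- accs(fit, function(p) part(p, mod))
        out[[length(out) + 1L]] <- tibble::tibble(
          seed = sd_i, family = "single", source = mod,
          train = a[1], validation = a[2], test = a[3]
        )
      }
    }
    lens <- vapply(mats$train[strategy$modalities], ncol, integer(1))
    if ("low" %in% families) {
      model <- cnn_s(cnn_s_config(input_length = sum(lens), ...), seed = sd_i)
      fit <- train_on_matrices(model, stacked_part("train", strategy$modalities),
                               stacked_part("validation", strategy$modalities),
                               cfg_i)
      a <- accs(fit, function(p) stacked_part(p, strategy$modalities))
      out[[length(out) + 1L]] <- tibble::tibble(
        seed = sd_i, family = "low", source = strategy$name,
        train = a[1], validation = a[2], test = a[3]
      )
    }
    if ("middle" %in% families) {
      model <- middle_fusion_model(strategy, lengths = lens, seed = sd_i, ...)
      fit <- train_on_matrices(model, part("train", strategy$modalities),
                               part("validation", strategy$modalities), cfg_i)
      a <- accs(fit, function(p) part(p, strategy$modalities))
      out[[length(out) + 1L]] <- tibble::tibble(
        seed = sd_i, family = "middle", source = strategy$name,
        train = a[1], validation = a[2], test = a[3]
      )
    }
    if ("high" %in% families) {
      model <- high_fusion_model(strategy, lengths = lens, seed = sd_i, ...)
      fit <- train_on_matrices(model, part("train", strategy$modalities),
                               part("validation", strategy$modalities), cfg_i)
      a <- accs(fit, function(p) part(p, strategy$modalities))
      out[[length(out) + 1L]] <- tibble::tibble(
        seed = sd_i, family = "high", source = strategy$name,
        train = a[1], validation = a[2], test = a[3]
      )
    }
  }
  dplyr::bind_rows(out)
}
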