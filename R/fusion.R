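# The three fusion levels over the modality-subset strategies:
#  low    - concatenate raw vectors, classify with one CNN-S;
#  middle - per-source CNN-S trunks to 128-d deep features, per-branch linear
#           map + ReLU, concatenation, dense head; one cross-entropy,
#           trained end-to-end;
#  high   - full per-source CNN-S submodels, concatenated probability
#           vectors into a 5-unit dense head; joint loss = head cross-entropy
#           plus every submodel's cross-entropy, trained end-to-end.
# Plus the two-stage baselines (separately trained extractors / probability
# averaging).

default_modality_lengths <- c(l_visnir = 396L, s_visnir = 396L,
                              l_fkc = 286L, s_fkc = 286L)

strategy_lengths <- function(strategy, lengths) {
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  missing <- setdiff(strategy$modalities, names(lengths))
  if (length(missing)) {
    stop("no length given for modality ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lengths[strategy$modalities]
}

#' Low-level fusion model
#'
#' A CNN-S consuming the raw concatenation of the selected modality vectors
#' (`assemble(..., mode = "stacked")` rows): the input length is the sum of
#' the selected modality lengths (1364 for Fusion 5 at the default 396-band /
#' 286-timepoint curves).
#'
#' @param strategy A [fusion_strategy()] or anything it accepts.
#' @param lengths Named vector of modality lengths.
#' @param seed Initialization seed.
#' @param ... Passed to [cnn_s_config()] (e.g. `conv_channels`,
#'   `attention_hidden`).
#' @return A `cnn_s` model whose `strategy` is recorded for assembly.
#' @examples
#' m <- low_level_model(1, lengths = c(l_visnir = 64, s_visnir = 64))
#' m$cfg$input_length
#' @export
low_level_model <- function(strategy, lengths = default_modality_lengths,
                            seed = 1L, ...) {
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  lens <- strategy_lengths(strategy, lengths)
  model <- cnn_s(cnn_s_config(input_length = sum(lens), ...), seed = seed)
  model$strategy <- strategy
  model$level <- "low"
  model
}

#' Single-source CNN-S model
#'
#' Convenience constructor for a base classifier on one modality, with the
#' modality recorded so dataset tibbles can be fed directly to [predict()]
#' and [train()].
#'
#' @param modality One of `"l_visnir"`, `"s_visnir"`, `"l_fkc"`, `"s_fkc"`.
#' @inheritParams low_level_model
#' @return A `cnn_s` model.
#' @export
single_source_model <- function(modality, lengths = default_modality_lengths,
                                seed = 1L, ...) {
  modality <- match.arg(modality, names(default_modality_lengths))
  model <- cnn_s(cnn_s_config(input_length = lengths[[modality]], ...),
                 seed = seed)
  model$strategy <- fusion_strategy(modality)
  model$level <- "single"
  model
}

## ---- middle-level fusion -------------------------------------------------

#' Middle-level (deep-feature) fusion model
#'
#' One CNN-S trunk per selected modality, truncated after the 128-unit dense
#' layer; each trunk's features pass through a trainable branch map (a
#' 128 x 128 linear map + ReLU, or a scalar weight when
#' `scalar_weights = TRUE`), are concatenated, and feed a dense layer with 5
#' units + softmax. The whole graph trains end-to-end with a single
#' cross-entropy on the fused output.
#'
#' @inheritParams low_level_model
#' @param scalar_weights Use a single trainable scalar per branch instead of
#'   a 128 x 128 linear map.
#' @param ... Passed to [cnn_s_config()] for every branch trunk.
#' @return A `middle_fusion` model.
#' @export
middle_fusion_model <- function(strategy = fusion_strategy(5),
                                lengths = default_modality_lengths,
                                seed = 1L, scalar_weights = FALSE, ...) {
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  lens <- strategy_lengths(strategy, lengths)
  m <- length(lens)
  if (m < 2) stop("middle-level fusion needs at least 2 modalities", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(1e6, m + 2L)
  branches <- vector("list", m)
  feat_dim <- NULL
  for (i in seq_len(m)) {
    bm <- cnn_s(cnn_s_config(input_length = lens[i], ...), seed = seeds[i])
    feat_dim <- bm$cfg$dense_sizes[2]
    branches[[i]] <- bm
  }
  # branch maps start as the identity so the fused features initially equal
  # the raw deep features; training reweights them from there
  branch_maps <- lapply(seq_len(m), function(i) {
    if (scalar_weights) {
      list(w = 1)
    } else {
      list(type = "dense", W = diag(feat_dim), b = numeric(feat_dim))
    }
  })
  set.seed(seeds[m + 2L])
  head <- layer_dense(feat_dim * m, 5L)
  structure(
    list(strategy = strategy, branches = branches, branch_maps = branch_maps,
         head = head, scalar_weights = scalar_weights, feat_dim = feat_dim,
         seed = as.integer(seed), input_mode = "per_modality",
         level = "middle"),
    class = "middle_fusion"
  )
}

middle_branch_apply <- function(map, feats, scalar) {
  if (scalar) {
    z <- map$w * feats
    z * (z > 0)
  } else {
    z <- sweep(feats %*% map$W, 2, map$b, "+")
    z * (z > 0)
  }
}

#' Middle-level fusion forward pass
#'
#' @param model A [middle_fusion_model()].
#' @param xs Named or ordered list with one input matrix per branch
#'   (`assemble(..., mode = "per_modality")`).
#' @return Matrix (batch x 5) of fused class probabilities.
#' @export
middle_fusion_forward <- function(model, xs) {
  stopifnot(inherits(model, "middle_fusion"))
  xs <- check_branch_inputs(model, xs)
  feats <- lapply(seq_along(model$branches), function(i) {
    penultimate_features(model$branches[[i]], xs[[i]])
  })
  z <- do.call(cbind, lapply(seq_along(feats), function(i) {
    middle_branch_apply(model$branch_maps[[i]], feats[[i]], model$scalar_weights)
  }))
  softmax_rows(sweep(z %*% model$head$W, 2, model$head$b, "+"))
}

check_branch_inputs <- function(model, xs) {
  m <- length(model$branches)
  if (!is.list(xs) || length(xs) != m) {
    stop("expected a list of ", m, " branch inputs", call. = FALSE)
  }
  if (!is.null(names(xs)) && all(model$strategy$modalities %in% names(xs))) {
    xs <- xs[model$strategy$modalities]
  }
  lapply(seq_len(m), function(i) {
    as_input_matrix(xs[[i]], model$branches[[i]]$cfg$input_length)
  })
}

middle_fusion_train_batch <- function(model, xs, y, lr) {
  m <- length(model$branches)
  n <- nrow(xs[[1]])
  fws <- vector("list", m)
  feats <- vector("list", m)
  mapped <- vector("list", m)
  for (i in seq_len(m)) {
    fw <- net_forward(model$branches[[i]]$layers, xs[[i]], training = TRUE,
                      upto = model$branches[[i]]$penultimate_at)
    fws[[i]] <- fw
    feats[[i]] <- fw$out
    mapped[[i]] <- middle_branch_apply(model$branch_maps[[i]], feats[[i]],
                                       model$scalar_weights)
  }
  z <- do.call(cbind, mapped)
  prob <- softmax_rows(sweep(z %*% model$head$W, 2, model$head$b, "+"))
  loss <- cross_entropy(prob, y)
  dlogits <- (prob - onehot(y)) / n
  dz <- tcrossprod(dlogits, model$head$W)
  model$head$W <- model$head$W - lr * crossprod(z, dlogits)
  model$head$b <- model$head$b - lr * colSums(dlogits)
  fd <- model$feat_dim
  for (i in seq_len(m)) {
    dzi <- dz[, (i - 1L) * fd + seq_len(fd), drop = FALSE]
    act <- mapped[[i]] > 0
    dpre <- dzi * act
    if (model$scalar_weights) {
      model$branch_maps[[i]]$w <- model$branch_maps[[i]]$w -
        lr * sum(dpre * feats[[i]])
      dfeat <- dpre * model$branch_maps[[i]]$w
    } else {
      dfeat <- tcrossprod(dpre, model$branch_maps[[i]]$W)
      model$branch_maps[[i]]$W <- model$branch_maps[[i]]$W -
        lr * crossprod(feats[[i]], dpre)
      model$branch_maps[[i]]$b <- model$branch_maps[[i]]$b - lr * colSums(dpre)
    }
    model$branches[[i]]$layers <- net_backward_update(
      fws[[i]]$layers, fws[[i]]$caches, dfeat, lr,
      from = model$branches[[i]]$penultimate_at
    )$layers
  }
  list(model = model, loss = loss,
       pred = max.col(prob, ties.method = "first") - 1L)
}

#' @rdname predict.cnn_s
#' @export
predict.middle_fusion <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- prepare_input(object, data)
  prob <- middle_fusion_forward(object, xs)
  if (type == "prob") prob else max.col(prob, ties.method = "first") - 1L
}

## ---- high-level (decision) fusion ---------------------------------------

#' High-level (decision) fusion model
#'
#' One complete CNN-S (softmax included) per selected modality; the
#' submodels' probability vectors are concatenated (length `5 m`) and fed to
#' a dense layer with five units + softmax for the fused decision. Training
#' is end-to-end under the joint loss ([joint_loss()]): the fused output's
#' cross-entropy plus every submodel's own cross-entropy, so each submodel is
#' forced toward the true class distribution while the head learns to
#' combine them.
#'
#' @inheritParams middle_fusion_model
#' @return A `high_fusion` model.
#' @export
high_fusion_model <- function(strategy = fusion_strategy(5),
                              lengths = default_modality_lengths,
                              seed = 1L, ...) {
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  lens <- strategy_lengths(strategy, lengths)
  m <- length(lens)
  if (m < 2) stop("high-level fusion needs at least 2 modalities", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(1e6, m + 1L)
  branches <- lapply(seq_len(m), function(i) {
    cnn_s(cnn_s_config(input_length = lens[i], ...), seed = seeds[i])
  })
  # the decision head starts as a probability averager (stacked identity
  # blocks), i.e. exactly the two-stage decision-fusion rule; end-to-end
  # training then learns how to reweight the submodels' votes
  head <- list(type = "dense",
               W = do.call(rbind, rep(list(diag(5)), m)),
               b = numeric(5L))
  structure(
    list(strategy = strategy, branches = branches, head = head,
         seed = as.integer(seed), input_mode = "per_modality",
         level = "high"),
    class = "high_fusion"
  )
}

#' High-level fusion forward pass
#'
#' @param model A [high_fusion_model()].
#' @param xs List with one input matrix per branch.
#' @return A `high_fusion_output`: list with `y_F` (batch x 5 fused
#'   probabilities) and `y_subs` (list of per-submodel probability matrices).
#' @export
high_fusion_forward <- function(model, xs) {
  stopifnot(inherits(model, "high_fusion"))
  xs <- check_branch_inputs(model, xs)
  y_subs <- lapply(seq_along(model$branches), function(i) {
    cnn_s_forward(model$branches[[i]], xs[[i]])
  })
  pcat <- do.call(cbind, y_subs)
  y_f <- softmax_rows(sweep(pcat %*% model$head$W, 2, model$head$b, "+"))
  structure(list(y_F = y_f, y_subs = y_subs), class = "high_fusion_output")
}

#' Joint decision-fusion loss
#'
#' The training loss of the end-to-end decision-fusion model: the
#' cross-entropy of the fused output plus the cross-entropy of every
#' submodel's output against the same true class,
#' \deqn{Loss = \ell(y, y_F) + \sum_i \ell(y, y_i).}
#' Zero exactly when the fused head and every submodel are one-hot correct;
#' probabilities are floored at `1e-12` inside the logarithm.
#'
#' @param out A `high_fusion_output` (from [high_fusion_forward()]), or any
#'   list with elements `y_F` and `y_subs`.
#' @param y True class labels (integer 0--4, one per batch row).
#' @return Nonnegative scalar (mean over the batch).
#' @examples
#' onehot_row <- matrix(c(1, 0, 0, 0, 0), 1)
#' out <- list(y_F = onehot_row, y_subs = rep(list(onehot_row), 4))
#' joint_loss(out, 0)
#' @export
joint_loss <- function(out, y) {
  stopifnot(!is.null(out$y_F), !is.null(out$y_subs))
  loss <- cross_entropy(out$y_F, y)
  for (p in out$y_subs) loss <- loss + cross_entropy(p, y)
  loss
}

high_fusion_train_batch <- function(model, xs, y, lr) {
  m <- length(model$branches)
  n <- nrow(xs[[1]])
  fws <- vector("list", m)
  y_subs <- vector("list", m)
  for (i in seq_len(m)) {
    fw <- net_forward(model$branches[[i]]$layers, xs[[i]], training = TRUE)
    fws[[i]] <- fw
    y_subs[[i]] <- softmax_rows(fw$out)
  }
  pcat <- do.call(cbind, y_subs)
  y_f <- softmax_rows(sweep(pcat %*% model$head$W, 2, model$head$b, "+"))
  loss <- joint_loss(list(y_F = y_f, y_subs = y_subs), y)
  oh <- onehot(y)
  dlogits_f <- (y_f - oh) / n
  dpcat <- tcrossprod(dlogits_f, model$head$W)
  model$head$W <- model$head$W - lr * crossprod(pcat, dlogits_f)
  model$head$b <- model$head$b - lr * colSums(dlogits_f)
  for (i in seq_len(m)) {
    p <- y_subs[[i]]
    dp <- dpcat[, (i - 1L) * 5L + 1:5, drop = FALSE]
    # back through the submodel softmax, plus the submodel's own CE term
    dz <- p * (dp - rowSums(dp * p)) + (p - oh) / n
    model$branches[[i]]$layers <- net_backward_update(
      fws[[i]]$layers, fws[[i]]$caches, dz, lr
    )$layers
  }
  pred <- max.col(y_f, ties.method = "first") - 1L
  list(model = model, loss = loss, pred = pred)
}

#' @rdname predict.cnn_s
#' @export
predict.high_fusion <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- prepare_input(object, data)
  out <- high_fusion_forward(object, xs)
  if (type == "prob") out$y_F else max.col(out$y_F, ties.method = "first") - 1L
}

## ---- two-stage baselines -------------------------------------------------

#' Two-stage middle-level fusion
#'
#' The conventional two-stage baseline: stage 1 trains an independent CNN-S
#' per selected modality; stage 2 freezes them, extracts their 128-d
#' penultimate features, concatenates (width `128 m`) and trains a fresh
#' CNN-S on the fused feature table. For all four modalities this trains
#' `m + 1 = 5` models.
#'
#' @param split A [stratified_split()] of a multimodal dataset.
#' @param strategy A [fusion_strategy()] or anything it accepts.
#' @param cfg A [train_config()] shared by all stages.
#' @param lengths Named modality lengths.
#' @param ... Passed to [cnn_s_config()] for every model.
#' @return A `two_stage_middle` object: `extractors` (the frozen stage-1
#'   models), `stage2` (the fused-feature classifier), their histories, and
#'   `n_models_trained`.
#' @export
two_stage_middle <- function(split, strategy = fusion_strategy(5),
                             cfg = train_config(),
                             lengths = default_modality_lengths, ...) {
  stopifnot(inherits(split, "dataset_split"))
  if (!inherits(strategy, "fusion_strategy")) strategy <- fusion_strategy(strategy)
  set.seed(cfg$seed)
  seeds <- sample.int(1e6, length(strategy$modalities) + 1L)
  extractors <- list()
  for (i in seq_along(strategy$modalities)) {
    mod <- strategy$modalities[i]
    model <- single_source_model(mod, lengths = lengths, seed = seeds[i], ...)
    cfg_i <- cfg; cfg_i$seed <- seeds[i]
    extractors[[mod]] <- train(model, split, cfg_i)
  }
  feat_of <- function(data) {
    do.call(cbind, lapply(strategy$modalities, function(mod) {
      x <- assemble(data, fusion_strategy(mod), mode = "stacked")
      penultimate_features(extractors[[mod]]$model, x)
    }))
  }
  fused_split <- list(
    train = list(x = feat_of(split$train), y = split$train$label),
    validation = list(x = feat_of(split$validation), y = split$validation$label),
    test = list(x = feat_of(split$test), y = split$test$label)
  )
  feat_width <- ncol(fused_split$train$x)
  stage2_model <- cnn_s(cnn_s_config(input_length = feat_width, ...),
                        seed = seeds[length(seeds)])
  cfg2 <- cfg; cfg2$seed <- seeds[length(seeds)]
  stage2 <- train_on_matrices(stage2_model, fused_split$train,
                              fused_split$validation, cfg2)
  structure(
    list(strategy = strategy, extractors = extractors, stage2 = stage2,
         feat_of = feat_of, feat_width = feat_width,
         n_models_trained = length(strategy$modalities) + 1L),
    class = "two_stage_middle"
  )
}

#' @rdname predict.cnn_s
#' @export
predict.two_stage_middle <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prob <- cnn_s_forward(object$stage2$model, object$feat_of(data))
  if (type == "prob") prob else max.col(prob, ties.method = "first") - 1L
}

#' Two-stage high-level fusion (probability averaging)
#'
#' Decision fusion of separately trained classifiers: averages their
#' predicted probability vectors and picks the arithmetic-mean argmax, ties
#' broken toward the smallest class index.
#'
#' @param prob_vectors List of probability vectors (or matrices with matching
#'   rows), one per classifier, each row on the 5-class simplex.
#' @return List with `class` (integer, per row) and `mean` (the averaged
#'   probability vector/matrix).
#' @examples
#' two_stage_high(list(c(.6, .4, 0, 0, 0), c(.2, .8, 0, 0, 0)))
#' @export
two_stage_high <- function(prob_vectors) {
  if (!is.list(prob_vectors) || length(prob_vectors) == 0) {
    stop("`prob_vectors` must be a nonempty list", call. = FALSE)
  }
  mats <- lapply(prob_vectors, function(p) {
    if (is.null(dim(p))) matrix(p, nrow = 1) else p
  })
  avg <- Reduce(`+`, mats) / length(mats)
  cls <- max.col(avg, ties.method = "first") - 1L
  if (nrow(avg) == 1) avg <- as.numeric(avg)
  list(class = cls, mean = avg)
}
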