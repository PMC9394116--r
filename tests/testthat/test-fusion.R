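test_that("low-level fusion widths equal summed modality lengths", {
  m5 <- low_level_model(5, seed = 1)
  expect_equal(m5$cfg$input_length, 1364L)
  m1 <- low_level_model(1, seed = 1)
  expect_equal(m1$cfg$input_length, 792L)

  tiny <- low_level_model(5, lengths = tiny_lengths, seed = 1,
                          conv_channels = c(2, 3, 3), attention_hidden = 4)
  set.seed(2)
  p <- cnn_s_forward(tiny, matrix(rnorm(2 * 56), 2))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})

test_that("middle fusion concatenates branch-mapped deep features", {
  mm <- middle_fusion_model(fusion_strategy(5), lengths = tiny_lengths,
                            seed = 2, conv_channels = c(2, 3, 3),
                            dense_sizes = c(16, 8, 5), attention_hidden = 4)
  set.seed(3)
  xs <- lapply(tiny_lengths, function(L) matrix(rnorm(3 * L), 3))
  p <- middle_fusion_forward(mm, xs)
  expect_equal(dim(p), c(3L, 5L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # identity branch maps at construction: fused vector is the concatenation
  # of the (ReLU of the) raw deep features
  feats <- lapply(seq_along(xs), function(i) {
    penultimate_features(mm$branches[[i]], xs[[i]])
  })
  z_manual <- do.call(cbind, lapply(feats, function(f) f * (f > 0)))
  logits <- sweep(z_manual %*% mm$head$W, 2, mm$head$b, "+")
  expect_equal(p, phenofuse:::softmax_rows(logits), tolerance = 1e-12)
  # head input width is feat_dim per branch times branch count
  expect_equal(nrow(mm$head$W), 4L * mm$feat_dim)
})

test_that("branch ReLU zeroes negative feature coordinates", {
  f <- matrix(c(-1, 2, 0, -3), 1)
  out <- phenofuse:::middle_branch_apply(
    list(type = "dense", W = diag(4), b = numeric(4)), f, scalar = FALSE
  )
  expect_equal(as.numeric(out), c(0, 2, 0, 0))
})

test_that("high-level fusion concatenates submodel probability vectors", {
  hm <- high_fusion_model(fusion_strategy(5), lengths = tiny_lengths,
                          seed = 3, conv_channels = c(2, 3, 3),
                          dense_sizes = c(16, 8, 5), attention_hidden = 4)
  expect_equal(nrow(hm$head$W), 20L)  # 5 * 4 fused-input width
  set.seed(4)
  xs <- lapply(tiny_lengths, function(L) matrix(rnorm(2 * L), 2))
  out <- high_fusion_forward(hm, xs)
  expect_s3_class(out, "high_fusion_output")
  expect_length(out$y_subs, 4L)
  pcat <- do.call(cbind, out$y_subs)
  expect_equal(rowSums(pcat), rep(4, 2), tolerance = 1e-6)
  expect_equal(rowSums(out$y_F), rep(1, 2), tolerance = 1e-6)
  expect_true(all(out$y_F >= 0))
})

test_that("a head reading only submodel 1 reproduces its decisions", {
  hm <- high_fusion_model(fusion_strategy(5), lengths = tiny_lengths,
                          seed = 5, conv_channels = c(2, 3, 3),
                          dense_sizes = c(16, 8, 5), attention_hidden = 4)
  hm$head$W <- rbind(diag(5), matrix(0, 15, 5))
  hm$head$b <- numeric(5)
  set.seed(6)
  xs <- lapply(tiny_lengths, function(L) matrix(rnorm(6 * L), 6))
  out <- high_fusion_forward(hm, xs)
  expect_equal(max.col(out$y_F, ties.method = "first"),
               max.col(out$y_subs[[1]], ties.method = "first"))
})

test_that("joint loss closed-form values", {
  oh <- matrix(c(1, 0, 0, 0, 0), 1)
  unif <- matrix(rep(0.2, 5), 1)
  perfect <- list(y_F = oh, y_subs = rep(list(oh), 4))
  expect_equal(joint_loss(perfect, 0), 0, tolerance = 1e-9)
  all_unif <- list(y_F = unif, y_subs = rep(list(unif), 4))
  expect_equal(joint_loss(all_unif, 0), 5 * log(5), tolerance = 1e-9)
  one_unif <- list(y_F = oh, y_subs = list(oh, oh, oh, unif))
  expect_equal(joint_loss(one_unif, 0), log(5), tolerance = 1e-9)
})

test_that("joint loss dominates the fused-output loss", {
  set.seed(7)
  for (rep in 1:10) {
    out <- list(y_F = random_simplex_rows(3),
                y_subs = replicate(4, random_simplex_rows(3), simplify = FALSE))
    y <- sample(0:4, 3, replace = TRUE)
    expect_gte(joint_loss(out, y), phenofuse:::cross_entropy(out$y_F, y))
  }
})

test_that("probability averaging decides like the printed toy cases", {
  four <- rep(list(c(1, 0, 0, 0, 0)), 4)
  res <- two_stage_high(four)
  expect_equal(res$class, 0L)
  expect_equal(res$mean, c(1, 0, 0, 0, 0))

  vecs <- list(c(.6, .4, 0, 0, 0), c(.2, .8, 0, 0, 0),
               c(.5, .5, 0, 0, 0), c(.1, .9, 0, 0, 0))
  res2 <- two_stage_high(vecs)
  expect_equal(res2$mean, c(.35, .65, 0, 0, 0))
  expect_equal(res2$class, 1L)

  tie <- list(c(.5, .5, 0, 0, 0), c(.5, .5, 0, 0, 0))
  expect_equal(two_stage_high(tie)$class, 0L)  # ties go to the smaller index

  expect_error(two_stage_high(list()), "nonempty")
})

test_that("averaged probabilities stay on the simplex", {
  set.seed(8)
  mats <- replicate(3, random_simplex_rows(6), simplify = FALSE)
  res <- two_stage_high(mats)
  expect_equal(rowSums(res$mean), rep(1, 6), tolerance = 1e-9)
  expect_true(all(res$mean >= 0))
})

test_that("two-stage middle fusion trains m + 1 models on frozen features", {
  d <- generate_dataset(tiny_gen_cfg(n = 12L, noise_sd = 0.02, seed = 9))
  sp <- stratified_split(d, seed = 9)
  ts <- two_stage_middle(sp, fusion_strategy(5),
                         train_config(epochs = 2, batch_size = 16, seed = 1),
                         lengths = tiny_lengths,
                         conv_channels = c(2, 3, 3), dense_sizes = c(16, 8, 5),
                         attention_hidden = 4)
  expect_equal(ts$n_models_trained, 5L)
  expect_equal(ts$feat_width, 4L * 8L)  # branches' penultimate width summed
  # extractors are frozen: feature extraction is reproducible bitwise
  f1 <- ts$feat_of(sp$test)
  f2 <- ts$feat_of(sp$test)
  expect_identical(f1, f2)
  pred <- predict(ts, sp$test)
  expect_length(pred, nrow(sp$test))
  expect_true(all(pred %in% 0:4))
})
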