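test_that("the stepped learning-rate schedule decays tenfold per 100 epochs", {
  cfg <- train_config()
  expect_equal(lr_at(50, cfg), 0.005)
  expect_equal(lr_at(150, cfg), 0.0005)
  expect_equal(lr_at(450, cfg), 5e-7)
  expect_equal(lr_at(100, cfg), 0.005)   # boundary: decay starts at 101
  expect_equal(lr_at(101, cfg), 0.0005)
  expect_error(lr_at(0, cfg), "out of range")
  expect_error(lr_at(501, cfg), "out of range")
})

make_tiny_split <- function(seed = 1, n = 12L, noise = 0.03) {
  d <- generate_dataset(tiny_gen_cfg(n = n, noise_sd = noise, seed = seed))
  stratified_split(d, seed = seed)
}

test_that("training records a full history and returns the best snapshot", {
  sp <- make_tiny_split()
  model <- single_source_model("l_visnir", lengths = tiny_lengths, seed = 1,
                               conv_channels = c(2, 3, 3),
                               dense_sizes = c(16, 8, 5), attention_hidden = 4)
  cfg <- train_config(epochs = 5, batch_size = 16, seed = 2)
  fit <- train(model, sp, cfg)
  expect_equal(nrow(fit$history), 5L)
  expect_named(fit$history,
               c("epoch", "lr", "loss", "train_accuracy", "val_accuracy",
                 "val_loss"))
  expect_equal(fit$history$lr, rep(0.005, 5))
  best <- evaluate(fit$model, sp$validation)$accuracy
  expect_equal(best, max(fit$history$val_accuracy))
  expect_equal(fit$history$val_accuracy[fit$best_epoch], best)
  # ties resolve to the earliest epoch
  firsts <- which(fit$history$val_accuracy == best)
  expect_equal(fit$best_epoch, firsts[1])
})

test_that("training is reproducible under a fixed seed", {
  sp <- make_tiny_split()
  mk <- function() single_source_model("l_fkc", lengths = tiny_lengths,
                                       seed = 4, conv_channels = c(2, 3, 3),
                                       dense_sizes = c(16, 8, 5),
                                       attention_hidden = 4)
  cfg <- train_config(epochs = 4, batch_size = 16, seed = 9)
  f1 <- train(mk(), sp, cfg)
  f2 <- train(mk(), sp, cfg)
  expect_identical(f1$best_epoch, f2$best_epoch)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, sp$test), predict(f2, sp$test))
})

test_that("oversized batches shrink with a warning", {
  sp <- make_tiny_split()
  model <- single_source_model("l_visnir", lengths = tiny_lengths, seed = 1,
                               conv_channels = c(2, 3, 3),
                               dense_sizes = c(16, 8, 5), attention_hidden = 4)
  expect_warning(
    train(model, sp, train_config(epochs = 1, batch_size = 1000, seed = 1)),
    "batch size"
  )
})

test_that("evaluation reports accuracy as trace over total", {
  sp <- make_tiny_split()
  # stub classifiers make the accounting exact and deterministic
  perfect <- structure(list(), class = c("oracle_clf", "list"))
  assign("predict.oracle_clf",
         function(object, data, type = "class", ...) data$label,
         envir = globalenv())
  on.exit(rm("predict.oracle_clf", envir = globalenv()), add = TRUE)
  rpt <- evaluate(perfect, sp$test)
  expect_equal(rpt$accuracy, 1)
  expect_true(all(rpt$confusion[upper.tri(rpt$confusion)] == 0))
  expect_equal(sum(diag(rpt$confusion)), rpt$n)

  constant <- structure(list(), class = c("const_clf", "list"))
  assign("predict.const_clf",
         function(object, data, type = "class", ...) rep(0L, nrow(data)),
         envir = globalenv())
  on.exit(rm("predict.const_clf", envir = globalenv()), add = TRUE)
  rpt0 <- evaluate(constant, sp$test)
  expect_equal(rpt0$accuracy, 0.2)  # balanced five-class set
  expect_equal(sum(rpt0$confusion), rpt0$n)
  expect_equal(unname(rowSums(rpt0$confusion)),
               as.integer(table(factor(sp$test$label, levels = 0:4))))
})

test_that("confusion-matrix row sums equal true class counts for real models", {
  sp <- make_tiny_split()
  model <- single_source_model("s_visnir", lengths = tiny_lengths, seed = 2,
                               conv_channels = c(2, 3, 3),
                               dense_sizes = c(16, 8, 5), attention_hidden = 4)
  fit <- train(model, sp, train_config(epochs = 2, batch_size = 16, seed = 3))
  for (part in c("train", "validation", "test")) {
    rpt <- evaluate(fit, sp[[part]])
    expect_equal(sum(rpt$confusion), nrow(sp[[part]]))
    expect_equal(unname(rowSums(rpt$confusion)),
                 as.integer(table(factor(sp[[part]]$label, levels = 0:4))))
  }
})

test_that("the whole protocol is reproducible end to end", {
  run <- function() {
    d <- generate_dataset(tiny_gen_cfg(n = 10L, noise_sd = 0.02, seed = 31))
    sp <- stratified_split(d, seed = 32)
    model <- single_source_model("l_visnir", lengths = tiny_lengths, seed = 33,
                                 conv_channels = c(2, 3, 3),
                                 dense_sizes = c(16, 8, 5),
                                 attention_hidden = 4)
    fit <- train(model, sp, train_config(epochs = 3, batch_size = 16, seed = 33))
    evaluate(fit, sp$test)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("tidiers expose history and reports as tibbles", {
  sp <- make_tiny_split()
  model <- single_source_model("l_visnir", lengths = tiny_lengths, seed = 1,
                               conv_channels = c(2, 3, 3),
                               dense_sizes = c(16, 8, 5), attention_hidden = 4)
  fit <- train(model, sp, train_config(epochs = 2, batch_size = 16, seed = 1))
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$best_epoch, fit$best_epoch)
  rpt <- evaluate(fit, sp$test)
  td <- tidy(rpt)
  expect_equal(nrow(td), 25L)
  expect_equal(sum(td$n), rpt$n)
  expect_equal(glance(rpt)$accuracy, rpt$accuracy)
})
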