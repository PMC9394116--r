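test_that("attention gate closed-form cases", {
  d <- 3L
  zero <- attention_params(W1 = matrix(0, d, d), W2 = matrix(0, d, d),
                           b1 = numeric(d), b2 = numeric(d))
  expect_equal(attention_forward(c(1, 2, 3), zero), c(0, 0, 0))

  ident <- attention_params(W1 = matrix(0, d, d), W2 = matrix(0, d, d),
                            b1 = numeric(d), b2 = rep(1, d))
  x <- c(-2, 0.5, 4)
  expect_equal(attention_forward(x, ident), x)

  # d = h = 2, identity weights, zero biases, x = (1, -1):
  # inner ReLU gives (1, 0), outer ReLU gives (1, 0), gated product (1, 0)
  p2 <- attention_params(W1 = diag(2), W2 = diag(2),
                         b1 = c(0, 0), b2 = c(0, 0))
  expect_equal(attention_forward(c(1, -1), p2), c(1, 0))
})

test_that("attention zeroes propagate and the gate is nonnegative", {
  set.seed(21)
  d <- 12L; h <- 7L
  for (rep in 1:5) {
    p <- attention_params(W1 = matrix(rnorm(d * h), d, h),
                          W2 = matrix(rnorm(h * d), h, d),
                          b1 = rnorm(h), b2 = rnorm(d))
    x <- rnorm(d)
    x[sample(d, 4)] <- 0
    y <- attention_forward(x, p)
    expect_true(all(y[x == 0] == 0))
    # gate >= 0 elementwise, so signs are preserved or zeroed
    expect_true(all(sign(y) == 0 | sign(y) == sign(x)))
  }
})

test_that("attention rejects mismatched shapes", {
  expect_error(attention_params(W1 = diag(2), W2 = diag(3),
                                b1 = c(0, 0), b2 = c(0, 0)), "shapes")
  p <- attention_params(W1 = diag(2), W2 = diag(2), b1 = c(0, 0), b2 = c(0, 0))
  expect_error(attention_forward(c(1, 2, 3), p), "length")
})

test_that("classifier outputs live on the probability simplex", {
  m <- cnn_s(tiny_cnn_cfg(), seed = 2)
  set.seed(5)
  x <- matrix(rnorm(7 * 16), 7)
  p <- cnn_s_forward(m, x)
  expect_equal(dim(p), c(7L, 5L))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # random parameter draws keep the property
  for (s in 3:5) {
    ms <- cnn_s(tiny_cnn_cfg(), seed = s)
    ps <- cnn_s_forward(ms, x[1:2, , drop = FALSE])
    expect_equal(rowSums(ps), rep(1, 2), tolerance = 1e-6)
    expect_true(all(ps >= 0))
  }
  expect_error(cnn_s_forward(m, matrix(0, 1, 10)), "length")
})

test_that("inference is deterministic and batch rows match single passes", {
  m <- cnn_s(tiny_cnn_cfg(), seed = 3)
  set.seed(6)
  x <- matrix(rnorm(4 * 16), 4)
  expect_identical(cnn_s_forward(m, x), cnn_s_forward(m, x))
  expect_equal(cnn_s_forward(m, x)[2, ],
               as.numeric(cnn_s_forward(m, x[2, ])), tolerance = 1e-12)
})

test_that("penultimate features feed the head consistently", {
  cfg <- cnn_s_config(input_length = 396)
  m <- cnn_s(cfg, seed = 1)
  set.seed(7)
  x <- matrix(rnorm(3 * 396), 3)
  f <- penultimate_features(m, x)
  expect_equal(ncol(f), 128L)
  expect_identical(f, penultimate_features(m, x))
  expect_equal(head_forward(m, f), cnn_s_forward(m, x), tolerance = 1e-12)
})

test_that("one SGD step decreases a single example's loss", {
  m <- cnn_s(tiny_cnn_cfg(), seed = 4)
  set.seed(8)
  x <- matrix(rnorm(16), 1)
  y <- 2L
  # compare losses under the same (training-mode) normalization statistics;
  # a zero-learning-rate pass reads the loss without moving the parameters
  before <- phenofuse:::cnn_s_train_batch(m, x, y, lr = 0)$loss
  st <- phenofuse:::cnn_s_train_batch(m, x, y, lr = 1e-4)
  after <- phenofuse:::cnn_s_train_batch(st$model, x, y, lr = 0)$loss
  expect_lt(after, before)
})

test_that("architecture constraints are enforced", {
  expect_error(cnn_s_config(input_length = 64, kernel_size = 5), "fixed")
  expect_error(cnn_s_config(input_length = 64, dense_sizes = c(512, 128, 4)),
               "ending in 5")
  cfg <- cnn_s_config(input_length = 64)
  expect_equal(cfg$attention_hidden, 64L)  # square attention maps by default
})
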