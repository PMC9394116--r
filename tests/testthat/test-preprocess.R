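test_that("black-white calibration maps the references to 0 and 1", {
  white <- matrix(runif(12, 90, 110), 3, 4)
  black <- matrix(runif(12, 0, 5), 3, 4)
  expect_equal(calibrate(white, white, black), matrix(1, 3, 4))
  expect_equal(calibrate(black, white, black), matrix(0, 3, 4))
  expect_equal(calibrate((white + black) / 2, white, black), matrix(0.5, 3, 4))
})

test_that("calibration broadcasts per-band references and rejects degenerate ones", {
  raw <- matrix(50, 2, 3)
  expect_equal(calibrate(raw, white = rep(100, 3), black = rep(0, 3)),
               matrix(0.5, 2, 3))
  expect_error(calibrate(raw, white = rep(0, 3), black = rep(0, 3)),
               "degenerate")
  expect_error(calibrate(raw, white = c(100, 100, -1), black = rep(0, 3)),
               "degenerate")
})

test_that("calibration is affine in the raw image", {
  set.seed(1)
  white <- matrix(runif(20, 90, 110), 4, 5)
  black <- matrix(runif(20, 0, 5), 4, 5)
  r1 <- matrix(runif(20, 10, 80), 4, 5)
  r2 <- matrix(runif(20, 10, 80), 4, 5)
  a <- 0.3
  lhs <- calibrate(a * r1 + (1 - a) * r2, white, black)
  rhs <- a * calibrate(r1, white, black) + (1 - a) * calibrate(r2, white, black)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("ROI averaging reduces to the pixel curves it contains", {
  cube <- array(0, c(2, 2, 6))
  u <- 1:6; v <- seq(2, 12, by = 2)
  cube[1, 1, ] <- u
  cube[2, 2, ] <- v
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(roi_mean_curve(cube, m1), u)
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(roi_mean_curve(cube, m2), (u + v) / 2)
  expect_error(roi_mean_curve(cube, matrix(FALSE, 2, 2)), "empty")
})

test_that("denoised ROI mean of a constant cube is the constant curve", {
  cube <- array(2.5, c(2, 2, 32))
  mask <- matrix(TRUE, 2, 2)
  out <- roi_mean_curve(cube, mask, spec = wavelet_spec())
  expect_equal(out, rep(2.5, 32), tolerance = 1e-8)
})

test_that("mask splitting commutes with ROI averaging", {
  set.seed(2)
  cube <- array(runif(4 * 3 * 8), c(4, 3, 8))
  m_a <- matrix(FALSE, 4, 3); m_a[1:2, ] <- TRUE
  m_b <- matrix(FALSE, 4, 3); m_b[3:4, ] <- TRUE
  full <- m_a | m_b
  w_a <- sum(m_a) / sum(full)
  expect_equal(
    w_a * roi_mean_curve(cube, m_a) + (1 - w_a) * roi_mean_curve(cube, m_b),
    roi_mean_curve(cube, full),
    tolerance = 1e-12
  )
})

test_that("band truncation keeps the closed 454-957 nm window", {
  wl <- 380:1030
  out <- truncate_bands(seq_along(wl), wl)
  expect_length(out, 504L)
  expect_equal(attr(out, "wavelengths")[1], 454)
  expect_equal(max(attr(out, "wavelengths")), 957)

  expect_equal(as.numeric(truncate_bands(1:5, c(10, 20, 30, 40, 50),
                                         low = 0, high = 100)), 1:5)
  expect_length(truncate_bands(1:3, c(400, 500, 600),
                               low = 500, high = 500), 1L)
  expect_error(truncate_bands(1:3, c(1, 2, 3), low = 10, high = 20), "window")
})

test_that("maximum normalization scales to a unit maximum", {
  expect_equal(max_normalize(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(max_normalize(rep(3, 5)), rep(1, 5))
  x <- c(0.1, 0.7, 1.0, 0.4)
  expect_equal(max_normalize(x), x)              # idempotent on normalized input
  expect_equal(max_normalize(17.3 * x), max_normalize(x))  # scale invariant
  expect_error(max_normalize(c(-1, 0)), "degenerate")
})

test_that("the full extraction chain produces a unit-max curve", {
  set.seed(3)
  nb <- 40L
  wl <- seq(440, 980, length.out = nb)
  true_curve <- 0.2 + 0.5 * plogis((wl - 700) / 20)
  cube <- array(rep(true_curve * 80 + 10, each = 9), c(3, 3, nb)) +
    array(rnorm(9 * nb, sd = 0.5), c(3, 3, nb))
  mask <- matrix(TRUE, 3, 3)
  out <- extract_sample_curve(cube, mask, white = rep(90, nb),
                              black = rep(10, nb), wavelengths = wl)
  expect_equal(max(out), 1)
  expect_true(length(out) < nb)  # ends outside the window are dropped
})
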