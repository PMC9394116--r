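test_that("curve generation is deterministic given a seed", {
  cfg <- synthetic_config(noise_sd = 0.05)
  a <- generate_visnir(2, "leaf", cfg, seed = 11)
  b <- generate_visnir(2, "leaf", cfg, seed = 11)
  expect_identical(a, b)
  f1 <- generate_fkc(3, "stem", cfg, seed = 7)
  f2 <- generate_fkc(3, "stem", cfg, seed = 7)
  expect_identical(f1, f2)
})

test_that("with no class effect and no noise all labels share the baseline", {
  cfg <- synthetic_config(class_effect_scale = 0, noise_sd = 0)
  base <- visnir_baseline(cfg$n_bands, "leaf")$reflectance
  for (lab in 0:4) {
    expect_equal(generate_visnir(lab, "leaf", cfg), base, tolerance = 1e-12)
  }
  ref <- generate_fkc(0, "leaf", cfg)
  for (lab in 1:4) {
    expect_equal(generate_fkc(lab, "leaf", cfg), ref, tolerance = 1e-12)
  }
})

test_that("class templates separate when the effect is on", {
  cfg <- synthetic_config(class_effect_scale = 1, noise_sd = 0)
  t0 <- visnir_template(0, "leaf", cfg)
  t1 <- visnir_template(1, "leaf", cfg)
  expect_gt(sqrt(sum((t0 - t1)^2)), 0)
})

test_that("kinetic curves rise above their initial fluorescence", {
  cfg <- synthetic_config(noise_sd = 0)
  for (lab in 0:4) {
    for (organ in c("leaf", "stem")) {
      f <- generate_fkc(lab, organ, cfg)
      expect_gte(max(f), f[1])
      expect_true(all(f >= 0))
    }
  }
})

test_that("invalid labels and organs are rejected", {
  cfg <- synthetic_config()
  expect_error(generate_visnir(5, "leaf", cfg), "label")
  expect_error(generate_visnir(-1, "leaf", cfg), "label")
  expect_error(generate_fkc(1, "root", cfg))
})

test_that("generated datasets have exact per-class counts and vector lengths", {
  cfg <- synthetic_config(n_per_class = rep(10L, 5))
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 50L)
  expect_equal(as.integer(table(d$label)), rep(10L, 5))
  expect_true(all(lengths(d$l_visnir) == 396L))
  expect_true(all(lengths(d$s_visnir) == 396L))
  expect_true(all(lengths(d$l_fkc) == 286L))
  expect_true(all(lengths(d$s_fkc) == 286L))
  expect_false(anyNA(unlist(d$l_visnir)))

  single <- generate_dataset(synthetic_config(n_per_class = c(0, 0, 0, 0, 1)))
  expect_equal(nrow(single), 1L)
  expect_equal(single$label, 4L)
})

test_that("identical configurations reproduce datasets bitwise", {
  cfg <- tiny_gen_cfg(noise_sd = 0.05, seed = 42)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("nearest-template classification is exact on noise-free shared-signal data", {
  cfg <- synthetic_config(n_per_class = rep(4L, 5), noise_sd = 0,
                          class_effect_scale = 1, complementarity = 0)
  d <- classify_nearest_template(generate_dataset(cfg), cfg,
                                 modalities = "l_visnir")
  expect_equal(d$nearest_template, d$label)
})

test_that("at full complementarity fused modalities beat any single one", {
  # Bayes-style oracle: nearest-template accuracy per modality vs on the
  # concatenation, median over three seeds, with noise that confuses the
  # designated class pairs within each single modality family.
  accs <- sapply(1:3, function(s) {
    cfg <- synthetic_config(n_per_class = rep(12L, 5), noise_sd = 0.08,
                            complementarity = 1, seed = s)
    d <- generate_dataset(cfg)
    single <- sapply(c("l_visnir", "s_visnir", "l_fkc", "s_fkc"), function(m) {
      mean(classify_nearest_template(d, cfg, m)$nearest_template == d$label)
    })
    fused <- mean(classify_nearest_template(d, cfg)$nearest_template == d$label)
    c(best_single = max(single), fused = fused)
  })
  expect_gt(stats::median(accs["fused", ]), stats::median(accs["best_single", ]))
})

test_that("dataset text round trip preserves curves and labels", {
  d <- generate_dataset(tiny_gen_cfg(n = 3L, seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(d, dir, prefix = "t")
  d2 <- read_dataset(dir, prefix = "t")
  expect_equal(d2$label, d$label)
  expect_equal(d2$l_visnir, d$l_visnir, tolerance = 1e-12)
  expect_equal(d2$s_fkc, d$s_fkc, tolerance = 1e-12)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(synthetic_config(n_per_class = rep(2, 4)), "n_per_class")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(complementarity = 1.5), "complementarity")
  expect_error(synthetic_config(class_effect_scale = -0.1), "class_effect_scale")
})
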