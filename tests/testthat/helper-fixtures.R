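# Small shared fixtures: tiny architectures and datasets keep the unit tests
# fast; full-size structures are exercised where a width itself is the claim.

tiny_cnn_cfg <- function(len = 16L) {
  cnn_s_config(input_length = len, conv_channels = c(2L, 3L, 3L),
               dense_sizes = c(16L, 8L, 5L), attention_hidden = 4L)
}

tiny_gen_cfg <- function(n = 6L, ...) {
  synthetic_config(n_per_class = rep(n, 5), n_bands = 16L, n_timepoints = 12L,
                   ...)
}

tiny_lengths <- c(l_visnir = 16L, s_visnir = 16L, l_fkc = 12L, s_fkc = 12L)

random_simplex_rows <- function(n, k = 5L) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
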