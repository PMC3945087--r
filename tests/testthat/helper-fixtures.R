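# Shared small fixtures, built once per test run.
# All sizes are desk-scale: large enough for stable statistics of the checked
# property, small enough to keep the suite fast.

# tiny cyclic dataset (5x5 torus, D = 24) with circulant whitening: the
# analytic ground truth (Fourier quadrature bank) is exactly invariant here
tiny_cyclic <- local({
  side <- 5L
  n <- 3000L
  patches <- make_circulant_pink_patches(n, side, seed = 301)
  proc <- transform_process("translation_cyclic", n_pairs = n, seed = 302,
                            max_shift = 2)
  pairs <- cyclic_shift_pairs(patches, proc)
  pre <- fit_preprocessor(rbind(pairs$x_t, pairs$x_t1), circulant_side = side)
  list(side = side, pairs = pairs, pre = pre,
       wpairs = preprocess_pairs(pre, pairs))
})

# whitened-coordinate Fourier quadrature bank for a circulant preprocessor
fourier_bank_whitened <- function(pre, side) {
  fb <- fourier_quadrature_basis(side)
  Wf <- filters_to_whitened_space(pre, t(fb$basis[, -1, drop = FALSE]))
  filter_bank(symmetric_orthogonalize(Wf), K = 2)
}

# small translation dataset on a pink-noise image
tiny_translation <- local({
  img <- make_pink_noise_image(128, 128, 1, seed = 311)
  proc <- transform_process("translation_open", n_pairs = 4000, seed = 312,
                            max_shift = 2)
  pairs <- translation_pairs(img, proc, 11)
  pre <- fit_preprocessor(rbind(pairs$x_t, pairs$x_t1))
  list(img = img, pairs = pairs, pre = pre,
       wpairs = preprocess_pairs(pre, pairs))
})

# random whitened pair set in D dimensions (no structure; for gradient and
# algebraic checks)
random_pairs <- function(D, n, seed) {
  with_seed(seed, {
    ps <- list(x_t = matrix(stats::rnorm(n * D), n, D),
               x_t1 = matrix(stats::rnorm(n * D), n, D),
               patch_side = NA, process = NULL, steps = NULL)
    class(ps) <- "pair_set"
    ps
  })
}

# central finite-difference gradient of f at W (matrix argument)
fd_gradient <- function(f, W, h = 1e-6) {
  G <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      Wp <- W; Wm <- W
      Wp[i, j] <- Wp[i, j] + h
      Wm[i, j] <- Wm[i, j] - h
      G[i, j] <- (f(Wp) - f(Wm)) / (2 * h)
    }
  }
  G
}
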