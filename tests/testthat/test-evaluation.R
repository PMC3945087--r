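# Evaluation metrics: slowness ranking, spectra, phases, recovery scores,
# localization, trade-off machinery.

test_that("rank_subspaces orders by ascending inverse slowness", {
  # hand case: energies 0 -> 2 (s = 4) and 0 -> 1 (s = 1)
  ps <- random_pairs(4, 1, seed = 1)
  ps$x_t <- matrix(0, 1, 4)
  ps$x_t1 <- matrix(c(sqrt(2), 0, 1, 0), 1, 4)
  rk <- rank_subspaces(filter_bank(diag(4), K = 2), ps)
  expect_identical(rk$subspace_order, c(2L, 1L))
  expect_equal(rk$s_by_subspace, c(1, 4))
  expect_identical(sort(rk$s_unsorted), sort(rk$s_by_subspace))

  # Fourier bank on cyclic data: everything at machine-zero slowness,
  # ties broken by original index
  bank <- fourier_bank_whitened(tiny_cyclic$pre, tiny_cyclic$side)
  rk2 <- rank_subspaces(bank, tiny_cyclic$wpairs)
  expect_lt(max(rk2$s_by_subspace), 1e-10)
})

test_that("learned banks are slower than their random initialization", {
  fx <- tiny_cyclic
  W0 <- random_orthonormal(24, seed = 2)
  fit <- train_subspace_bank(fx$wpairs, gamma = 0, W0 = W0,
                             config = optimizer_config(mu0 = 8, max_iter = 150))
  expect_lt(rank_subspaces(fit$bank, fx$wpairs)$mean_s,
            rank_subspaces(W0, fx$wpairs)$mean_s)
})

test_that("amplitude spectrum is DC-centered and Parseval-consistent", {
  side <- 11L
  g <- patchwave <- function(kx, ky, phi) {
    ii <- rep(0:(side - 1), times = side); jj <- rep(0:(side - 1), each = side)
    cos(2 * pi * (kx * ii + ky * jj) / side + phi)
  }
  v <- patchwave(2, 1, 0)
  m <- amplitude_spectrum(v, side)
  expect_identical(sum(m > 1e-8), 2L)  # two symmetric peaks
  ctr <- (side + 1) / 2
  expect_lt(m[ctr, ctr], 1e-10)        # DC-free filter: center bin zero

  set.seed(3)
  f <- rnorm(side^2)
  expect_equal(sum(amplitude_spectrum(f, side)^2), side^2 * sum(f^2),
               tolerance = 1e-8)
  expect_error(amplitude_spectrum(rnorm(10), 11), "side")
})

test_that("pair phase difference recovers planted offsets", {
  side <- 11L
  wave <- function(phi) {
    ii <- rep(0:(side - 1), times = side); jj <- rep(0:(side - 1), each = side)
    cos(2 * pi * (3 * ii + 1 * jj) / side + phi)
  }
  expect_equal(as.numeric(pair_phase_difference(wave(0), wave(pi / 2), side)),
               pi / 2, tolerance = 1e-8)
  expect_equal(as.numeric(pair_phase_difference(wave(0.4), wave(0.4), side)),
               0, tolerance = 1e-8)
  for (delta in c(0.3, 1.1, 2.6)) {
    expect_equal(as.numeric(pair_phase_difference(wave(0.2), wave(0.2 + delta), side)),
                 delta, tolerance = 1e-6)
  }
  # filters peaking at different frequencies get flagged, not raised
  wave2 <- function(phi) {
    ii <- rep(0:(side - 1), times = side); jj <- rep(0:(side - 1), each = side)
    cos(2 * pi * (1 * ii + 4 * jj) / side + phi)
  }
  ph <- pair_phase_difference(wave(0), wave2(0), side)
  expect_true(attr(ph, "flagged"))
})

test_that("fourier match score: gauge invariance, random baseline, decomposition", {
  fx <- tiny_cyclic
  bank <- fourier_bank_whitened(fx$pre, fx$side)
  expect_equal(fourier_match_score(bank, fx$side, fx$pre), 1, tolerance = 1e-10)

  # invariant under within-pair rotations and subspace permutation
  W2 <- bank$W
  set.seed(4)
  perm <- sample(bank$I)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  W2 <- W2[rows, ]
  for (i in seq_len(bank$I)) {
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    W2[c(2 * i - 1, 2 * i), ] <- R %*% W2[c(2 * i - 1, 2 * i), ]
  }
  expect_equal(fourier_match_score(filter_bank(W2, K = 2), fx$side, fx$pre), 1,
               tolerance = 1e-10)

  # random banks score well below
  rnd <- vapply(1:5, function(s)
    fourier_match_score(random_orthonormal(24, seed = 40 + s), fx$side, fx$pre),
    numeric(1))
  expect_lt(max(rnd), 0.5)

  # independent oracle: explicit double loop over principal angles
  b <- random_orthonormal(24, seed = 77)
  fb <- fourier_quadrature_basis(fx$side)
  score_oracle <- local({
    refs <- lapply(fb$pair_index, function(idx) {
      V <- filters_to_whitened_space(fx$pre, t(fb$basis[, idx]))
      qr.Q(qr(t(V)))
    })
    per <- numeric(b$I)
    for (i in seq_len(b$I)) {
      U <- qr.Q(qr(t(b$W[c(2 * i - 1, 2 * i), ])))
      best <- 0
      for (V in refs) {
        cosang <- svd(crossprod(U, V))$d
        best <- max(best, mean(cosang^2))
      }
      per[i] <- best
    }
    mean(per)
  })
  expect_equal(fourier_match_score(b, fx$side, fx$pre), score_oracle,
               tolerance = 1e-10)
})

test_that("subspace overlap is 1 for re-gauged banks and below for random", {
  b <- random_orthonormal(16, seed = 5)
  expect_equal(subspace_overlap(b, b), 1, tolerance = 1e-12)
  W2 <- b$W[c(5:16, 1:4), ]  # permute subspaces
  expect_equal(subspace_overlap(b, filter_bank(W2, K = 2)), 1, tolerance = 1e-10)
  expect_lt(subspace_overlap(b, random_orthonormal(16, seed = 6)), 0.9)
})

test_that("localization index separates point, window and global filters", {
  side <- 11L
  point <- rep(0, side^2); point[61] <- 1
  expect_identical(localization_index(point, side), 1)

  ii <- rep(0:(side - 1), times = side); jj <- rep(0:(side - 1), each = side)
  # constant-magnitude global wave (quadrature magnitude trick not needed:
  # use a wave whose squared magnitude is constant)
  glob <- exp(2i * pi * (2 * ii + jj) / side)
  expect_lt(localization_index(Mod(glob), side), 0.05)

  widths <- c(0.8, 1.5, 2.5, 4, 8)
  idx <- vapply(widths, function(w) {
    g <- exp(-((ii - 5)^2 + (jj - 5)^2) / (2 * w^2)) * cos(2 * pi * 3 * ii / side)
    localization_index(g, side)
  }, numeric(1))
  expect_true(all(diff(idx) < 0))          # wider window -> less localized
  expect_true(all(idx > 0 & idx < 1))
})

test_that("trade-off curve endpoints are exact and replication is stable", {
  fx <- tiny_cyclic
  cfg <- optimizer_config(mu0 = 8, tol = 1e-9, max_iter = 120, seed = 21)
  tc <- tradeoff_curve(fx$wpairs, gammas = c(0, 0.5, 1), config = cfg)
  expect_identical(tc$curve$perf_slow[1], 100)
  expect_identical(tc$curve$perf_sparse[3], 100)
  expect_true(all(is.finite(tc$curve$perf_slow)))

  cfg2 <- optimizer_config(mu0 = 8, tol = 1e-9, max_iter = 120, seed = 22)
  tc2 <- tradeoff_curve(fx$wpairs, gammas = c(0, 0.5, 1), config = cfg2)
  expect_lt(max(abs(tc$curve$perf_slow - tc2$curve$perf_slow)), 5)
  expect_lt(max(abs(tc$curve$perf_sparse - tc2$curve$perf_sparse)), 5)

  expect_error(tradeoff_curve(fx$wpairs, gammas = c(0, 0.5)), "endpoints")
})

test_that("curve crossing interpolates linearly", {
  g <- seq(0, 1, 0.25)
  expect_equal(slowsubspace:::curve_crossing(g, c(100, 80, 60, 40, 20),
                                             c(20, 40, 60, 80, 100)), 0.5)
  expect_equal(slowsubspace:::curve_crossing(g, c(4, 3, 2, 1, 0),
                                             c(0, 0, 0, 0, 8)),
               0.75 + 0.25 * (1 / 9))
  expect_true(is.na(slowsubspace:::curve_crossing(g, 5:1, rep(-1, 5))))
})
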