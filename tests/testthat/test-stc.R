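# SFA-derived quadratic model neurons and spike-triggered covariance.

test_that("quadratic expansion enumerates monomials then linear terms", {
  expect_identical(quadratic_expansion(c(1, 2)), c(1, 2, 4, 1, 2))
  expect_identical(quadratic_expansion(c(0, 0, 0)), rep(0, 9))

  # any quadratic form is an exact linear functional of the features
  set.seed(1)
  n <- 5L
  Q <- matrix(rnorm(n^2), n, n); Q <- (Q + t(Q)) / 2
  b <- rnorm(n)
  Z <- matrix(rnorm(200 * n), 200, n)
  truth <- rowSums((Z %*% Q) * Z) + Z %*% b
  idx <- slowsubspace:::quad_index_pairs(n)
  w <- c(ifelse(idx[, 1] == idx[, 2], Q[idx], 2 * Q[idx]), b)
  expect_equal(as.numeric(quadratic_expansion(Z) %*% w), as.numeric(truth),
               tolerance = 1e-12)

  # round trip through the coefficient mapping
  qb <- slowsubspace:::weights_to_quadratic(w, n)
  expect_equal(qb$Q, Q, tolerance = 1e-12)
  expect_equal(qb$b, b, tolerance = 1e-12)
})

test_that("quadratic SFA finds a planted invariant form", {
  # 2-D rotations leave |z|^2 exactly constant: Q = I is the slowest form
  set.seed(2)
  n <- 3000L
  z1 <- matrix(rnorm(2 * n), n, 2)
  ang <- runif(n, 0, 2 * pi)
  z2 <- cbind(cos(ang) * z1[, 1] - sin(ang) * z1[, 2],
              sin(ang) * z1[, 1] + cos(ang) * z1[, 2])
  comps <- sfa_quadratic(z1, z2, n_components = 3)
  Q1 <- comps[[1]]$Q
  # coefficient-space cosine with the planted form (identity, no linear part)
  v_found <- c(Q1[1, 1], 2 * Q1[1, 2], Q1[2, 2], comps[[1]]$b)
  v_true <- c(1, 0, 1, 0, 0)
  cosang <- abs(sum(v_found * v_true)) /
    sqrt(sum(v_found^2) * sum(v_true^2))
  expect_gt(cosang, 0.999)
  expect_lt(comps[[1]]$delta_variance, 1e-3)

  # components are decorrelated and ordered by temporal-difference variance
  r <- vapply(comps, neuron_response, numeric(n), stimuli = z1)
  cc <- stats::cor(r)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  dv <- vapply(comps, function(x) x$delta_variance, numeric(1))
  expect_true(all(diff(dv) >= -1e-12))
})

test_that("median split produces complementary rate streams", {
  neuron <- structure(list(Q = diag(2), b = c(0, 0), offset = 0,
                           delta_variance = NA, rate_scale = NA,
                           median_threshold = NA),
                      class = "quadratic_neuron")
  # hand case via a linear-only neuron on 1-feature stimuli
  lin <- structure(list(Q = matrix(0, 2, 2), b = c(1, 0), offset = 0,
                        delta_variance = NA, rate_scale = NA,
                        median_threshold = NA),
                   class = "quadratic_neuron")
  stim <- cbind(c(1, 2, 3, 4), 0)
  rt <- neuron_rates(lin, stim, rate_scale = 2)
  expect_equal(rt$excitatory, c(0, 0, 0.5, 1.5) * 2)
  expect_equal(rt$inhibitory, c(1.5, 0.5, 0, 0) * 2)
  expect_true(all(rt$excitatory * rt$inhibitory == 0))

  # constant response: both streams vanish
  rc <- neuron_rates(lin, cbind(rep(2, 10), 0), rate_scale = 1)
  expect_true(all(rc$excitatory == 0) && all(rc$inhibitory == 0))

  # calibration: mean total rate hits the target
  set.seed(3)
  stim2 <- matrix(rnorm(2000 * 2), 2000, 2)
  rt2 <- neuron_rates(neuron, stim2)
  expect_equal(mean(rt2$excitatory + rt2$inhibitory), 0.5, tolerance = 1e-12)
})

test_that("poisson counts are seeded and match their rates", {
  expect_identical(poisson_counts(rep(0, 100), seed = 4), rep(0L, 100))
  cts <- poisson_counts(rep(5, 100000), seed = 5)
  expect_identical(cts, poisson_counts(rep(5, 100000), seed = 5))
  expect_lt(abs(mean(cts) - 5), 4 * sqrt(5 / 100000))
  expect_error(poisson_counts(c(1, -1), seed = 6), "nonnegative")
})

test_that("stc matrix is symmetric, null-centered, and recovers planted spans", {
  set.seed(7)
  n <- 16L; Tn <- 20000L
  stim <- matrix(rnorm(Tn * n), Tn, n)

  # constant rate: entries within sampling error of zero
  c0 <- poisson_counts(rep(0.5, Tn), seed = 8)
  C0 <- stc_matrix(stim, c0)
  expect_identical(C0, t(C0))
  expect_lt(max(abs(C0)), 4 * sqrt(2 / sum(c0)) * 3)

  # rank-2 energy neuron: top-2 eigenvectors span the planted plane
  v <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  rate <- 0.5 * rowSums((stim %*% v)^2)
  cts <- poisson_counts(rate, seed = 9)
  C <- stc_matrix(stim, cts)
  ev <- eigen(C, symmetric = TRUE)
  U <- ev$vectors[, 1:2]
  cosang <- svd(crossprod(U, v))$d
  expect_gt(min(cosang), cos(5 * pi / 180))

  expect_error(stc_matrix(stim, rep(0, Tn)), "zero total")
})

test_that("shuffle significance: null calibration and planted detection", {
  set.seed(10)
  n <- 12L; Tn <- 6000L
  stim <- matrix(rnorm(Tn * n), Tn, n)

  # planted rank-2 excitatory energy neuron: exactly 2 significant excitatory
  v <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  rate <- 1.0 * rowSums((stim %*% v)^2)
  cts <- poisson_counts(rate, seed = 11)
  res <- stc_significance(stim, cts, n_shuffles = 100, z = 4.4, seed = 12)
  expect_identical(res$n_sig_excitatory, 2L)
  expect_identical(res$n_sig_inhibitory, 0L)

  # null neurons: significant-eigenvector rate below 1% at z = 4.4
  n_null <- 50L
  sig <- vapply(seq_len(n_null), function(k) {
    cts0 <- poisson_counts(rep(0.5, Tn), seed = 100 + k)
    r <- stc_significance(stim, cts0, n_shuffles = 50, z = 4.4, seed = 200 + k)
    r$n_sig_excitatory + r$n_sig_inhibitory
  }, integer(1))
  expect_lt(sum(sig) / (n_null * n), 0.01)

  expect_identical(
    stc_significance(stim, cts, n_shuffles = 30, z = 4.4, seed = 13)$n_sig_excitatory,
    stc_significance(stim, cts, n_shuffles = 30, z = 4.4, seed = 13)$n_sig_excitatory)
})

test_that("fourier stimulus coordinates are unit-variance projections", {
  fx <- tiny_translation
  co <- fourier_stimulus_coords(fx$pairs, 8)
  expect_identical(ncol(co$z_t), 8L)
  expect_equal(unname(apply(rbind(co$z_t, co$z_t1), 2, stats::var)),
               rep(1, 8), tolerance = 1e-10)
})
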