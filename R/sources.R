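# Synthetic subspace source models with known ground truth.
#
# Two seeded generators used for validation: a static spherical-exponential
# subspace model (the ISA generative model; known mixing, used for parameter
# recovery) and a dynamic variant in which slowness-optimal and
# sparsity-optimal subspace decompositions provably differ (used for the
# slowness-sparseness trade-off analysis, where image surrogates are
# uninformative: whitened Gaussian data look identical to the sparsity
# objective under every orthonormal bank).

#' Static spherical-exponential subspace sources
#'
#' Draws `n` samples of `I` independent 2-dimensional sources with
#' spherically symmetric exponential radial law (`radius ~ Gamma(2, rate)`,
#' uniform angle), scaled to unit coordinate variance, and mixes them with a
#' known orthonormal matrix. The mixing matrix rows are the ground-truth
#' filters that ISA should recover.
#'
#' @param I number of 2-D subspaces (total dimension `D = 2 I`).
#' @param n number of samples.
#' @param seed integer seed.
#' @param rate radial Gamma rate before scaling (default `sqrt(3)`, giving
#'   unit coordinate variance).
#' @return list with `x` (`n x D` mixed data), `mixing` (orthonormal `D x D`
#'   ground truth, a [filter_bank()]), and `sources`.
#' @export
spherical_subspace_sources <- function(I, n, seed, rate = sqrt(3)) {
  I <- check_count(I, "I"); n <- check_count(n, "n")
  D <- 2L * I
  out <- with_seed(seed, {
    radius <- matrix(stats::rgamma(n * I, shape = 2, rate = rate), n, I)
    ang <- matrix(stats::runif(n * I, 0, 2 * pi), n, I)
    S <- matrix(0, n, D)
    S[, seq(1, D, 2)] <- radius * cos(ang)
    S[, seq(2, D, 2)] <- radius * sin(ang)
    # unit variance per coordinate: E r^2 / 2 = 3 / rate^2
    S <- S / sqrt(3) * rate
    M <- random_orthonormal(D, seed = stats::runif(1, 1, 2^30))
    list(x = S %*% M$W, mixing = M, sources = S)
  })
  out
}

#' Dynamic sources with competing slowness and sparsity structure
#'
#' Generates pairs from independent 4-dimensional blocks designed so that
#' the slowest and the sparsest 2-D subspace decompositions differ. Within a
#' block with coordinates `(c1, c2, c3, c4)`, a single heavy-tailed radius
#' `rho ~ Gamma(shape, rate)` is shared by two planes: `(c1, c2) = rho *
#' (cos phi1, sin phi1)` and `(c3, c4) = rho * (cos phi2, sin phi2)`. From
#' frame t to t+1 the radius persists and each phase advances by an
#' independent uniform increment. Consequently:
#' * the plane pairing `{c1, c2}, {c3, c4}` has exactly constant energies
#'   (`rho^2`): it is the slowness optimum with inverse slowness 0;
#' * the cross pairing `{c1, c3}, {c2, c4}` has energies
#'   `rho^2 (cos^2 + cos^2)` whose square root has smaller expectation than
#'   `rho` (concavity), so it is strictly sparser than the slow pairing —
#'   but its energies fluctuate with the phases, so it is fast.
#' A weighted slowness-sparsity objective therefore faces a genuine
#' trade-off. Blocks are mixed by a known orthonormal matrix.
#'
#' @param n_blocks number of 4-D blocks (total dimension `D = 4 n_blocks`).
#' @param n_pairs number of frame pairs.
#' @param seed integer seed.
#' @param angle_range per-step phase increment range in radians (default
#'   `c(-pi, pi) / 2`).
#' @param shape,rate radial Gamma parameters (default shape 1, rate 1:
#'   exponential radius, strongly heavy-tailed energies).
#' @return a whitened-scale `pair_set` with the mixing bank in
#'   `$mixing` (slowness-optimal filters) and `$sparse_pairing` (row indices
#'   of the sparsity-optimal regrouping of the unmixed coordinates).
#' @export
competing_structure_pairs <- function(n_blocks, n_pairs, seed,
                                      angle_range = c(-pi / 2, pi / 2),
                                      shape = 1, rate = 1) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  n <- check_count(n_pairs, "n_pairs")
  D <- 4L * n_blocks
  res <- with_seed(seed, {
    rho <- matrix(stats::rgamma(n * n_blocks, shape = shape, rate = rate),
                  n, n_blocks)
    phi1 <- matrix(stats::runif(n * n_blocks, 0, 2 * pi), n, n_blocks)
    phi2 <- matrix(stats::runif(n * n_blocks, 0, 2 * pi), n, n_blocks)
    d1 <- matrix(stats::runif(n * n_blocks, angle_range[1], angle_range[2]),
                 n, n_blocks)
    d2 <- matrix(stats::runif(n * n_blocks, angle_range[1], angle_range[2]),
                 n, n_blocks)
    mk <- function(p1, p2) {
      S <- matrix(0, n, D)
      for (b in seq_len(n_blocks)) {
        cols <- 4L * (b - 1L)
        S[, cols + 1L] <- rho[, b] * cos(p1[, b])
        S[, cols + 2L] <- rho[, b] * sin(p1[, b])
        S[, cols + 3L] <- rho[, b] * cos(p2[, b])
        S[, cols + 4L] <- rho[, b] * sin(p2[, b])
      }
      S
    }
    # unit coordinate variance: E rho^2 / 2
    sc <- sqrt(shape * (shape + 1) / rate^2 / 2)
    S1 <- mk(phi1, phi2) / sc
    S2 <- mk(phi1 + d1, phi2 + d2) / sc
    M <- random_orthonormal(D, seed = stats::runif(1, 1, 2^30))
    list(S1 = S1, S2 = S2, M = M)
  })
  ps <- new_pair_set(res$S1 %*% res$M$W, res$S2 %*% res$M$W, NA, NULL, NULL)
  ps$mixing <- res$M
  ps$sparse_pairing <- as.vector(vapply(seq_len(n_blocks), function(b) {
    4L * (b - 1L) + c(1L, 3L, 2L, 4L)
  }, integer(4)))
  ps$whitened <- TRUE
  ps
}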