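# Subspace-energy model and the slowness / sparsity / mixture objectives.
#
# A filter bank is an orthonormal D x D matrix W over whitened coordinates
# whose rows are grouped into I = D/K subspaces of dimension K = 2
# (consecutive rows). The energy of subspace i at time t is
#   y_i(t) = sum_{k in subspace i} (w_k' x(t))^2 ,
# the squared radial component of the signal in that subspace: the energy
# model of a complex cell. When the filters are Fourier quadrature pairs, y
# is the power spectrum of the input.
#
# Slowness (SSA) penalizes the mean squared temporal difference of the
# energies over adjacent frames:
#   s_i = mean_t (y_i(t+1) - y_i(t))^2,   Psi_slow = mean_i s_i .
# Sparsity (ISA) is the spherical-exponential negative log-likelihood with
# constants dropped:
#   Psi_sparse = mean over (t, i) of sqrt(y_i(t)) .
# Both are minimized under W W' = I; the mixture is
#   Psi(gamma) = (1 - gamma) Psi_slow + gamma Psi_sparse .

#' Construct a filter bank
#'
#' @param W orthonormal `D x D` matrix, rows are filters in whitened
#'   coordinates; consecutive rows `(2i-1, 2i)` form subspace `i`.
#' @param K subspace dimension (default 2; `D` must be divisible by `K`).
#' @param check verify orthonormality within 1e-8 (default TRUE).
#' @return object of class `filter_bank` with fields `W`, `K`, `I`,
#'   `grouping` (subspace id per row).
#' @export
filter_bank <- function(W, K = 2, check = TRUE) {
  W <- check_matrix(W, "W")
  D <- nrow(W)
  if (ncol(W) != D) stop("`W` must be square", call. = FALSE)
  if (D %% K != 0) stop("`D` must be divisible by `K`", call. = FALSE)
  if (check) {
    err <- max(abs(tcrossprod(W) - diag(D)))
    if (err > 1e-8) {
      stop(sprintf("`W` is not orthonormal (max |WW' - I| = %.2e)", err),
           call. = FALSE)
    }
  }
  structure(list(W = W, K = as.integer(K), I = as.integer(D / K),
                 grouping = rep(seq_len(D / K), each = K)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> D = %d, %d subspaces of dimension %d\n",
              nrow(x$W), x$I, x$K))
  invisible(x)
}

as_bank <- function(W, K = 2) {
  if (inherits(W, "filter_bank")) W else filter_bank(W, K = K, check = FALSE)
}

# group indicator matrix (D x I) summing squared responses into energies
group_matrix <- function(bank) {
  G <- matrix(0, nrow(bank$W), bank$I)
  G[cbind(seq_len(nrow(bank$W)), bank$grouping)] <- 1
  G
}

#' Subspace energy outputs
#'
#' @param bank a [filter_bank()] (or bare orthonormal matrix).
#' @param x `n x D` matrix of whitened input vectors (rows are samples).
#' @return `n x I` matrix of energies `y_i(t) >= 0`; for a square orthonormal
#'   bank each row sums to the squared norm of the input.
#' @export
subspace_energies <- function(bank, x) {
  bank <- as_bank(bank)
  x <- check_matrix(x, "x")
  if (ncol(x) != ncol(bank$W)) {
    stop("input dimension does not match the filter bank", call. = FALSE)
  }
  R <- x %*% t(bank$W)
  (R * R) %*% group_matrix(bank)
}

new_objective_value <- function(gamma, slow_part, sparse_part, s_i = NULL) {
  total <- if (gamma == 0) slow_part
  else if (gamma == 1) sparse_part
  else (1 - gamma) * slow_part + gamma * sparse_part
  structure(
    list(total = total,
         gamma = gamma, slow_part = slow_part, sparse_part = sparse_part,
         per_subspace_slowness = s_i),
    class = "objective_value"
  )
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective_value> total %.6g (gamma %.3g: slow %.6g, sparse %.6g)\n",
              x$total, x$gamma, x$slow_part, x$sparse_part))
  invisible(x)
}

check_pairs <- function(pairs) {
  if (!inherits(pairs, "pair_set")) stop("`pairs` must be a pair_set", call. = FALSE)
  if (nrow(pairs$x_t) < 1) stop("empty pair set", call. = FALSE)
  pairs
}

# per-subspace inverse slowness s_i on a pair set
subspace_slowness <- function(bank, pairs) {
  y1 <- subspace_energies(bank, pairs$x_t)
  y2 <- subspace_energies(bank, pairs$x_t1)
  d <- y2 - y1
  colMeans(d * d)
}

#' Temporal-slowness (SSA) objective
#'
#' Mean over subspaces of the per-subspace inverse slowness
#' `s_i = mean_t (y_i(t+1) - y_i(t))^2`. Increases with the amount of rapid
#' energy changes; 0 means perfect invariance.
#'
#' @param bank a [filter_bank()].
#' @param pairs a whitened `pair_set`.
#' @return an `objective_value` with `slow_part`, `per_subspace_slowness`.
#' @export
ssa_objective <- function(bank, pairs) {
  bank <- as_bank(bank)
  check_pairs(pairs)
  s_i <- subspace_slowness(bank, pairs)
  new_objective_value(0, mean(s_i), NA_real_, s_i)
}

#' Analytic gradient of the SSA objective
#'
#' Row `j` (subspace `i`):
#' `(4 / (I T)) sum_t dy_i(t) [ (w_j' x_{t+1}) x_{t+1} - (w_j' x_t) x_t ]`,
#' the exact derivative of [ssa_objective()] with respect to `W` (before
#' projection onto the orthogonal group).
#'
#' @inheritParams ssa_objective
#' @return `D x D` gradient matrix.
#' @export
ssa_gradient <- function(bank, pairs) {
  bank <- as_bank(bank)
  check_pairs(pairs)
  W <- bank$W
  G <- group_matrix(bank)
  R1 <- pairs$x_t %*% t(W)
  R2 <- pairs$x_t1 %*% t(W)
  dY <- (R2 * R2) %*% G - (R1 * R1) %*% G        # T x I
  dYe <- dY[, bank$grouping, drop = FALSE]       # T x D
  Tn <- nrow(R1)
  (4 / (bank$I * Tn)) * (crossprod(dYe * R2, pairs$x_t1) -
                           crossprod(dYe * R1, pairs$x_t))
}

#' Sparsity (ISA) objective
#'
#' Spherical-exponential negative log-likelihood with scaling and
#' normalization constants dropped:
#' `Psi_sparse = (1 / (I T)) sum_t sum_i sqrt(y_i(t))`; minimized.
#'
#' @param bank a [filter_bank()].
#' @param x `n x D` matrix of whitened inputs.
#' @return an `objective_value` with `sparse_part`.
#' @export
isa_objective <- function(bank, x) {
  bank <- as_bank(bank)
  y <- subspace_energies(bank, x)
  if (nrow(y) < 1) stop("empty input", call. = FALSE)
  new_objective_value(1, NA_real_, mean(sqrt(y)))
}

#' Analytic gradient of the ISA objective
#'
#' Row `j` (subspace `i`):
#' `(1 / (I T)) sum_t (w_j' x_t) x_t / sqrt(y_i(t) + eps)`; `eps` guards the
#' non-differentiable point `y = 0`.
#'
#' @inheritParams isa_objective
#' @param eps numerical guard inside the square root (default 1e-12).
#' @return `D x D` gradient matrix.
#' @export
isa_gradient <- function(bank, x, eps = 1e-12) {
  bank <- as_bank(bank)
  x <- check_matrix(x, "x")
  G <- group_matrix(bank)
  R <- x %*% t(bank$W)
  y <- (R * R) %*% G
  inv <- 1 / sqrt(y + eps)
  Tn <- nrow(x)
  (1 / (bank$I * Tn)) * crossprod(R * inv[, bank$grouping, drop = FALSE], x)
}

#' Trade-off specification for the mixed objective
#'
#' @param gamma trade-off weight in `[0, 1]`: 0 gives pure slowness (SSA), 1
#'   pure sparsity (ISA).
#' @param alpha,logZ spherical-exponential constants; fixed at 1 and 0 (they
#'   only shift/scale the objective and are dropped).
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(gamma, alpha = 1, logZ = 0) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(gamma = gamma, alpha = alpha, logZ = logZ),
            class = "objective_spec")
}

# frames feeding the sparsity term: both members of every pair
all_frames <- function(pairs) rbind(pairs$x_t, pairs$x_t1)

#' Mixed slowness-sparsity (ISSA) objective and gradient
#'
#' `Psi = (1 - gamma) Psi_slow + gamma Psi_sparse`, with the sparsity term
#' evaluated over all frames of the pair set. `gamma = 0` reduces bit-exactly
#' to [ssa_objective()], `gamma = 1` to [isa_objective()].
#'
#' @param bank a [filter_bank()].
#' @param pairs a whitened `pair_set`.
#' @param spec an [objective_spec()] (or a bare `gamma` value).
#' @return an `objective_value`.
#' @export
mixed_objective <- function(bank, pairs, spec) {
  if (is.numeric(spec)) spec <- objective_spec(spec)
  stopifnot(inherits(spec, "objective_spec"))
  bank <- as_bank(bank)
  check_pairs(pairs)
  g <- spec$gamma
  if (g == 0) return(ssa_objective(bank, pairs))
  if (g == 1) return(isa_objective(bank, all_frames(pairs)))
  s_i <- subspace_slowness(bank, pairs)
  sparse <- isa_objective(bank, all_frames(pairs))$sparse_part
  new_objective_value(g, mean(s_i), sparse, s_i)
}

#' @rdname mixed_objective
#' @export
mixed_gradient <- function(bank, pairs, spec) {
  if (is.numeric(spec)) spec <- objective_spec(spec)
  stopifnot(inherits(spec, "objective_spec"))
  bank <- as_bank(bank)
  check_pairs(pairs)
  g <- spec$gamma
  if (g == 0) return(ssa_gradient(bank, pairs))
  if (g == 1) return(isa_gradient(bank, all_frames(pairs)))
  (1 - g) * ssa_gradient(bank, pairs) + g * isa_gradient(bank, all_frames(pairs))
}
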