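# Rosen-style gradient projection on the orthogonal group.
#
# Each iteration takes a plain gradient step W - mu * grad and projects the
# result back onto the orthogonal group by symmetric (Loewdin)
# orthogonalization, the Frobenius-closest orthonormal matrix. A backtracking
# line search halves mu until the candidate improves the objective; if no
# improving step exists within the backtracking budget the optimizer halts
# and reports convergence rather than accepting an ascent.

#' Optimizer configuration
#'
#' @param mu0 initial (and maximal) step length (default 1).
#' @param backtrack_factor multiplicative step reduction per backtrack, in
#'   (0, 1) (default 0.5).
#' @param max_backtracks line-search budget per iteration (default 30).
#' @param tol convergence threshold: relative change of the objective between
#'   accepted iterations (default 1e-8).
#' @param max_iter iteration budget (default 2000).
#' @param seed integer seed (used by [random_orthonormal()] initialization
#'   when the caller requests one).
#' @param warm_start if TRUE (default) the line search of iteration `k + 1`
#'   starts at twice the step accepted at iteration `k` (capped at `mu0`)
#'   instead of restarting at `mu0`; monotone descent is unaffected.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(mu0 = 1, backtrack_factor = 0.5,
                             max_backtracks = 30, tol = 1e-8,
                             max_iter = 2000, seed = 1L,
                             warm_start = TRUE) {
  stopifnot(mu0 > 0, backtrack_factor > 0, backtrack_factor < 1, tol > 0,
            max_backtracks >= 1, max_iter >= 1)
  structure(list(mu0 = mu0, backtrack_factor = backtrack_factor,
                 max_backtracks = as.integer(max_backtracks), tol = tol,
                 max_iter = as.integer(max_iter), seed = seed,
                 warm_start = isTRUE(warm_start)),
            class = "optimizer_config")
}

#' Random orthonormal filter matrix
#'
#' Draws a Haar-distributed (rotation-invariant) orthogonal matrix via the
#' sign-corrected QR decomposition of a Gaussian matrix. `D` must be even so
#' the rows can be grouped into 2-dimensional subspaces.
#'
#' @param D matrix dimension (even, >= 2).
#' @param seed integer seed; the same seed reproduces the matrix bit-exactly.
#' @return a [filter_bank()] with `K = 2`.
#' @export
random_orthonormal <- function(D, seed) {
  D <- check_count(D, "D", min = 2L)
  if (D %% 2L != 0L) {
    stop("`D` must be even (rows are grouped into 2-dimensional subspaces)",
         call. = FALSE)
  }
  W <- with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(D * D), D, D))
    Q <- qr.Q(qr_)
    Q * rep(sign(diag(qr.R(qr_))), each = D)
  })
  filter_bank(t(W), K = 2, check = FALSE)
}

#' Symmetric (Loewdin) orthogonalization
#'
#' Projects a nonsingular square matrix onto the orthogonal group:
#' `M (M' M)^(-1/2)`, the closest orthonormal matrix in Frobenius norm
#' (the orthogonal polar factor). The inverse square root is computed from
#' the symmetric eigendecomposition of `M' M` with an eigenvalue floor.
#'
#' @param M nonsingular square numeric matrix.
#' @param floor_eig eigenvalue floor for `M' M` (default 1e-12 relative to
#'   the largest eigenvalue).
#' @return orthonormal matrix of the same shape.
#' @export
symmetric_orthogonalize <- function(M, floor_eig = 1e-12) {
  M <- check_matrix(M, "M")
  if (nrow(M) != ncol(M)) stop("`M` must be square", call. = FALSE)
  ev <- eigen(crossprod(M), symmetric = TRUE)
  smin <- sqrt(max(ev$values[length(ev$values)], 0))
  if (smin^2 <= floor_eig * ev$values[1]) {
    stop(sprintf("`M` is numerically singular (smallest singular value %.3e)",
                 smin), call. = FALSE)
  }
  M %*% (ev$vectors %*% (t(ev$vectors) / sqrt(ev$values)))
}

#' Gradient projection on the orthogonal group
#'
#' Minimizes `objective(W)` over orthonormal `W`: each iteration forms the
#' candidate `symmetric_orthogonalize(W - mu * gradient(W))` and backtracks
#' `mu` until the candidate's objective is smaller than the current one.
#' Terminates when the relative objective change falls below `config$tol`,
#' when no improving step is found, or at `config$max_iter`.
#'
#' @param objective function `(W_matrix) -> scalar` objective value.
#' @param gradient function `(W_matrix) -> D x D` gradient matrix.
#' @param W0 initial [filter_bank()] (or orthonormal matrix).
#' @param config an [optimizer_config()].
#' @param verbose print one line per iteration (default FALSE).
#' @return list with `bank` (final `filter_bank`) and `trace` (class
#'   `optimization_trace`: `objective_per_iteration` over accepted iterations
#'   including the initial value, `accepted_step_lengths`, `n_iterations`,
#'   `converged`).
#' @export
optimize_filters <- function(objective, gradient, W0, config = optimizer_config(),
                             verbose = FALSE) {
  bank0 <- as_bank(W0)
  W <- bank0$W
  f <- objective(W)
  if (!is.finite(f)) stop("objective is non-finite at the initial point", call. = FALSE)
  obj_trace <- f
  steps <- numeric(0)
  mu_start <- config$mu0
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    G <- gradient(W)
    if (!all(is.finite(G))) {
      stop(sprintf("non-finite gradient at iteration %d", iter), call. = FALSE)
    }
    mu <- mu_start
    accepted <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      # a step so large that W - mu G is numerically singular cannot be
      # projected; treat it as a failed line-search trial
      cand <- tryCatch(symmetric_orthogonalize(W - mu * G),
                       error = function(e) NULL)
      if (is.null(cand)) {
        mu <- mu * config$backtrack_factor
        next
      }
      fc <- objective(cand)
      if (!is.finite(fc)) {
        stop(sprintf("non-finite objective at iteration %d", iter), call. = FALSE)
      }
      if (fc < f) {
        accepted <- TRUE
        break
      }
      mu <- mu * config$backtrack_factor
    }
    if (!accepted) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    W <- cand
    delta <- f - fc
    f <- fc
    obj_trace <- c(obj_trace, f)
    steps <- c(steps, mu)
    if (config$warm_start) mu_start <- min(config$mu0, 2 * mu)
    if (verbose) {
      message(sprintf("iter %4d  obj %.8e  step %.3e", iter, f, mu))
    }
    if (delta < config$tol * max(abs(f), .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  list(
    bank = filter_bank(W, K = bank0$K, check = FALSE),
    trace = structure(
      list(objective_per_iteration = obj_trace,
           accepted_step_lengths = steps,
           n_iterations = iter, converged = converged),
      class = "optimization_trace"
    )
  )
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("<optimization_trace> %d iterations, objective %.6g -> %.6g, %s\n",
              x$n_iterations,
              x$objective_per_iteration[1],
              x$objective_per_iteration[length(x$objective_per_iteration)],
              if (x$converged) "converged" else "iteration budget reached"))
  invisible(x)
}

#' Train a filter bank on a pair set
#'
#' Convenience wrapper wiring [mixed_objective()] / [mixed_gradient()] into
#' [optimize_filters()]: SSA for `gamma = 0`, ISA for `gamma = 1`, the ISSA
#' mixture in between. For the pure slowness objective an optional
#' block-refinement stage ([refine_subspace_blocks()]) follows the gradient
#' projection: full-bank descent can stall at configurations where two
#' subspaces each span half of two invariant planes, a genuine local optimum
#' that targeted re-optimization of the offending 4-dimensional blocks
#' resolves. Refinement steps are accepted only when they lower the
#' objective, so descent remains monotone.
#'
#' @param pairs a whitened `pair_set`.
#' @param gamma trade-off weight in `[0, 1]`.
#' @param W0 initial bank; default `random_orthonormal(D, config$seed)`.
#' @param config an [optimizer_config()].
#' @param refine number of block-refinement rounds after convergence of the
#'   full-bank descent (default 0: plain gradient projection only).
#' @param verbose passed to [optimize_filters()].
#' @return list with `bank` and `trace` (see [optimize_filters()]).
#' @export
train_subspace_bank <- function(pairs, gamma = 0, W0 = NULL,
                                config = optimizer_config(), refine = 0,
                                verbose = FALSE) {
  check_pairs(pairs)
  spec <- objective_spec(gamma)
  D <- ncol(pairs$x_t)
  if (is.null(W0)) W0 <- random_orthonormal(D, config$seed)
  bank0 <- as_bank(W0)
  K <- bank0$K
  frames <- if (gamma > 0) all_frames(pairs) else NULL
  obj <- function(W) {
    b <- filter_bank(W, K = K, check = FALSE)
    if (gamma == 0) return(ssa_objective(b, pairs)$total)
    if (gamma == 1) return(isa_objective(b, frames)$total)
    (1 - gamma) * ssa_objective(b, pairs)$total +
      gamma * isa_objective(b, frames)$total
  }
  grad <- function(W) {
    b <- filter_bank(W, K = K, check = FALSE)
    if (gamma == 0) return(ssa_gradient(b, pairs))
    if (gamma == 1) return(isa_gradient(b, frames))
    (1 - gamma) * ssa_gradient(b, pairs) + gamma * isa_gradient(b, frames)
  }
  fit <- optimize_filters(obj, grad, bank0, config, verbose = verbose)
  if (refine > 0) {
    for (round in seq_len(refine)) {
      ref <- refine_subspace_blocks(fit$bank, pairs, config, gamma = gamma,
                                    seed = config$seed + 7919L * round)
      if (!ref$improved) break
      polish <- optimize_filters(obj, grad, ref$bank, config)
      fit$bank <- polish$bank
      fit$trace$objective_per_iteration <- c(
        fit$trace$objective_per_iteration,
        polish$trace$objective_per_iteration[-1]
      )
      fit$trace$n_iterations <- fit$trace$n_iterations +
        polish$trace$n_iterations
      fit$trace$converged <- polish$trace$converged
    }
  }
  fit
}

#' Re-optimize entangled subspace pairs within their joint span
#'
#' Full-bank gradient projection under the slowness objective can converge to
#' configurations in which two subspaces each carry half of two invariant
#' planes; the joint 4-dimensional span is correct but its split is not, and
#' the split is a local optimum of the full problem. Such subspaces are
#' recognizable by their large inverse slowness. This pass re-optimizes the
#' 4x4 rotation inside the joint span of candidate subspace pairs from
#' several seeded random restarts, keeping a re-split only when it lowers the
#' per-block slowness; the remaining subspaces (and the overall span) are
#' untouched, so the full objective can only decrease.
#'
#' @param bank a [filter_bank()] with `K = 2`.
#' @param pairs whitened `pair_set` (the training data).
#' @param config an [optimizer_config()] for the 4x4 sub-problems.
#' @param seed integer seed for the restarts.
#' @param gamma trade-off weight of the objective being refined; both the
#'   slowness and the sparsity term decompose over subspaces, so the block
#'   sub-problem optimizes the same functional (default 0).
#' @param s_floor absolute inverse-slowness floor: for the pure slowness
#'   objective on large banks, only subspaces with `s_i > s_floor` and
#'   `s_i > 10 * median(s)` are candidates (default 1e-4); for small banks
#'   every pair is a candidate. When `gamma > 0`, entangled blocks are not
#'   slowness outliers; candidate pairs are instead those whose subspace
#'   energies correlate (shared radial structure — the independence
#'   criterion itself), above `cor_floor`.
#' @param cor_floor energy-correlation threshold for the `gamma > 0`
#'   candidate rule (default 0.05, well above the `1/sqrt(T)` noise floor at
#'   the package's sample sizes).
#' @param n_restarts random restarts per block (default 8; the 4x4 sub-problem
#'   lands in its own entangled optimum in roughly half of random starts).
#' @param max_candidates at most this many worst subspaces are considered
#'   (default 12).
#' @return list with `bank` (possibly improved) and `improved` (logical).
#' @export
refine_subspace_blocks <- function(bank, pairs, config = optimizer_config(),
                                   seed = 1L, gamma = 0, s_floor = 1e-4,
                                   n_restarts = 8, max_candidates = 12,
                                   cor_floor = 0.05) {
  bank <- as_bank(bank)
  stopifnot(bank$K == 2L)
  W <- bank$W
  if (gamma > 0) {
    # entangled subspaces share radial structure: their energies correlate
    Y <- subspace_energies(bank, all_frames(pairs))
    EC <- abs(stats::cor(Y))
    hits <- which(upper.tri(EC) & EC > cor_floor, arr.ind = TRUE)
    if (nrow(hits) == 0) return(list(bank = bank, improved = FALSE))
    hits <- hits[order(EC[hits], decreasing = TRUE), , drop = FALSE]
    hits <- hits[seq_len(min(nrow(hits), 4L * max_candidates)), , drop = FALSE]
    combos <- t(hits)
  } else if (bank$I <= 16L) {
    combos <- utils::combn(seq_len(bank$I), 2)
  } else {
    s <- subspace_slowness(bank, pairs)
    bad <- which(s > max(s_floor, 10 * stats::median(s)))
    if (length(bad) < 2) return(list(bank = bank, improved = FALSE))
    bad <- bad[order(s[bad], decreasing = TRUE)]
    bad <- bad[seq_len(min(length(bad), max_candidates))]
    combos <- utils::combn(sort(bad), 2)
  }
  R1 <- pairs$x_t %*% t(W)
  R2 <- pairs$x_t1 %*% t(W)
  sub_cfg <- optimizer_config(mu0 = config$mu0, tol = config$tol,
                              max_iter = min(config$max_iter, 300L),
                              seed = seed)
  improved <- FALSE
  restart_seeds <- with_seed(seed, sample.int(2^30, n_restarts * ncol(combos)))
  sk <- 0L
  for (cc in seq_len(ncol(combos))) {
    i <- combos[1, cc]; j <- combos[2, cc]
    cols <- c(2L * i - 1L, 2L * i, 2L * j - 1L, 2L * j)
    block_pairs <- new_pair_set(R1[, cols, drop = FALSE],
                                R2[, cols, drop = FALSE],
                                NA, pairs$process, NULL)
    cur <- mixed_objective(filter_bank(diag(4), check = FALSE),
                           block_pairs, gamma)$total
    best_q <- NULL
    best <- cur
    for (r in seq_len(n_restarts)) {
      sk <- sk + 1L
      sub <- train_subspace_bank(block_pairs, gamma = gamma,
                                 W0 = random_orthonormal(4, restart_seeds[sk]),
                                 config = sub_cfg)
      val <- utils::tail(sub$trace$objective_per_iteration, 1)
      if (val < best - 1e-15) {
        best <- val
        best_q <- sub$bank$W
      }
    }
    if (!is.null(best_q)) {
      W[cols, ] <- best_q %*% W[cols, , drop = FALSE]
      R1[, cols] <- R1[, cols, drop = FALSE] %*% t(best_q)
      R2[, cols] <- R2[, cols, drop = FALSE] %*% t(best_q)
      improved <- TRUE
    }
  }
  list(bank = filter_bank(W, K = 2, check = FALSE), improved = improved)
}
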