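# Evaluation of learned banks: per-subspace slowness ordering, amplitude
# spectra, quadrature-phase statistics, Fourier-recovery and localization
# scores, and the slowness-sparseness trade-off curve.

#' Rank subspaces by slowness
#'
#' Computes the per-subspace inverse slowness `s_i` on a pair set and orders
#' the subspaces ascending (slowest first), ties broken by original index.
#'
#' @param bank a [filter_bank()].
#' @param pairs a whitened `pair_set`.
#' @return object of class `slowness_report`: `s_by_subspace` (sorted
#'   ascending), `subspace_order` (permutation of original indices),
#'   `s_unsorted`, `mean_s`.
#' @export
rank_subspaces <- function(bank, pairs) {
  bank <- as_bank(bank)
  s <- subspace_slowness(bank, check_pairs(pairs))
  ord <- order(s, seq_along(s))
  structure(
    list(s_by_subspace = s[ord], subspace_order = ord,
         s_unsorted = s, mean_s = mean(s)),
    class = "slowness_report"
  )
}

#' @export
print.slowness_report <- function(x, ...) {
  cat(sprintf("<slowness_report> %d subspaces, mean s = %.6g, range [%.3g, %.3g]\n",
              length(x$s_by_subspace), x$mean_s,
              x$s_by_subspace[1], x$s_by_subspace[length(x$s_by_subspace)]))
  invisible(x)
}

#' Amplitude spectrum of a pixel-space filter
#'
#' 2-D DFT magnitude of the filter, quadrant-shifted so the DC component sits
#' at the center of the array.
#'
#' @param filter numeric vector of length `side^2` (column-major).
#' @param side patch side in pixels.
#' @return `side x side` matrix of DFT magnitudes, DC centered.
#' @export
amplitude_spectrum <- function(filter, side) {
  if (length(filter) != side^2) {
    stop("`filter` length must be side^2", call. = FALSE)
  }
  m <- Mod(stats::fft(matrix(filter, side, side)))
  sh <- function(s) c((floor(s / 2) + 2):s, 1:(floor(s / 2) + 1))
  m[sh(side), sh(side)]
}

# principal value of an angle difference folded into [0, pi]
fold_angle <- function(a) abs(atan2(sin(a), cos(a)))

#' Phase difference of a subspace filter pair
#'
#' Locates the dominant frequency bin shared by the two filters (the peak of
#' the product of their DFT magnitude spectra) and returns the absolute
#' principal-value phase difference at that bin, in `[0, pi]`. Quadrature
#' pairs (sine/cosine at one frequency) give `pi/2`.
#'
#' If the dominant bin carries less than `min_peak_fraction` of either
#' filter's own peak power, the estimate is flagged (attribute `flagged`)
#' rather than raised as an error.
#'
#' @param v1,v2 pixel-space filter vectors of length `side^2`.
#' @param side patch side.
#' @param min_peak_fraction consistency threshold (default 0.25).
#' @return phase difference in radians with attribute `flagged` (logical) and
#'   `bin` (the dominant frequency bin, 1-based DFT index pair).
#' @export
pair_phase_difference <- function(v1, v2, side, min_peak_fraction = 0.25) {
  stopifnot(length(v1) == side^2, length(v2) == side^2,
            any(v1 != 0), any(v2 != 0))
  F1 <- stats::fft(matrix(v1, side, side))
  F2 <- stats::fft(matrix(v2, side, side))
  p1 <- Mod(F1)^2; p2 <- Mod(F2)^2
  prod <- p1 * p2
  prod[1, 1] <- 0  # ignore DC
  k <- arrayInd(which.max(prod), dim(prod))
  flagged <- p1[k] < min_peak_fraction * max(p1) ||
    p2[k] < min_peak_fraction * max(p2)
  d <- fold_angle(Arg(F1[k]) - Arg(F2[k]))
  structure(d, flagged = flagged, bin = as.integer(k))
}

# orthonormalize the rows of a K x D matrix (within-subspace frame)
orthonormal_rows <- function(M) {
  s <- svd(t(M))
  t(s$u %*% t(s$v))[seq_len(nrow(M)), , drop = FALSE]
}

# mean squared principal-angle cosine between the row spans of two K x D
# matrices with orthonormal rows
subspace_affinity <- function(U, V) {
  d <- svd(tcrossprod(U, V))$d
  mean(pmin(d, 1)^2)
}

# split a bank into a list of orthonormalized K x D subspace frames
bank_frames <- function(bank) {
  bank <- as_bank(bank)
  lapply(seq_len(bank$I), function(i) {
    M <- bank$W[bank$grouping == i, , drop = FALSE]
    orthonormal_rows(M)
  })
}

#' Overlap between two filter banks
#'
#' Mean over the subspaces of `bank_a` of the largest mean squared
#' principal-angle cosine against any subspace of `bank_b`. Invariant to
#' rotations within subspaces and to subspace permutation; 1 means the two
#' banks span identical subspace decompositions.
#'
#' @param bank_a,bank_b [filter_bank()]s over the same space.
#' @return score in `[0, 1]`.
#' @export
subspace_overlap <- function(bank_a, bank_b) {
  fa <- bank_frames(bank_a)
  fb <- bank_frames(bank_b)
  mean(vapply(fa, function(U) {
    max(vapply(fb, function(V) subspace_affinity(U, V), numeric(1)))
  }, numeric(1)))
}

#' Fourier-basis recovery score
#'
#' Mean over learned subspaces of the largest mean squared principal-angle
#' cosine against any DFT quadrature-pair subspace. When a preprocessor is
#' given, the reference quadrature pairs are first mapped into the whitened
#' learning coordinates (the representation-equivalent subspaces). 1 means
#' the bank is the Fourier quadrature basis up to within-pair rotations and
#' subspace permutation.
#'
#' @param bank a [filter_bank()] (whitened coordinates if `preproc` given,
#'   pixel-space AC coordinates otherwise).
#' @param side patch side in pixels.
#' @param preproc optional [fit_preprocessor()] result used to express the
#'   Fourier pairs in whitened coordinates.
#' @return score in `[0, 1]`.
#' @export
fourier_match_score <- function(bank, side, preproc = NULL) {
  bank <- as_bank(bank)
  fb <- fourier_quadrature_basis(side)
  refs <- lapply(fb$pair_index, function(idx) {
    V <- t(fb$basis[, idx, drop = FALSE])  # 2 x side^2 pixel-space pair
    if (!is.null(preproc)) V <- filters_to_whitened_space(preproc, V)
    orthonormal_rows(V)
  })
  frames <- bank_frames(bank)
  mean(vapply(frames, function(U) {
    max(vapply(refs, function(V) subspace_affinity(U, V), numeric(1)))
  }, numeric(1)))
}

#' Spatial localization index of a filter
#'
#' One minus the normalized spatial entropy of the filter's energy map
#' (squared pixel values normalized to sum 1): 1 for a single-pixel
#' indicator, near 0 for a constant-magnitude global wave.
#'
#' @param filter pixel-space filter vector (nonzero).
#' @param side patch side (`length(filter) == side^2`).
#' @return index in `[0, 1]`.
#' @export
localization_index <- function(filter, side) {
  stopifnot(length(filter) == side^2, any(filter != 0))
  e <- filter^2
  e <- e / sum(e)
  nz <- e > 0
  H <- -sum(e[nz] * log(e[nz]))
  1 - H / log(side^2)
}

#' Quadrature-phase and localization summary of a learned bank
#'
#' Projects a whitened bank to pixel space and computes, per subspace, the
#' pair phase difference, and per filter the localization index; combined
#' with the slowness ranking this is the full per-subspace report.
#'
#' @param bank a [filter_bank()] in whitened coordinates.
#' @param preproc the [fit_preprocessor()] used for training.
#' @param pairs whitened `pair_set` used to rank the subspaces.
#' @param side patch side in pixels.
#' @return a `data.frame` with one row per subspace: `subspace` (original
#'   index), `s` (inverse slowness, ascending), `phase_diff` (radians),
#'   `phase_flagged`, `loc_index_1`, `loc_index_2`.
#' @export
subspace_report <- function(bank, preproc, pairs, side) {
  bank <- as_bank(bank)
  rk <- rank_subspaces(bank, pairs)
  V <- filters_to_pixel_space(preproc, bank$W)
  rows <- lapply(seq_along(rk$subspace_order), function(r) {
    i <- rk$subspace_order[r]
    j <- which(bank$grouping == i)
    ph <- pair_phase_difference(V[j[1], ], V[j[2], ], side)
    data.frame(subspace = i, s = rk$s_by_subspace[r],
               phase_diff = as.numeric(ph),
               phase_flagged = attr(ph, "flagged"),
               loc_index_1 = localization_index(V[j[1], ], side),
               loc_index_2 = localization_index(V[j[2], ], side))
  })
  do.call(rbind, rows)
}

#' Slowness-sparseness trade-off curve
#'
#' Optimizes the mixed objective over a grid of trade-off weights `gamma`
#' from a shared random initialization and reports, per `gamma`, the
#' performance with respect to each objective as a percentage of the maximal
#' achievable gain:
#' `perf_slow(gamma) = 100 * (Psi_slow(W_rand) - Psi_slow(W_gamma)) /
#'  (Psi_slow(W_rand) - Psi_slow(W_0))`, and analogously `perf_sparse`
#' against the pure-ISA endpoint. The shared random start anchors the
#' baseline, so the pure endpoint of each objective scores exactly 100%.
#' The break-even `gamma` where the two curves cross is located by linear
#' interpolation between grid points.
#'
#' @param pairs whitened `pair_set`.
#' @param gammas grid in `[0, 1]` including both endpoints (default
#'   `seq(0, 1, 0.1)`).
#' @param config an [optimizer_config()]; `config$seed` fixes the shared
#'   initialization.
#' @return object of class `tradeoff_curve`: data.frame `curve` with columns
#'   `gamma`, `perf_slow`, `perf_sparse`, `psi_slow`, `psi_sparse`,
#'   `converged`, `failed`; `break_even` (interpolated crossing);
#'   `banks` (list of `filter_bank` per gamma); `baseline` (random-start
#'   objective values).
#' @export
tradeoff_curve <- function(pairs, gammas = seq(0, 1, by = 0.1),
                           config = optimizer_config()) {
  check_pairs(pairs)
  gammas <- sort(unique(as.numeric(gammas)))
  if (gammas[1] != 0 || gammas[length(gammas)] != 1) {
    stop("`gammas` must include both endpoints 0 and 1", call. = FALSE)
  }
  D <- ncol(pairs$x_t)
  W0 <- random_orthonormal(D, config$seed)
  frames <- all_frames(pairs)
  slow0 <- ssa_objective(W0, pairs)$total
  sparse0 <- isa_objective(W0, frames)$total
  banks <- vector("list", length(gammas))
  slow_g <- sparse_g <- rep(NA_real_, length(gammas))
  conv <- failed <- logical(length(gammas))
  for (k in seq_along(gammas)) {
    fit <- tryCatch(
      train_subspace_bank(pairs, gamma = gammas[k], W0 = W0, config = config),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed[k] <- TRUE
      warning(sprintf("optimization failed at gamma = %g: %s",
                      gammas[k], conditionMessage(fit)), call. = FALSE)
      next
    }
    banks[[k]] <- fit$bank
    conv[k] <- fit$trace$converged
    slow_g[k] <- ssa_objective(fit$bank, pairs)$total
    sparse_g[k] <- isa_objective(fit$bank, frames)$total
  }
  # ratio first: x / x is exactly 1, so the pure endpoints are exactly 100
  perf_slow <- 100 * ((slow0 - slow_g) / (slow0 - slow_g[1]))
  perf_sparse <- 100 * ((sparse0 - sparse_g) / (sparse0 - sparse_g[length(gammas)]))
  curve <- data.frame(gamma = gammas, perf_slow = perf_slow,
                      perf_sparse = perf_sparse,
                      psi_slow = slow_g, psi_sparse = sparse_g,
                      converged = conv, failed = failed)
  structure(
    list(curve = curve,
         break_even = curve_crossing(gammas, perf_slow, perf_sparse),
         banks = banks,
         baseline = c(psi_slow = slow0, psi_sparse = sparse0)),
    class = "tradeoff_curve"
  )
}

# gamma where two piecewise-linear curves cross (first sign change of the
# difference), by linear interpolation; NA if they never cross
curve_crossing <- function(g, a, b) {
  d <- a - b
  ok <- is.finite(d)
  g <- g[ok]; d <- d[ok]
  if (length(d) < 2) return(NA_real_)
  s <- which(d[-length(d)] * d[-1] <= 0)
  if (length(s) == 0) return(NA_real_)
  k <- s[1]
  if (d[k] == d[k + 1]) return(g[k])
  g[k] + (g[k + 1] - g[k]) * d[k] / (d[k] - d[k + 1])
}

#' @export
print.tradeoff_curve <- function(x, ...) {
  cat(sprintf("<tradeoff_curve> %d gamma points, break-even gamma = %s\n",
              nrow(x$curve), format(x$break_even, digits = 3)))
  print(x$curve[, c("gamma", "perf_slow", "perf_sparse")], row.names = FALSE)
  invisible(x)
}

#' Plot a mosaic of pixel-space filters
#'
#' Arranges filters (rows of `V`) as grayscale tiles, subspace pairs
#' adjacent, in reading order; the standard way to inspect a learned bank.
#'
#' @param V matrix of pixel-space filters (one per row, length `side^2`), or
#'   a list of frame matrices for disc-masked filters.
#' @param side patch side.
#' @param ncol_tiles tiles per row (default 12).
#' @param file optional PNG path; when given the mosaic is written there.
#' @return invisibly, the mosaic matrix.
#' @export
plot_filter_mosaic <- function(V, side, ncol_tiles = 12, file = NULL) {
  n <- nrow(V)
  nrow_tiles <- ceiling(n / ncol_tiles)
  pad <- 1
  mos <- matrix(NA_real_,
                nrow_tiles * (side + pad) + pad,
                ncol_tiles * (side + pad) + pad)
  for (k in seq_len(n)) {
    r <- (k - 1) %/% ncol_tiles
    c <- (k - 1) %% ncol_tiles
    tile <- matrix(V[k, ], side, side)
    tile <- tile / max(abs(tile))
    mos[r * (side + pad) + pad + seq_len(side),
        c * (side + pad) + pad + seq_len(side)] <- tile
  }
  if (!is.null(file)) {
    grDevices::png(file, width = ncol(mos) * 6, height = nrow(mos) * 6)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(t(mos[rev(seq_len(nrow(mos))), ]), axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), zlim = c(-1, 1),
                  useRaster = TRUE)
  invisible(mos)
}
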