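# DC projection and symmetric (ZCA-style) whitening.
#
# Patches are reduced to their 120 AC components by projecting off the
# constant (DC) vector, expressed in a fixed deterministic orthonormal AC
# basis, and whitened with the symmetric inverse square root of the AC
# covariance. All learning happens in the whitened coordinates; learned
# filters are projected back to pixel space for visualization.

# deterministic orthonormal basis of the complement of the constant vector:
# columns 2..D of the Householder reflector exchanging e1 and 1/sqrt(D)
ac_basis_matrix <- function(D) {
  u <- rep(1 / sqrt(D), D)
  v <- u
  v[1] <- v[1] - 1
  v <- v / sqrt(sum(v^2))
  H <- diag(D) - 2 * tcrossprod(v)
  H[, -1, drop = FALSE]
}

# project a D x D pixel covariance onto the circulant (torus-stationary)
# class by averaging entries over torus offsets; D = side^2, column-major
circulant_project <- function(C, side) {
  stopifnot(nrow(C) == side^2, ncol(C) == side^2)
  ii <- rep(0:(side - 1), times = side)
  jj <- rep(0:(side - 1), each = side)
  di <- outer(ii, ii, function(a, b) (b - a) %% side)
  dj <- outer(jj, jj, function(a, b) (b - a) %% side)
  code <- di + side * dj + 1L
  avg <- as.vector(rowsum(as.vector(C), as.vector(code))) /
    as.vector(table(as.vector(code)))
  Cb <- matrix(avg[code], side^2, side^2)
  (Cb + t(Cb)) / 2
}

#' Fit the DC-projection + symmetric whitening preprocessor
#'
#' Removes each patch's own mean (projection off the constant vector),
#' expresses the residual in a fixed orthonormal AC basis, and computes the
#' symmetric whitening transform `C^(-1/2)` from the eigendecomposition of
#' the AC-coordinate covariance. No low-pass filtering or dimensionality
#' reduction is applied: an `11 x 11` patch keeps all 120 AC components.
#'
#' @param x_all `n x D` matrix of training patch vectors (n >= 10 D).
#' @param circulant_side if the training patches are stationary on a torus
#'   (the cyclic-shift dataset), give the patch side here: the covariance is
#'   then estimated within the circulant class (averaging the autocovariance
#'   over torus offsets), which preserves the exact rotation symmetry of
#'   cyclic shifts in whitened coordinates. Default `NULL` (unconstrained
#'   sample covariance).
#' @param reg diagonal regularization as a fraction of the mean eigenvalue
#'   (default 1e-10), guarding near-degenerate directions.
#' @return object of class `preprocessor` with fields `D_pixel`, `D_ac`,
#'   `ac_basis`, `whitener`, `dewhitener`, `mean_vector`, `eigenvalues`.
#' @export
fit_preprocessor <- function(x_all, circulant_side = NULL, reg = 1e-10) {
  x_all <- check_matrix(x_all, "x_all")
  D <- ncol(x_all)
  if (nrow(x_all) < 10 * D) {
    stop(sprintf("need at least %d training vectors for D = %d", 10 * D, D),
         call. = FALSE)
  }
  B <- ac_basis_matrix(D)
  xc <- x_all - rowMeans(x_all)
  if (!is.null(circulant_side)) {
    side <- check_count(circulant_side, "circulant_side", min = 2L)
    if (side^2 != D) stop("`circulant_side`^2 must equal ncol(x_all)", call. = FALSE)
    Cpix <- stats::cov(xc)
    Cac <- crossprod(B, circulant_project(Cpix, side)) %*% B
  } else {
    Cac <- stats::cov(xc %*% B)
  }
  Cac <- (Cac + t(Cac)) / 2
  ev <- eigen(Cac, symmetric = TRUE)
  n_def <- sum(ev$values < 1e-12 * max(ev$values))
  if (n_def > 0) {
    stop(sprintf("AC covariance is rank-deficient: %d eigenvalue(s) below threshold",
                 n_def), call. = FALSE)
  }
  vals <- ev$values + reg * mean(ev$values)
  V <- ev$vectors
  whitener <- V %*% (t(V) / sqrt(vals))
  dewhitener <- V %*% (t(V) * sqrt(vals))
  structure(
    list(D_pixel = D, D_ac = D - 1L, ac_basis = B,
         whitener = whitener, dewhitener = dewhitener,
         mean_vector = colMeans(x_all), eigenvalues = vals,
         circulant_side = circulant_side),
    class = "preprocessor"
  )
}

#' @export
print.preprocessor <- function(x, ...) {
  cat(sprintf("<preprocessor> %d px -> %d AC dims, eigenvalues [%.3g, %.3g]%s\n",
              x$D_pixel, x$D_ac, min(x$eigenvalues), max(x$eigenvalues),
              if (!is.null(x$circulant_side)) ", circulant covariance" else ""))
  invisible(x)
}

#' Apply the preprocessor
#'
#' Maps pixel vectors to whitened AC coordinates:
#' `z = whitener %*% t(ac_basis) %*% (x - per-patch mean)`. The map is linear
#' and is applied row-wise to matrices.
#'
#' @param p a [fit_preprocessor()] result.
#' @param x numeric vector of length `D_pixel`, or `n x D_pixel` matrix.
#' @return whitened coordinates (vector of length `D_ac`, or `n x D_ac`).
#' @export
apply_preprocessor <- function(p, x) {
  stopifnot(inherits(p, "preprocessor"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != p$D_pixel) {
    stop(sprintf("input has %d columns, preprocessor expects %d",
                 ncol(x), p$D_pixel), call. = FALSE)
  }
  z <- ((x - rowMeans(x)) %*% p$ac_basis) %*% p$whitener
  if (vec) drop(z) else z
}

#' Apply a preprocessor to both frames of a pair set
#'
#' @param p a `preprocessor`.
#' @param pairs a `pair_set` in pixel space.
#' @return a `pair_set` in whitened coordinates.
#' @export
preprocess_pairs <- function(p, pairs) {
  stopifnot(inherits(pairs, "pair_set"))
  out <- pairs
  out$x_t <- apply_preprocessor(p, pairs$x_t)
  out$x_t1 <- apply_preprocessor(p, pairs$x_t1)
  out$whitened <- TRUE
  out
}

#' Project filters from whitened coordinates back to pixel space
#'
#' Returns, for every filter row `w` of `W`, the pixel-space vector `v` with
#' `v' x == w' apply_preprocessor(p, x)` for all patches `x`, i.e.
#' `v = ac_basis %*% whitener %*% w`. All returned filters have zero mean
#' (they live in the AC subspace).
#'
#' @param p a `preprocessor`.
#' @param W filter matrix with rows in whitened coordinates (e.g.
#'   `filter_bank$W`), or a `filter_bank`.
#' @return matrix with one pixel-space filter per row (`D_pixel` columns).
#' @export
filters_to_pixel_space <- function(p, W) {
  stopifnot(inherits(p, "preprocessor"))
  if (inherits(W, "filter_bank")) W <- W$W
  W <- check_matrix(W, "W")
  if (ncol(W) != p$D_ac) {
    stop(sprintf("filters have %d columns, preprocessor has %d AC dims",
                 ncol(W), p$D_ac), call. = FALSE)
  }
  (W %*% p$whitener) %*% t(p$ac_basis)
}

#' Map pixel-space filters into whitened coordinates
#'
#' Inverse-direction companion of [filters_to_pixel_space()]: for a
#' pixel-space filter `v` (zero mean), returns `w` with
#' `w' apply_preprocessor(p, x) == v' x`, i.e.
#' `w = dewhitener %*% t(ac_basis) %*% v`. Used to express reference banks
#' (e.g. the Fourier quadrature basis) in the learning coordinates.
#'
#' @param p a `preprocessor`.
#' @param V matrix with one pixel-space filter per row.
#' @return matrix with one whitened-coordinate filter per row.
#' @export
filters_to_whitened_space <- function(p, V) {
  stopifnot(inherits(p, "preprocessor"))
  V <- check_matrix(V, "V")
  if (ncol(V) != p$D_pixel) stop("filter length must equal D_pixel", call. = FALSE)
  (V %*% p$ac_basis) %*% p$dewhitener
}

#' Serialize / restore a preprocessor as plain text
#'
#' Writes the preprocessor matrices to a JSON file (full double precision)
#' and restores them; round-trips bit-exactly.
#'
#' @param p a `preprocessor`.
#' @param path file path.
#' @return `read_preprocessor` returns the restored `preprocessor`.
#' @export
write_preprocessor <- function(p, path) {
  stopifnot(inherits(p, "preprocessor"))
  obj <- list(D_pixel = p$D_pixel, D_ac = p$D_ac,
              ac_basis = p$ac_basis, whitener = p$whitener,
              dewhitener = p$dewhitener, mean_vector = p$mean_vector,
              eigenvalues = p$eigenvalues,
              circulant_side = p$circulant_side)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(D_pixel = as.integer(obj$D_pixel), D_ac = as.integer(obj$D_ac),
         ac_basis = matrix(unlist(obj$ac_basis), nrow = obj$D_pixel),
         whitener = matrix(unlist(obj$whitener), nrow = obj$D_ac),
         dewhitener = matrix(unlist(obj$dewhitener), nrow = obj$D_ac),
         mean_vector = as.numeric(obj$mean_vector),
         eigenvalues = as.numeric(obj$eigenvalues),
         circulant_side = if (is.null(obj$circulant_side)) NULL else as.integer(obj$circulant_side)),
    class = "preprocessor"
  )
}
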