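# Pink-noise surrogates for natural-image input, plus the torus Fourier
# machinery shared by the cyclic-shift experiment and the evaluation module.

# signed torus frequencies for an s-point DFT axis: 0, 1, ..., floor(s/2), -...
torus_freqs <- function(s) {
  k <- 0:(s - 1)
  ifelse(k > s / 2, k - s, k)
}

#' Synthesize a large 1/f ("pink") noise image
#'
#' Builds a grayscale image whose DFT amplitudes are proportional to
#' `1 / f^spectral_exponent` (DC amplitude zero) with uniformly random,
#' Hermitian-symmetric phases, the standard stationary surrogate for the
#' second-order statistics of natural images. The result has zero mean and
#' unit pixel variance.
#'
#' @param height,width image size in pixels (both >= 16).
#' @param spectral_exponent amplitude falls off as `1/f^exponent`; 0 gives
#'   white noise, 1 (the default) the canonical natural-image surrogate
#'   (power spectrum `1/f^2`).
#' @param seed integer seed; the same seed reproduces the image bit-exactly.
#' @return an object of class `source_image` with fields `pixels`, `height`,
#'   `width`, `spectral_exponent`, `seed`.
#' @export
make_pink_noise_image <- function(height, width, spectral_exponent = 1, seed) {
  height <- check_count(height, "height", min = 16L)
  width <- check_count(width, "width", min = 16L)
  if (!is.numeric(spectral_exponent) || spectral_exponent < 0 ||
      spectral_exponent > 3) {
    stop("`spectral_exponent` must lie in [0, 3]", call. = FALSE)
  }
  z <- with_seed(seed, matrix(stats::rnorm(height * width), height, width))
  zf <- stats::fft(z)
  # unit-modulus Hermitian phase field from the white noise
  mod <- Mod(zf)
  mod[mod == 0] <- 1
  phase <- zf / mod
  fy <- torus_freqs(height) / height
  fx <- torus_freqs(width) / width
  f <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- ifelse(f > 0, f^(-spectral_exponent), 0)
  img <- Re(stats::fft(phase * amp, inverse = TRUE)) / (height * width)
  img <- img - mean(img)
  img <- img / stats::sd(img)
  structure(
    list(pixels = img, height = height, width = width,
         spectral_exponent = spectral_exponent, seed = seed),
    class = "source_image"
  )
}

#' Wrap a pixel matrix as a source image
#'
#' Utility for feeding deterministic test images (ramps, gratings) to the
#' pair generators.
#'
#' @param pixels numeric matrix of grayscale intensities.
#' @return a `source_image`.
#' @export
as_source_image <- function(pixels) {
  pixels <- check_matrix(pixels, "pixels")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         spectral_exponent = NA_real_, seed = NA_integer_),
    class = "source_image"
  )
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("<source_image> %d x %d px, 1/f^%g amplitude spectrum, seed %s\n",
              x$height, x$width, x$spectral_exponent, format(x$seed)))
  invisible(x)
}

# Real orthonormal Fourier basis on the side x side torus.
#
# Columns are the DC vector followed by quadrature (cosine, sine) pairs, one
# pair per conjugate frequency pair {k, -k}, ordered by increasing spatial
# frequency. For odd `side` every nonzero frequency belongs to such a pair,
# so the basis has 1 + 2 * (side^2 - 1) / 2 = side^2 columns.
#' Real Fourier quadrature basis on the torus
#'
#' @param side patch side in pixels (odd).
#' @return list with `basis` (side^2 x side^2 orthonormal matrix, columns in
#'   pixel space, column-major pixel order), `pair_index` (list of column
#'   index pairs, one per nonzero frequency), `freq` (two-column matrix of
#'   the signed frequency per pair) and `freq_mag` (cycles per patch).
#' @export
fourier_quadrature_basis <- function(side) {
  side <- check_count(side, "side", min = 3L)
  if (side %% 2L == 0L) {
    stop("`side` must be odd so that all nonzero frequencies form quadrature pairs",
         call. = FALSE)
  }
  ii <- rep(0:(side - 1), times = side)  # row index, column-major
  jj <- rep(0:(side - 1), each = side)   # col index
  ks <- torus_freqs(side)
  seen <- matrix(FALSE, side, side)
  cols <- matrix(0, side^2, side^2)
  cols[, 1] <- 1 / side
  pair_index <- list()
  freq <- NULL
  cn <- 1L
  # enumerate one representative per conjugate pair, sorted by |f|
  reps <- NULL
  for (a in seq_len(side)) {
    for (b in seq_len(side)) {
      kx <- ks[a]; ky <- ks[b]
      if (kx == 0 && ky == 0) next
      na <- ((side - (a - 1)) %% side) + 1L
      nb <- ((side - (b - 1)) %% side) + 1L
      if (seen[a, b] || seen[na, nb]) next
      seen[a, b] <- TRUE
      reps <- rbind(reps, c(kx, ky))
    }
  }
  ord <- order(reps[, 1]^2 + reps[, 2]^2)
  reps <- reps[ord, , drop = FALSE]
  for (r in seq_len(nrow(reps))) {
    kx <- reps[r, 1]; ky <- reps[r, 2]
    arg <- 2 * pi * (kx * ii + ky * jj) / side
    cvec <- cos(arg) * sqrt(2) / side
    svec <- sin(arg) * sqrt(2) / side
    cols[, cn + 1L] <- cvec
    cols[, cn + 2L] <- svec
    pair_index[[r]] <- c(cn + 1L, cn + 2L)
    cn <- cn + 2L
  }
  list(basis = cols, pair_index = pair_index, freq = reps,
       freq_mag = sqrt(reps[, 1]^2 + reps[, 2]^2))
}

#' Pink-noise patches with circulant covariance
#'
#' Draws patches that are stationary on the `side x side` torus: independent
#' Gaussian DFT coefficients with amplitude proportional to `1/f` on torus
#' frequencies and zero DC. Pixels on opposite borders are therefore
#' correlated as if they were direct neighbours, which makes cyclic
#' translation an exactly covariance-preserving transformation.
#'
#' @param n number of patches.
#' @param side patch side in pixels (odd, >= 5).
#' @param seed integer seed.
#' @param spectral_exponent amplitude exponent (default 1).
#' @return `n x side^2` matrix, rows are column-major vectorized patches with
#'   zero mean (DC removed by construction) and unit average pixel variance.
#' @export
make_circulant_pink_patches <- function(n, side = 11, seed,
                                        spectral_exponent = 1) {
  n <- check_count(n, "n")
  side <- check_count(side, "side", min = 5L)
  fb <- fourier_quadrature_basis(side)
  sig <- fb$freq_mag^(-spectral_exponent)
  # unit average pixel variance: sum_k 2 sigma_k^2 / side^2 = 1
  sig <- sig / sqrt(2 * sum(sig^2) / side^2)
  npair <- length(fb$pair_index)
  coef_sd <- rep(sig, each = 2L)
  coefs <- with_seed(seed, matrix(stats::rnorm(n * 2L * npair), n, 2L * npair))
  coefs <- sweep(coefs, 2L, coef_sd, "*")
  coefs %*% t(fb$basis[, -1, drop = FALSE])
}

#' Disc mask inside a square frame
#'
#' Selects the `n_pixels` pixels of a `frame_side x frame_side` grid closest
#' to the frame center (ties broken in row-major order), forming the round
#' 121-pixel patch used for patch-centered rotations. With the default odd
#' frame side the center falls on a pixel and the 121-pixel disc is exact
#' (no tie is split) and mirror-symmetric about both frame axes; an even
#' frame admits no symmetric odd-sized disc, so the customary 14 x 14 frame
#' is used only for visualization (see [embed_in_frame()]).
#'
#' @param frame_side frame side in pixels (default 13).
#' @param n_pixels number of pixels to keep (default 121).
#' @return object of class `disc_mask`: `frame_side`, `selected` (two-column
#'   matrix of 1-based (row, col) coordinates) and `index` (column-major
#'   linear indices into the frame).
#' @export
disc_mask <- function(frame_side = 13, n_pixels = 121) {
  frame_side <- check_count(frame_side, "frame_side", min = 2L)
  n_pixels <- check_count(n_pixels, "n_pixels")
  if (n_pixels > frame_side^2) stop("`n_pixels` exceeds frame size", call. = FALSE)
  ctr <- (frame_side + 1) / 2
  rows <- rep(seq_len(frame_side), each = frame_side)   # row-major enumeration
  colsv <- rep(seq_len(frame_side), times = frame_side)
  d2 <- (rows - ctr)^2 + (colsv - ctr)^2
  keep <- order(d2, rows, colsv)[seq_len(n_pixels)]
  sel <- cbind(row = rows[keep], col = colsv[keep])
  sel <- sel[order(sel[, "col"], sel[, "row"]), , drop = FALSE]  # column-major
  structure(
    list(frame_side = frame_side,
         selected = sel,
         index = (sel[, "col"] - 1L) * frame_side + sel[, "row"]),
    class = "disc_mask"
  )
}

#' Embed disc-masked values in a square frame for visualization
#'
#' Places the 121 disc pixel values back on their grid positions inside a
#' square frame (default 14 x 14, the round patch centered), filling the
#' remaining pixels with `fill`.
#'
#' @param values numeric vector, one value per mask pixel.
#' @param mask a [disc_mask()].
#' @param frame_side output frame side (>= `mask$frame_side`).
#' @param fill fill value for pixels outside the disc (default `NA`).
#' @return `frame_side x frame_side` matrix.
#' @export
embed_in_frame <- function(values, mask, frame_side = 14, fill = NA_real_) {
  stopifnot(inherits(mask, "disc_mask"),
            length(values) == nrow(mask$selected),
            frame_side >= mask$frame_side)
  off <- floor((frame_side - mask$frame_side) / 2)
  out <- matrix(fill, frame_side, frame_side)
  out[cbind(mask$selected[, "row"] + off, mask$selected[, "col"] + off)] <- values
  out
}
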