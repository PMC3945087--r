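# Transformation processes and patch-pair generation.
#
# All stimulus sequences are stored as pairs of time-adjacent frames
# (x_t, x_t1): the discrete-time slowness objective only ever needs adjacent
# frames, and pairs keep datasets rectangular and seed-reproducible.

.process_kinds <- c("translation_open", "translation_cyclic", "rotation_square",
                    "rotation_disc", "scaling", "movie_surrogate")

#' Specify a random transformation process
#'
#' Describes the random walk that carries one frame into the next: open- or
#' cyclic-boundary translation, patch-centered rotation (square or disc
#' window), patch-centered anisotropic scaling, or their composition as a
#' movie surrogate.
#'
#' @param kind one of `"translation_open"`, `"translation_cyclic"`,
#'   `"rotation_square"`, `"rotation_disc"`, `"scaling"`, `"movie_surrogate"`.
#' @param n_pairs number of frame pairs to generate (default 50000).
#' @param seed integer seed for the walk.
#' @param max_shift maximum per-axis translation magnitude in pixels; the
#'   per-step displacement magnitude is uniform on `[0, max_shift]` per axis
#'   with independent random sign (default 2).
#' @param angle_range per-step rotation increment range in radians (default
#'   `c(-pi, pi)/18`, i.e. +/- 10 degrees).
#' @param scale_factor_range per-step multiplicative window-size factor range
#'   per axis (default `c(0.95, 1.05)`).
#' @return object of class `transform_process`.
#' @export
transform_process <- function(kind, n_pairs = 50000, seed,
                              max_shift = 2,
                              angle_range = c(-pi / 18, pi / 18),
                              scale_factor_range = c(0.95, 1.05)) {
  kind <- match.arg(kind, .process_kinds)
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (!is.numeric(max_shift) || max_shift < 0) {
    stop("`max_shift` must be >= 0", call. = FALSE)
  }
  if (length(angle_range) != 2L || diff(angle_range) < 0) {
    stop("`angle_range` must be an interval", call. = FALSE)
  }
  if (length(scale_factor_range) != 2L || any(scale_factor_range <= 0) ||
      diff(scale_factor_range) < 0) {
    stop("`scale_factor_range` endpoints must be positive and ordered",
         call. = FALSE)
  }
  structure(
    list(kind = kind, n_pairs = n_pairs, seed = seed, max_shift = max_shift,
         angle_range = angle_range, scale_factor_range = scale_factor_range),
    class = "transform_process"
  )
}

new_pair_set <- function(x_t, x_t1, patch_side, process, steps) {
  stopifnot(nrow(x_t) == nrow(x_t1), ncol(x_t) == ncol(x_t1))
  if (!all(is.finite(x_t)) || !all(is.finite(x_t1))) {
    stop("pair set contains non-finite values", call. = FALSE)
  }
  structure(
    list(x_t = x_t, x_t1 = x_t1, patch_side = patch_side,
         process = process, steps = steps),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs, D = %d (%s), process: %s\n",
              nrow(x$x_t), ncol(x$x_t),
              if (is.numeric(x$patch_side)) sprintf("%dx%d patches", x$patch_side, x$patch_side)
              else as.character(x$patch_side),
              x$process$kind))
  invisible(x)
}

#' @export
dim.pair_set <- function(x) dim(x$x_t)

# Bilinear interpolation of `pixels` at real-valued (row, col) coordinate
# matrices R, C (1-based, same shape). Coordinates must satisfy
# 1 <= . <= nrow/ncol.
bilinear_sample <- function(pixels, R, C) {
  H <- nrow(pixels); W <- ncol(pixels)
  if (any(R < 1 - 1e-9) || any(R > H + 1e-9) ||
      any(C < 1 - 1e-9) || any(C > W + 1e-9)) {
    stop("sampling coordinates fall outside the source image", call. = FALSE)
  }
  R <- pmin(pmax(R, 1), H)
  C <- pmin(pmax(C, 1), W)
  r0 <- pmin(floor(R), H - 1); c0 <- pmin(floor(C), W - 1)
  fr <- R - r0; fc <- C - c0
  i00 <- (c0 - 1) * H + r0
  v <- (1 - fr) * (1 - fc) * pixels[i00] +
    fr * (1 - fc) * pixels[i00 + 1] +
    (1 - fr) * fc * pixels[i00 + H] +
    fr * fc * pixels[i00 + H + 1]
  dim(v) <- dim(R)
  v
}

# reflect a coordinate vector into [lo, hi]
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) stop("image too small for the requested window", call. = FALSE)
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

# per-axis random-walk steps: magnitude U(0, max_shift), independent sign
walk_steps <- function(n, max_shift) {
  mag <- stats::runif(n, 0, max_shift)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

# column-major in-patch offsets (0-based) for a side x side window
patch_grid <- function(side) {
  list(i = rep(0:(side - 1), times = side),   # row offset, fastest
       j = rep(0:(side - 1), each = side))    # col offset
}

#' Translation pairs with open boundary conditions
#'
#' Slides a `patch_side x patch_side` window over a source image along a
#' two-dimensional random walk with per-axis displacement magnitudes uniform
#' on `[0, max_shift]` (independent random sign per axis), reflecting the
#' walk at the image borders. Subpixel positions are sampled by bilinear
#' interpolation; consecutive window contents form the pairs.
#'
#' @param image a [make_pink_noise_image()] result (or any `source_image`).
#' @param process a [transform_process()] of kind `"translation_open"`.
#' @param patch_side window side in pixels (default 11).
#' @param shifts optional `n_pairs x 2` matrix of (row, col) walk steps
#'   overriding the random walk (used for exactness checks).
#' @return a `pair_set`; `steps` records the per-axis displacement of every
#'   step.
#' @export
translation_pairs <- function(image, process, patch_side = 11, shifts = NULL) {
  stopifnot(inherits(image, "source_image"),
            inherits(process, "transform_process"))
  if (process$kind != "translation_open") {
    stop("`process$kind` must be 'translation_open'", call. = FALSE)
  }
  side <- check_count(patch_side, "patch_side", min = 2L)
  H <- image$height; W <- image$width
  if (side > H || side > W) stop("patch larger than image", call. = FALSE)
  n <- process$n_pairs
  st <- with_seed(process$seed, {
    list(r0 = stats::runif(1, 1, H - side + 1),
         c0 = stats::runif(1, 1, W - side + 1),
         dr = walk_steps(n, process$max_shift),
         dc = walk_steps(n, process$max_shift))
  })
  if (!is.null(shifts)) {
    stopifnot(nrow(shifts) == n, ncol(shifts) == 2)
    st$dr <- shifts[, 1]
    st$dc <- shifts[, 2]
    st$r0 <- floor(st$r0)
    st$c0 <- floor(st$c0)
  }
  # walk positions (top-left corner, real-valued), reflected at borders
  rpos <- reflect_into(st$r0 + c(0, cumsum(st$dr)), 1, H - side + 1)
  cpos <- reflect_into(st$c0 + c(0, cumsum(st$dc)), 1, W - side + 1)
  g <- patch_grid(side)
  R <- outer(rpos, g$i, "+")
  C <- outer(cpos, g$j, "+")
  frames <- bilinear_sample(image$pixels, R, C)
  new_pair_set(frames[1:n, , drop = FALSE], frames[2:(n + 1), , drop = FALSE],
               side, process,
               data.frame(d_row = st$dr, d_col = st$dc))
}

#' Cyclic translation pairs on the torus
#'
#' Shifts each patch by a random subpixel displacement with periodic boundary
#' conditions, implemented exactly in the frequency domain (phase
#' multiplication), so that torus translation is exact for any real-valued
#' shift and the power spectrum of every frame is preserved to machine
#' precision.
#'
#' @param patches `n x side^2` matrix of square patches (column-major rows),
#'   e.g. from [make_circulant_pink_patches()].
#' @param process a [transform_process()] of kind `"translation_cyclic"`;
#'   `n_pairs` is taken from the number of rows of `patches`.
#' @param shifts optional `n x 2` matrix of (row, col) shifts overriding the
#'   random walk (used for exactness checks).
#' @return a `pair_set` with `x_t = patches` and `x_t1` the shifted frames.
#' @export
cyclic_shift_pairs <- function(patches, process, shifts = NULL) {
  patches <- check_matrix(patches, "patches")
  stopifnot(inherits(process, "transform_process"))
  if (process$kind != "translation_cyclic") {
    stop("`process$kind` must be 'translation_cyclic'", call. = FALSE)
  }
  side <- sqrt(ncol(patches))
  if (side != round(side)) stop("patches are not square", call. = FALSE)
  side <- as.integer(side)
  n <- nrow(patches)
  if (is.null(shifts)) {
    shifts <- with_seed(process$seed, cbind(walk_steps(n, process$max_shift),
                                            walk_steps(n, process$max_shift)))
  }
  stopifnot(nrow(shifts) == n, ncol(shifts) == 2)
  # 2-D DFT of all rows at once via the Kronecker DFT matrix (side is small)
  Fm <- stats::mvfft(diag(side))            # side x side DFT matrix (columns)
  D2 <- kronecker(Fm, Fm)                   # acts on column-major vectors:
  # index k = ky + side*kx <-> frequency (row ky, col kx)
  Xf <- patches %*% t(D2)
  ks <- torus_freqs(side)
  krow <- rep(ks, times = side)             # frequency along rows
  kcol <- rep(ks, each = side)              # frequency along cols
  phase <- exp(-2i * pi * (outer(shifts[, 1], krow) +
                             outer(shifts[, 2], kcol)) / side)
  x1 <- Re((Xf * phase) %*% t(Conj(D2))) / side^2
  new_pair_set(patches, x1, side, process,
               data.frame(d_row = shifts[, 1], d_col = shifts[, 2]))
}

# sample a window grid rotated by `angle` and scaled per-axis by (qr, qc)
# around a real-valued center (cr, cc); offsets u (row), v (col) are the
# centered patch grid. Returns an n x D coordinate pair via rotation of the
# sampling lattice (positive angle rotates the sampling window).
affine_grid <- function(cr, cc, u, v, angle, qr = 1, qc = 1) {
  n <- max(length(cr), length(angle), length(qr))
  cr <- rep_len(cr, n); cc <- rep_len(cc, n)
  angle <- rep_len(angle, n); qr <- rep_len(qr, n); qc <- rep_len(qc, n)
  R <- outer(cos(angle) * qr, u) - outer(sin(angle) * qc, v) + cr
  C <- outer(sin(angle) * qr, u) + outer(cos(angle) * qc, v) + cc
  list(R = R, C = C)
}

#' Patch-centered rotation pairs
#'
#' Each pair is a window rotated about its center pixel: the first frame at a
#' random base angle, the second rotated further by an increment drawn
#' uniformly from `process$angle_range`. Window contents are resampled from
#' the source image by bilinear interpolation. For `rotation_disc` only the
#' pixels of the [disc_mask()] are emitted (121 values per frame).
#'
#' @param image a `source_image`.
#' @param process a [transform_process()] of kind `"rotation_square"` or
#'   `"rotation_disc"`.
#' @param patch_side window side for the square variant (default 11).
#' @param mask a [disc_mask()] for the disc variant (required there,
#'   forbidden for `rotation_square`).
#' @return a `pair_set`; `steps` records base angle and increment.
#' @export
rotation_pairs <- function(image, process, patch_side = 11, mask = NULL) {
  stopifnot(inherits(image, "source_image"),
            inherits(process, "transform_process"))
  if (!process$kind %in% c("rotation_square", "rotation_disc")) {
    stop("`process$kind` must be a rotation kind", call. = FALSE)
  }
  if (process$kind == "rotation_square" && !is.null(mask)) {
    stop("`mask` must not be given for 'rotation_square'", call. = FALSE)
  }
  if (process$kind == "rotation_disc") {
    if (is.null(mask)) mask <- disc_mask()
    patch_side <- mask$frame_side
  }
  side <- check_count(patch_side, "patch_side", min = 2L)
  n <- process$n_pairs
  half <- (side - 1) / 2
  margin <- ceiling(half * sqrt(2)) + 2
  H <- image$height; W <- image$width
  if (2 * margin >= min(H, W)) stop("image too small for rotation window", call. = FALSE)
  st <- with_seed(process$seed, {
    list(cr = stats::runif(n, 1 + margin, H - margin),
         cc = stats::runif(n, 1 + margin, W - margin),
         theta0 = stats::runif(n, 0, 2 * pi),
         dtheta = stats::runif(n, process$angle_range[1], process$angle_range[2]))
  })
  g <- patch_grid(side)
  u <- g$i - half; v <- g$j - half
  g0 <- affine_grid(st$cr, st$cc, u, v, st$theta0)
  g1 <- affine_grid(st$cr, st$cc, u, v, st$theta0 + st$dtheta)
  f0 <- bilinear_sample(image$pixels, g0$R, g0$C)
  f1 <- bilinear_sample(image$pixels, g1$R, g1$C)
  if (process$kind == "rotation_disc") {
    f0 <- f0[, mask$index, drop = FALSE]
    f1 <- f1[, mask$index, drop = FALSE]
    side_out <- mask
  } else {
    side_out <- side
  }
  new_pair_set(f0, f1, if (is.numeric(side_out)) side_out else "disc",
               process, data.frame(theta0 = st$theta0, d_theta = st$dtheta))
}

#' Rotate a window about its center (deterministic helper)
#'
#' Resamples a `side x side` window centered at `(center_row, center_col)`
#' from `image`, rotated by `angle` radians, with bilinear interpolation.
#' Used for exactness checks (a full turn reproduces the unrotated window).
#'
#' @param image a `source_image`.
#' @param center_row,center_col window center (1-based, may be fractional).
#' @param side window side.
#' @param angle rotation angle in radians.
#' @return vector of length `side^2` (column-major window contents).
#' @export
rotate_window <- function(image, center_row, center_col, side, angle) {
  g <- patch_grid(side)
  half <- (side - 1) / 2
  gg <- affine_grid(center_row, center_col, g$i - half, g$j - half, angle)
  as.vector(bilinear_sample(image$pixels, gg$R, gg$C))
}

#' Patch-centered anisotropic scaling pairs
#'
#' Each frame is a window of per-axis size `(s_row, s_col)` pixels around a
#' fixed random center, resampled to `patch_side x patch_side` by bilinear
#' interpolation. Window sides start uniform in
#' `[patch_side, 2 * patch_side]` and are multiplied per step by independent
#' per-axis factors uniform on `scale_factor_range`, clipped back to that
#' interval.
#'
#' @param image a `source_image`.
#' @param process a [transform_process()] of kind `"scaling"`.
#' @param patch_side output patch side (default 11).
#' @return a `pair_set`; `steps` records the window sides of both frames.
#' @export
scaling_pairs <- function(image, process, patch_side = 11) {
  stopifnot(inherits(image, "source_image"),
            inherits(process, "transform_process"))
  if (process$kind != "scaling") stop("`process$kind` must be 'scaling'", call. = FALSE)
  if (diff(process$scale_factor_range) == 0 &&
      process$scale_factor_range[1] != 1) {
    stop("degenerate `scale_factor_range` (fixed factor != 1 drifts out of range)",
         call. = FALSE)
  }
  side <- check_count(patch_side, "patch_side", min = 2L)
  n <- process$n_pairs
  lo <- side; hi <- 2 * side
  margin <- hi / 2 + 2
  H <- image$height; W <- image$width
  if (2 * margin >= min(H, W)) stop("image too small for scaling window", call. = FALSE)
  st <- with_seed(process$seed, {
    list(cr = stats::runif(n, 1 + margin, H - margin),
         cc = stats::runif(n, 1 + margin, W - margin),
         s0r = stats::runif(n, lo, hi), s0c = stats::runif(n, lo, hi),
         fr = stats::runif(n, process$scale_factor_range[1], process$scale_factor_range[2]),
         fc = stats::runif(n, process$scale_factor_range[1], process$scale_factor_range[2]))
  })
  s1r <- pmin(pmax(st$s0r * st$fr, lo), hi)
  s1c <- pmin(pmax(st$s0c * st$fc, lo), hi)
  g <- patch_grid(side)
  half <- (side - 1) / 2
  u <- g$i - half; v <- g$j - half
  g0 <- affine_grid(st$cr, st$cc, u, v, 0, st$s0r / side, st$s0c / side)
  g1 <- affine_grid(st$cr, st$cc, u, v, 0, s1r / side, s1c / side)
  new_pair_set(bilinear_sample(image$pixels, g0$R, g0$C),
               bilinear_sample(image$pixels, g1$R, g1$C),
               side, process,
               data.frame(s0_row = st$s0r, s0_col = st$s0c,
                          s1_row = s1r, s1_col = s1c,
                          f_row = st$fr, f_col = st$fc))
}

#' Movie-surrogate pairs: composed translation, rotation and scaling
#'
#' Emulates natural-movie statistics by composing small random increments of
#' translation, rotation and anisotropic scaling per step along a single
#' random walk over a pink-noise scene. All increments are logged in
#' `steps`.
#'
#' @param image a `source_image`.
#' @param process a [transform_process()] of kind `"movie_surrogate"`; its
#'   `max_shift`, `angle_range` and `scale_factor_range` set the per-step
#'   increment laws of the three components.
#' @param patch_side output patch side (default 11).
#' @return a `pair_set`.
#' @export
movie_surrogate_pairs <- function(image, process, patch_side = 11) {
  stopifnot(inherits(image, "source_image"),
            inherits(process, "transform_process"))
  if (process$kind != "movie_surrogate") {
    stop("`process$kind` must be 'movie_surrogate'", call. = FALSE)
  }
  side <- check_count(patch_side, "patch_side", min = 2L)
  n <- process$n_pairs
  lo <- side; hi <- 2 * side
  half <- (side - 1) / 2
  margin <- ceiling(hi / 2 * sqrt(2)) + 2
  H <- image$height; W <- image$width
  if (2 * margin >= min(H, W)) stop("image too small for movie window", call. = FALSE)
  st <- with_seed(process$seed, {
    list(r0 = stats::runif(1, 1 + margin, H - margin),
         c0 = stats::runif(1, 1 + margin, W - margin),
         dr = walk_steps(n, process$max_shift),
         dc = walk_steps(n, process$max_shift),
         th0 = stats::runif(1, 0, 2 * pi),
         dth = stats::runif(n, process$angle_range[1], process$angle_range[2]),
         sr0 = stats::runif(1, lo, hi), sc0 = stats::runif(1, lo, hi),
         fr = stats::runif(n, process$scale_factor_range[1], process$scale_factor_range[2]),
         fc = stats::runif(n, process$scale_factor_range[1], process$scale_factor_range[2]))
  })
  cr <- reflect_into(st$r0 + c(0, cumsum(st$dr)), 1 + margin, H - margin)
  cc <- reflect_into(st$c0 + c(0, cumsum(st$dc)), 1 + margin, W - margin)
  th <- st$th0 + c(0, cumsum(st$dth))
  lsr <- reflect_into(log(st$sr0) + c(0, cumsum(log(st$fr))), log(lo), log(hi))
  lsc <- reflect_into(log(st$sc0) + c(0, cumsum(log(st$fc))), log(lo), log(hi))
  g <- patch_grid(side)
  u <- g$i - half; v <- g$j - half
  gg <- affine_grid(cr, cc, u, v, th, exp(lsr) / side, exp(lsc) / side)
  frames <- bilinear_sample(image$pixels, gg$R, gg$C)
  new_pair_set(frames[1:n, , drop = FALSE], frames[2:(n + 1), , drop = FALSE],
               side, process,
               data.frame(d_row = st$dr, d_col = st$dc, d_theta = st$dth,
                          f_row = st$fr, f_col = st$fc))
}
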