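# Spike-triggered covariance analysis of quadratic model neurons.
#
# Slow feature analysis (SFA) on the quadratic feature space of a reduced
# stimulus representation yields model complex cells whose response is a
# quadratic form. Their responses are median-split into an excitatory and an
# inhibitory firing-rate stream, turned into Poisson spike counts, and
# analyzed with spike-triggered covariance; eigenvalue significance is
# assessed against spectra recomputed with shuffled spike counts.

#' Quadratic feature expansion
#'
#' All monomials `z_a * z_b` with `a <= b` followed by the linear terms:
#' for `n` coordinates, `n (n + 1) / 2 + n` features. For `z = (z1, z2)` the
#' feature vector is `(z1^2, z1 z2, z2^2, z1, z2)`.
#'
#' @param z numeric vector of `n >= 2` stimulus coordinates, or a `T x n`
#'   matrix (one stimulus per row).
#' @return feature vector, or `T x (n(n+1)/2 + n)` matrix.
#' @export
quadratic_expansion <- function(z) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1)
  n <- ncol(z)
  if (n < 2) stop("need at least 2 stimulus coordinates", call. = FALSE)
  quad <- do.call(cbind, lapply(seq_len(n), function(a) {
    z[, a] * z[, a:n, drop = FALSE]
  }))
  out <- cbind(quad, z)
  if (vec) drop(out) else out
}

# index pairs (a, b), a <= b, in the order produced by quadratic_expansion
quad_index_pairs <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(a) cbind(a, a:n)))
}

# map feature-space weights back to (Q, b): r(z) = z' Q z + b' z + const
weights_to_quadratic <- function(w, n) {
  np <- n * (n + 1) / 2
  stopifnot(length(w) == np + n)
  idx <- quad_index_pairs(n)
  Q <- matrix(0, n, n)
  for (k in seq_len(np)) {
    a <- idx[k, 1]; b <- idx[k, 2]
    if (a == b) Q[a, a] <- w[k] else {
      Q[a, b] <- Q[a, b] + w[k] / 2
      Q[b, a] <- Q[b, a] + w[k] / 2
    }
  }
  list(Q = Q, b = w[np + seq_len(n)])
}

#' Slow feature analysis on the quadratic feature space
#'
#' Expands stimulus pairs quadratically, centers and whitens the features,
#' and solves the symmetric eigenproblem of the temporal-difference
#' covariance; the eigenvectors with the smallest difference variance are the
#' slowest quadratic functions of the input. Each component is mapped back to
#' an explicit quadratic form.
#'
#' @param z_t,z_t1 `T x n` matrices of time-adjacent stimulus coordinates.
#' @param n_components number of slow components to return (default 1).
#' @param reg relative eigenvalue floor below which the feature covariance is
#'   declared rank-deficient (default 1e-10).
#' @return list of `quadratic_neuron` objects (fields `Q` symmetric, `b`,
#'   `offset`, `delta_variance`, `rate_scale` initially `NA`), slowest first.
#' @export
sfa_quadratic <- function(z_t, z_t1, n_components = 1, reg = 1e-10) {
  z_t <- check_matrix(z_t, "z_t"); z_t1 <- check_matrix(z_t1, "z_t1")
  stopifnot(nrow(z_t) == nrow(z_t1), ncol(z_t) == ncol(z_t1))
  n <- ncol(z_t)
  F1 <- quadratic_expansion(z_t)
  F2 <- quadratic_expansion(z_t1)
  p <- ncol(F1)
  if (nrow(F1) < 5 * p) {
    stop("too few pairs for the quadratic feature dimension", call. = FALSE)
  }
  mu <- colMeans(rbind(F1, F2))
  F1 <- sweep(F1, 2, mu); F2 <- sweep(F2, 2, mu)
  C <- (crossprod(F1) + crossprod(F2)) / (2 * nrow(F1))
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
  n_def <- sum(ev$values < reg * max(ev$values))
  if (n_def > 0) {
    stop(sprintf("feature covariance is rank-deficient: %d eigenvalue(s) below threshold",
                 n_def), call. = FALSE)
  }
  Wh <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  Dm <- (F2 - F1) %*% Wh
  A <- crossprod(Dm) / nrow(Dm)
  evA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  p_ <- length(evA$values)
  sel <- p_ - seq_len(n_components) + 1L  # smallest eigenvalues = slowest
  lapply(seq_len(n_components), function(k) {
    v <- Wh %*% evA$vectors[, sel[k]]
    qb <- weights_to_quadratic(as.numeric(v), n)
    structure(
      list(Q = qb$Q, b = qb$b, offset = -sum(mu * v),
           delta_variance = evA$values[sel[k]],
           rate_scale = NA_real_, median_threshold = NA_real_),
      class = "quadratic_neuron"
    )
  })
}

#' Response of a quadratic neuron
#'
#' @param neuron a `quadratic_neuron`.
#' @param stimuli `T x n` stimulus matrix.
#' @return numeric response vector `r(t) = z' Q z + b' z + offset`.
#' @export
neuron_response <- function(neuron, stimuli) {
  stopifnot(inherits(neuron, "quadratic_neuron"))
  stimuli <- check_matrix(stimuli, "stimuli")
  rowSums((stimuli %*% neuron$Q) * stimuli) +
    as.numeric(stimuli %*% neuron$b) + neuron$offset
}

#' Median-split excitatory and inhibitory firing rates
#'
#' Centers the neuron's responses at their median and splits them into an
#' excitatory rate stream (positive part) and an inhibitory stream (absolute
#' value of the negative part), scaled to spikes per frame. At most one of
#' the two rates is positive in any frame.
#'
#' @param neuron a `quadratic_neuron`.
#' @param stimuli `T x n` stimulus matrix.
#' @param rate_scale spikes per frame per response unit; the default `NULL`
#'   calibrates it so that the mean of `excitatory + inhibitory` is
#'   `target_mean_rate`.
#' @param target_mean_rate mean rate used for calibration (default 0.5
#'   spikes/frame).
#' @return list with `excitatory`, `inhibitory` (rate vectors), `median`
#'   (the split threshold) and `rate_scale` used.
#' @export
neuron_rates <- function(neuron, stimuli, rate_scale = NULL,
                         target_mean_rate = 0.5) {
  r <- neuron_response(neuron, stimuli)
  med <- stats::median(r)
  e <- pmax(r - med, 0)
  i <- pmax(med - r, 0)
  if (is.null(rate_scale)) {
    m <- mean(e + i)
    rate_scale <- if (m > 0) target_mean_rate / m else 0
  }
  list(excitatory = e * rate_scale, inhibitory = i * rate_scale,
       median = med, rate_scale = rate_scale)
}

#' Poisson spike counts from firing rates
#'
#' @param rates nonnegative rate vector (spikes per frame).
#' @param seed integer seed.
#' @return integer vector of independent Poisson draws.
#' @export
poisson_counts <- function(rates, seed) {
  if (any(rates < 0)) stop("`rates` must be nonnegative", call. = FALSE)
  with_seed(seed, stats::rpois(length(rates), rates))
}

#' Spike-triggered covariance matrix
#'
#' Spike-count-weighted covariance of the stimuli about the spike-triggered
#' mean, minus the identity prior (stimuli are assumed white with unit
#' variance).
#'
#' @param stimuli `T x n` white stimulus matrix.
#' @param counts integer spike counts per frame (`sum(counts) > 0`).
#' @return symmetric `n x n` matrix.
#' @export
stc_matrix <- function(stimuli, counts) {
  stimuli <- check_matrix(stimuli, "stimuli")
  stopifnot(length(counts) == nrow(stimuli))
  N <- sum(counts)
  if (N <= 0) stop("zero total spike count", call. = FALSE)
  sta <- as.numeric(crossprod(stimuli, counts)) / N
  Xc <- sweep(stimuli, 2, sta)
  C <- crossprod(Xc * counts, Xc) / N - diag(ncol(stimuli))
  (C + t(C)) / 2
}

#' Shuffle-based significance of STC eigenvalues
#'
#' Computes the STC eigen-spectrum of the data and of `n_shuffles` controls
#' in which the spike counts are randomly permuted against the stimuli. Data
#' eigenvalues above `mean + z * SD` of the shuffled control distribution
#' are significant excitatory directions, below `mean - z * SD` significant
#' inhibitory ones — the dashed significance band drawn on an eigen-spectrum
#' panel.
#'
#' With `band = "pooled"` (the default) the mean and SD are taken over all
#' shuffled eigenvalues pooled, giving one flat band. With
#' `band = "per_rank"` each eigenvalue rank gets its own band from the
#' shuffled spectra at that rank. The per-rank band is only calibrated when
#' the number of signal dimensions is a negligible fraction of the stimulus
#' dimension: a data spectrum with `k` genuine eigenvalues compares its
#' rank `k + 1` (the *largest* of the remaining null directions) against the
#' shuffles' rank-`(k + 1)` order statistic, an upward-biased comparison
#' that at a few dozen stimulus dimensions produces spurious detections.
#'
#' @param stimuli `T x n` white stimulus matrix.
#' @param counts spike counts per frame.
#' @param n_shuffles number of shuffled controls (>= 20; default 100).
#' @param z significance threshold in shuffled SDs (default 4.4).
#' @param seed integer seed for the shuffles.
#' @param band `"pooled"` (default) or `"per_rank"`, see above.
#' @return object of class `stc_result`: `eigenvalues` (sorted decreasing),
#'   `shuffle_mean`, `shuffle_sd` (per rank), `n_sig_excitatory`,
#'   `n_sig_inhibitory`, `z_threshold`, `band`.
#' @export
stc_significance <- function(stimuli, counts, n_shuffles = 100, z = 4.4, seed,
                             band = c("pooled", "per_rank")) {
  band <- match.arg(band)
  n_shuffles <- check_count(n_shuffles, "n_shuffles", min = 20L)
  ev <- sort(eigen(stc_matrix(stimuli, counts), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  shuf <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      cs <- counts[sample.int(length(counts))]
      sort(eigen(stc_matrix(stimuli, cs), symmetric = TRUE,
                 only.values = TRUE)$values, decreasing = TRUE)
    }, numeric(length(ev)))
  })
  if (band == "pooled") {
    m <- rep(mean(shuf), length(ev))
    s <- rep(stats::sd(as.vector(shuf)), length(ev))
  } else {
    m <- rowMeans(shuf)
    s <- apply(shuf, 1, stats::sd)
  }
  structure(
    list(eigenvalues = ev, shuffle_mean = m, shuffle_sd = s,
         n_sig_excitatory = sum(ev > m + z * s),
         n_sig_inhibitory = sum(ev < m - z * s),
         z_threshold = z, band = band),
    class = "stc_result"
  )
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf("<stc_result> %d dims: %d significant excitatory, %d inhibitory (z = %.1f)\n",
              length(x$eigenvalues), x$n_sig_excitatory, x$n_sig_inhibitory,
              x$z_threshold))
  invisible(x)
}

#' Low-frequency Fourier stimulus coordinates of a pair set
#'
#' Projects pixel-space patch pairs onto the `n_components` lowest-frequency
#' vectors of the real Fourier basis (DC excluded), the reduced stimulus
#' space on which the SFA model neurons are built.
#'
#' @param pairs a pixel-space `pair_set` of square patches.
#' @param n_components number of Fourier coordinates to keep.
#' @param whiten scale each coordinate to unit variance over the training
#'   frames (default TRUE).
#' @return list with `z_t`, `z_t1` (`T x n_components`), `basis` (pixel-space
#'   vectors, one per column) and `scale`.
#' @export
fourier_stimulus_coords <- function(pairs, n_components, whiten = TRUE) {
  check_pairs(pairs)
  side <- pairs$patch_side
  stopifnot(is.numeric(side))
  fb <- fourier_quadrature_basis(side)
  B <- fb$basis[, -1, drop = FALSE][, seq_len(n_components), drop = FALSE]
  z1 <- pairs$x_t %*% B
  z2 <- pairs$x_t1 %*% B
  sc <- rep(1, n_components)
  if (whiten) {
    sc <- 1 / sqrt(apply(rbind(z1, z2), 2, stats::var))
    z1 <- sweep(z1, 2, sc, "*")
    z2 <- sweep(z2, 2, sc, "*")
  }
  list(z_t = z1, z_t1 = z2, basis = B, scale = sc)
}
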