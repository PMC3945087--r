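# Configuration-driven experiment orchestration: data generation,
# preprocessing, training, evaluation, and serialized artifacts with a
# manifest for bit-exact re-runs.

#' Write / read a pair set as plain text
#'
#' Frames go to two gzipped CSV files (`<prefix>_x_t.csv.gz`,
#' `<prefix>_x_t1.csv.gz`), step logs to `<prefix>_steps.csv`, and process
#' metadata to a JSON sidecar `<prefix>_process.json`.
#'
#' @param pairs a `pair_set`.
#' @param prefix file path prefix.
#' @return `read_pair_set` returns the restored `pair_set` (numeric values
#'   round-trip at full double precision).
#' @export
write_pair_set <- function(pairs, prefix) {
  stopifnot(inherits(pairs, "pair_set"))
  wr <- function(m, path) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  wr(pairs$x_t, paste0(prefix, "_x_t.csv.gz"))
  wr(pairs$x_t1, paste0(prefix, "_x_t1.csv.gz"))
  utils::write.csv(pairs$steps, paste0(prefix, "_steps.csv"), row.names = FALSE)
  meta <- pairs$process
  meta$patch_side <- if (is.numeric(pairs$patch_side)) pairs$patch_side else "disc"
  meta$whitened <- isTRUE(pairs$whitened)
  jsonlite::write_json(unclass(meta), paste0(prefix, "_process.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_pair_set
#' @export
read_pair_set <- function(prefix) {
  rd <- function(path) {
    as.matrix(utils::read.table(gzfile(path), sep = ",",
                                colClasses = "numeric"))
  }
  x_t <- unname(rd(paste0(prefix, "_x_t.csv.gz")))
  x_t1 <- unname(rd(paste0(prefix, "_x_t1.csv.gz")))
  steps <- utils::read.csv(paste0(prefix, "_steps.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_process.json"),
                              simplifyVector = TRUE)
  proc <- transform_process(
    kind = meta$kind, n_pairs = meta$n_pairs, seed = meta$seed,
    max_shift = meta$max_shift, angle_range = meta$angle_range,
    scale_factor_range = meta$scale_factor_range
  )
  ps <- new_pair_set(x_t, x_t1,
                     if (identical(meta$patch_side, "disc")) "disc"
                     else as.numeric(meta$patch_side),
                     proc, steps)
  if (isTRUE(meta$whitened)) ps$whitened <- TRUE
  ps
}

#' Write / read a filter bank as plain text
#'
#' @param bank a `filter_bank`.
#' @param path CSV file path (a JSON sidecar `<path>.json` holds `K`).
#' @return `read_filter_bank` returns the restored `filter_bank`.
#' @export
write_filter_bank <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  utils::write.table(format(bank$W, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(K = bank$K), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  W <- unname(as.matrix(utils::read.table(path, sep = ",",
                                          colClasses = "numeric")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  filter_bank(W, K = meta$K, check = FALSE)
}

.dataset_kinds <- c(translation = "translation_open",
                    cyclic = "translation_cyclic",
                    rotation = "rotation_square",
                    `rotation-disc` = "rotation_disc",
                    scaling = "scaling",
                    `movie-surrogate` = "movie_surrogate")

default_experiment_config <- function() {
  list(
    dataset = "translation", n_pairs = 20000, patch_side = 11,
    image_size = 512, spectral_exponent = 1,
    max_shift = 2, angle_range_deg = c(-10, 10),
    scale_factor_range = c(0.95, 1.05),
    gamma = 0, mu0 = 1, tol = 1e-8, max_iter = 500,
    seed = NULL, out_dir = NULL,
    evaluate = TRUE, mosaic = TRUE
  )
}

validate_experiment_config <- function(config) {
  base <- default_experiment_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  merged <- utils::modifyList(base, config)
  missing <- c("seed", "out_dir")[vapply(merged[c("seed", "out_dir")],
                                         is.null, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("config field(s) required but missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!merged$dataset %in% names(.dataset_kinds)) {
    stop(sprintf("config field `dataset` must be one of: %s",
                 paste(names(.dataset_kinds), collapse = ", ")), call. = FALSE)
  }
  if (merged$gamma < 0 || merged$gamma > 1) {
    stop("config field `gamma` must lie in [0, 1]", call. = FALSE)
  }
  merged
}

generate_dataset <- function(config) {
  kind <- .dataset_kinds[[config$dataset]]
  data_seed <- config$seed + 1000L
  proc <- transform_process(
    kind, n_pairs = config$n_pairs, seed = data_seed,
    max_shift = config$max_shift,
    angle_range = config$angle_range_deg * pi / 180,
    scale_factor_range = config$scale_factor_range
  )
  if (kind == "translation_cyclic") {
    patches <- make_circulant_pink_patches(config$n_pairs, config$patch_side,
                                           seed = data_seed + 1L)
    return(cyclic_shift_pairs(patches, proc))
  }
  img <- make_pink_noise_image(config$image_size, config$image_size,
                               config$spectral_exponent, seed = data_seed + 1L)
  switch(kind,
         translation_open = translation_pairs(img, proc, config$patch_side),
         rotation_square = rotation_pairs(img, proc, config$patch_side),
         rotation_disc = rotation_pairs(img, proc, mask = disc_mask()),
         scaling = scaling_pairs(img, proc, config$patch_side),
         movie_surrogate = movie_surrogate_pairs(img, proc, config$patch_side))
}

#' Run a complete seeded experiment
#'
#' Generates the configured stimulus pair set, fits the preprocessor (with
#' the circulant covariance estimator for the cyclic dataset), trains a
#' filter bank for the configured trade-off weight, evaluates it, and writes
#' all artifacts plus a manifest to the output directory. Re-running the
#' same config reproduces all numeric artifacts bit-exactly.
#'
#' @param config named list; recognized fields (with defaults): `dataset`
#'   (`"translation"`, `"cyclic"`, `"rotation"`, `"rotation-disc"`,
#'   `"scaling"`, `"movie-surrogate"`), `n_pairs`, `patch_side`,
#'   `image_size`, `spectral_exponent`, `max_shift`, `angle_range_deg`,
#'   `scale_factor_range`, `gamma`, `mu0`, `tol`, `max_iter`, `evaluate`,
#'   `mosaic`, and the required `seed` and `out_dir`. May also be a path to
#'   a YAML file holding these fields.
#' @return invisibly, a list with `bank`, `trace`, `preproc`, `report`,
#'   `artifacts` (file paths).
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_experiment_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  pairs <- generate_dataset(config)
  is_disc <- !is.numeric(pairs$patch_side)
  side <- if (is_disc) NA_integer_ else pairs$patch_side

  preproc <- fit_preprocessor(
    rbind(pairs$x_t, pairs$x_t1),
    circulant_side = if (config$dataset == "cyclic") side else NULL
  )
  wpairs <- preprocess_pairs(preproc, pairs)

  cfg <- optimizer_config(mu0 = config$mu0, tol = config$tol,
                          max_iter = config$max_iter, seed = config$seed)
  fit <- train_subspace_bank(wpairs, gamma = config$gamma, config = cfg)

  artifacts <- character(0)
  write_preprocessor(preproc, out("preprocessor.json"))
  write_filter_bank(fit$bank, out("filters.csv"))
  utils::write.csv(
    data.frame(iteration = seq_along(fit$trace$objective_per_iteration) - 1L,
               objective = fit$trace$objective_per_iteration),
    out("trace.csv"), row.names = FALSE
  )
  artifacts <- c(artifacts, out(c("preprocessor.json", "filters.csv",
                                  "filters.csv.json", "trace.csv")))

  report <- NULL
  if (isTRUE(config$evaluate) && !is_disc) {
    report <- subspace_report(fit$bank, preproc, wpairs, side)
    utils::write.csv(report, out("subspace_report.csv"), row.names = FALSE)
    artifacts <- c(artifacts, out("subspace_report.csv"))
    if (config$dataset == "cyclic") {
      fm <- fourier_match_score(fit$bank, side, preproc)
      jsonlite::write_json(list(fourier_match_score = fm),
                           out("fourier_match.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, out("fourier_match.json"))
    }
    if (isTRUE(config$mosaic)) {
      V <- filters_to_pixel_space(preproc, fit$bank)
      ord <- rank_subspaces(fit$bank, wpairs)$subspace_order
      row_ord <- as.vector(rbind(2 * ord - 1, 2 * ord))
      plot_filter_mosaic(V[row_ord, , drop = FALSE], side,
                         file = out("filter_mosaic.png"))
      artifacts <- c(artifacts, out("filter_mosaic.png"))
    }
  }

  manifest <- list(
    config = config[order(names(config))],
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(
      names(config)[order(names(config))],
      vapply(config[order(names(config))], function(v) paste(format(v), collapse = ","),
             character(1)),
      collapse = ";"))),
    final_objective = fit$trace$objective_per_iteration[
      length(fit$trace$objective_per_iteration)],
    n_iterations = fit$trace$n_iterations,
    converged = fit$trace$converged,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("slowsubspace"))
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, out("manifest.json"))

  invisible(list(bank = fit$bank, trace = fit$trace, preproc = preproc,
                 report = report, artifacts = artifacts))
}
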