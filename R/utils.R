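#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, restoring the
#' previous RNG state afterwards so library calls do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# single positive integer check with a caller-facing name
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  x
}

#' Column-major vectorization of an image patch
#'
#' Stacks the columns of a rectangular patch into a vector, the convention
#' used throughout for mapping between pixel grids and coordinate vectors.
#'
#' @param patch numeric matrix (rows x cols).
#' @return numeric vector of length `nrow(patch) * ncol(patch)`.
#' @examples
#' vectorize_patch(matrix(c(1, 2, 3, 4), 2, 2))
#' @export
vectorize_patch <- function(patch) {
  if (!is.matrix(patch)) stop("`patch` must be a matrix", call. = FALSE)
  as.vector(patch)
}

#' @rdname vectorize_patch
#' @param v numeric vector of length `side^2` (or `rows*cols`).
#' @param rows,cols patch dimensions.
#' @export
unvectorize_patch <- function(v, rows, cols = rows) {
  if (length(v) != rows * cols) {
    stop("length of `v` does not match `rows * cols`", call. = FALSE)
  }
  matrix(v, nrow = rows, ncol = cols)
}
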