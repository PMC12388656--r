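#' @useDynLib assemblyscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2
NULL

# Deterministic child seeds: one user-facing seed fans out to independent
# streams per component so stages are individually reproducible.
child_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483562L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Convert a symmetric matrix to a validated distance matrix
#'
#' A light wrapper around a base matrix that enforces the contract every
#' pairwise metric in the package relies on: named, symmetric to within
#' 1e-12, zero diagonal. Signed matrices (e.g. betaNTI) are allowed via
#' `nonnegative = FALSE`.
#'
#' @param m square numeric matrix with identical row/column names.
#' @param nonnegative require all entries >= 0 (default TRUE).
#' @return the matrix, invisibly validated, with class `dist_matrix`.
#' @export
as_dist_matrix <- function(m, nonnegative = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort("`m` must be a square matrix.")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort("`m` must carry row and column names.")
  if (!identical(rownames(m), colnames(m)))
    abort("Row and column names must be identical.")
  if (anyDuplicated(rownames(m)))
    abort("Duplicated labels in distance matrix.")
  finite <- is.finite(m)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12)
    abort("Matrix is not symmetric within 1e-12.")
  if (any(abs(diag(m)) > 0))
    abort("Diagonal must be exactly zero.")
  if (nonnegative && any(m[finite] < 0))
    abort("Negative entries in a non-negative distance matrix.")
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

dm_labels <- function(m) rownames(m)

check_matching_labels <- function(a, b, what = "matrices") {
  if (!identical(dm_labels(a), dm_labels(b)))
    abort(paste0("Labels of ", what, " do not match."))
  invisible(TRUE)
}

#' Lower-triangle pairs of a distance matrix as a tibble
#'
#' @param m a square named matrix.
#' @param value name for the value column.
#' @return a tibble with columns `sample_1`, `sample_2`, and `value`.
#' @export
dm_pairs <- function(m, value = "value") {
  lab <- rownames(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  out <- tibble(
    sample_1 = lab[idx[, 2L]],
    sample_2 = lab[idx[, 1L]],
    value = m[idx]
  )
  names(out)[3L] <- value
  out
}

lower_vec <- function(m) m[lower.tri(m)]
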