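#' Symmetric pairwise distance matrix
#'
#' Thin wrapper around a base matrix that enforces the pairwise-distance
#' contract used throughout the pipeline: square, symmetric (to 1e-12), zero
#' diagonal, labelled by sample ids, and tagged with units — `"km"` for
#' geographic distances, `"dissimilarity"` for community dissimilarities
#' (values then checked to lie in `[0, 1]` up to numerical slack).
#'
#' @param values Square numeric matrix with identical row and column names.
#' @param units `"dissimilarity"`, `"km"`, or `"raw"` (unbounded
#'   branch-length or other scale; no `[0, 1]` check).
#' @return A `dist_matrix` (a classed matrix; use [as.matrix()] or
#'   [stats::as.dist()] to strip it down).
#' @export
dist_matrix <- function(values, units = c("dissimilarity", "km", "raw")) {
  units <- match.arg(units)
  check_that(is.matrix(values) && is.numeric(values) &&
               nrow(values) == ncol(values),
             "`values` must be a square numeric matrix")
  check_that(!is.null(rownames(values)) &&
               identical(rownames(values), colnames(values)),
             "row and column names must be identical sample ids")
  check_that(!anyNA(values), "distances must be non-missing")
  check_that(max(abs(values - t(values))) <= 1e-12,
             "matrix is not symmetric (tolerance 1e-12)")
  check_that(all(diag(values) == 0), "diagonal must be exactly zero")
  check_that(all(values >= 0), "distances must be non-negative")
  if (units == "dissimilarity") {
    check_that(all(values <= 1 + 1e-12),
               "dissimilarities must lie in [0, 1]")
  }
  values <- (values + t(values)) / 2  # exact symmetry
  structure(values, units = units, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, units = %s\n", nrow(x),
              attr(x, "units")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))],
        ...)
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "units") <- NULL
  y
}

# units tag of a dist_matrix
dist_units <- function(x) attr(x, "units") %||% "dissimilarity"

# coerce any of: dist_matrix, dist, plain symmetric matrix
as_dist_matrix <- function(x, units = "dissimilarity") {
  if (inherits(x, "dist_matrix")) return(x)
  if (inherits(x, "dist")) {
    m <- as.matrix(x)
    if (is.null(rownames(m))) {
      rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
    }
    return(dist_matrix(m, units = units))
  }
  dist_matrix(as.matrix(x), units = units)
}

# check two distance matrices cover the same samples, align the second
align_dist <- function(d1, d2) {
  ids <- rownames(d1)
  check_that(setequal(ids, rownames(d2)),
             "distance matrices cover different sample sets")
  m2 <- as.matrix(d2)[ids, ids]
  list(d1 = as.matrix(d1), d2 = m2, ids = ids)
}

#' Long-format view of a distance matrix
#'
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered sample pair
#'   (`sample_1`, `sample_2`, `value`).
#' @export
as_tibble.dist_matrix <- function(x, ...) {
  m <- as.matrix(x)
  out <- pair_index(rownames(m))
  out$value <- upper_tri_vec(m)
  out
}
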