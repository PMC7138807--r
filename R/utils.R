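#' @importFrom rlang abort warn %||%
#' @importFrom stats cor sd var quantile setNames
NULL

# stop unless `cond`, with a caller-facing message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Derive a stage-specific child seed from a master seed
#'
#' Stages of the pipeline each consume their own RNG seed so that any stage
#' can be re-run in isolation and reproduce the full-run result. The child
#' seed is a deterministic 31-bit hash of the master seed and the stage label.
#'
#' @param seed Master seed (single integer).
#' @param stage Stage label (single string).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  check_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "`seed` must be a single finite number")
  check_that(is.character(stage) && length(stage) == 1L,
             "`stage` must be a single string")
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# run code under a local RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# upper-triangle (i < j) of a square matrix as a vector, column-major
upper_tri_vec <- function(m) m[upper.tri(m)]

# tibble of unordered sample pairs aligned with upper_tri_vec()
pair_index <- function(ids) {
  n <- length(ids)
  j <- rep(seq_len(n), each = n)[upper.tri(diag(n))]
  i <- rep(seq_len(n), times = n)[upper.tri(diag(n))]
  tibble::tibble(sample_1 = ids[i], sample_2 = ids[j])
}
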