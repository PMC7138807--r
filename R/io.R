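#' Read a classic tab-separated OTU table
#'
#' Reads the QIIME-era classic dialect: rows are OTUs, columns are samples,
#' the first column holds OTU ids, and an optional final column named
#' `taxonomy` carries semicolon-delimited lineage strings. The table is
#' transposed internally so the package always works samples x OTUs.
#'
#' @param path Path to a tab-separated file. A leading `#` on the header
#'   line (classic `#OTU ID`) is tolerated.
#' @param format Input dialect; only `"tsv_classic"` is supported.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv_classic")) {
  format <- match.arg(format)
  check_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]  # comment lines
  check_that(length(lines) >= 1L, "empty OTU table file")
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          colClasses = "character", quote = "")
  names(df)[1] <- sub("^#", "", names(df)[1])
  has_tax <- tolower(names(df)[ncol(df)]) == "taxonomy" && ncol(df) > 1L
  tax <- if (has_tax) df[[ncol(df)]] else NULL
  count_cols <- setdiff(seq_along(df), c(1L, if (has_tax) ncol(df)))
  otu_ids <- df[[1]]
  sample_ids <- names(df)[count_cols]
  check_that(!anyDuplicated(otu_ids),
             "duplicate OTU ids in first column")
  check_that(!anyDuplicated(sample_ids), "duplicate sample ids in header")

  counts <- matrix(0, nrow = length(otu_ids), ncol = length(count_cols),
                   dimnames = list(otu_ids, sample_ids))
  for (jj in seq_along(count_cols)) {
    v <- suppressWarnings(as.numeric(df[[count_cols[jj]]]))
    if (anyNA(v)) abort(sprintf(
      "non-numeric count in sample column '%s'", names(df)[count_cols[jj]]))
    counts[, jj] <- v
  }
  if (any(counts < 0)) abort("negative counts in OTU table")
  if (any(counts != round(counts)))
    abort("non-integer counts: relative-abundance input is not accepted")
  otu_table(t(counts), lineages = tax)
}

#' Write an OTU table in the classic dialect
#'
#' Inverse of [read_otu_table()]: rows = OTUs, columns = samples, optional
#' trailing `taxonomy` column. Counts, ids and lineage strings round-trip
#' exactly.
#'
#' @param table An [otu_table].
#' @param path Output path (tab-delimited, UTF-8).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  m <- t(table$counts)  # OTUs x samples
  df <- data.frame(`#OTU ID` = rownames(m) %||% character(0),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  if (!is.null(table$lineages)) {
    df$taxonomy <- format_lineage(table$lineages)
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read per-site metadata
#'
#' Expects a tab-separated table with columns `sample_id`, `latitude`,
#' `longitude`, any number of numeric environmental covariates (pH, AK, OC,
#' TN, AN, AP, PRE, TEM, ...), and an optional categorical `soil_type`.
#'
#' @param path Path to a TSV file.
#' @return A `site_metadata` tibble (one row per sample).
#' @export
read_metadata <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  site_metadata(df)
}

#' Validate a site-metadata table
#'
#' @param df A data frame with `sample_id`, `latitude` and `longitude`
#'   columns; remaining numeric columns are treated as environmental
#'   covariates.
#' @return The validated tibble with class `site_metadata`.
#' @export
site_metadata <- function(df) {
  df <- tibble::as_tibble(df)
  for (col in c("sample_id", "latitude", "longitude")) {
    check_that(col %in% names(df),
               sprintf("metadata is missing required column '%s'", col))
  }
  df$sample_id <- as.character(df$sample_id)
  check_that(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  check_that(all(is.finite(df$latitude)) &&
               all(df$latitude >= -90 & df$latitude <= 90),
             "latitude out of range [-90, 90]")
  check_that(all(is.finite(df$longitude)) &&
               all(df$longitude >= -180 & df$longitude <= 180),
             "longitude out of range [-180, 180]")
  class(df) <- c("site_metadata", class(df))
  df
}

#' @export
print.site_metadata <- function(x, ...) {
  cat(sprintf("<site_metadata> %d sites, covariates: %s\n", nrow(x),
              paste(env_covariates(x), collapse = ", ")))
  NextMethod()
}

#' Names of the environmental covariate columns in a metadata table
#' @param metadata A `site_metadata` tibble.
#' @export
env_covariates <- function(metadata) {
  num <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  setdiff(num, c("latitude", "longitude"))
}

#' Write site metadata as TSV
#' @param metadata A `site_metadata` tibble.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(tibble::as_tibble(metadata), path, progress = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' @param path Path to a single-tree newick file.
#' @return An [ape::phylo] tree with finite non-negative branch lengths;
#'   missing branch lengths are set to 0 with a warning.
#' @export
read_newick <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  check_that(!anyDuplicated(tree$tip.label), "duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warn("missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  check_that(all(is.finite(tree$edge.length)) && all(tree$edge.length >= 0),
             "branch lengths must be finite and non-negative")
  tree
}

#' Write / read a distance matrix as square TSV
#'
#' Square layout with a header row and a leading column of sample ids.
#'
#' @param d A distance matrix as produced by [dist_matrix()].
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns a [dist_matrix()].
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param units Units tag to attach on read (`"dissimilarity"` or `"km"`).
#' @export
read_distance_matrix <- function(path, units = "dissimilarity") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  dist_matrix(m, units = units)
}
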