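#' OTU count table
#'
#' The central observational object of the pipeline: a samples-by-OTUs matrix
#' of non-negative integer counts, with optional per-OTU taxonomy lineages.
#'
#' @param counts Numeric matrix, samples in rows and OTUs in columns, with
#'   row and column names. All entries must be non-negative whole numbers;
#'   relative-abundance input is rejected because rarefaction needs counts
#'   (normalisation is an explicit, separate pipeline step).
#' @param lineages Optional taxonomy: either a character vector of
#'   greengenes/SILVA-style lineage strings (`"k__Bacteria; p__..."`), one
#'   per OTU, or a data frame as returned by [parse_lineage()] with an
#'   `otu_id` column.
#' @return An `otu_table` object.
#' @seealso [read_otu_table()], [relative_abundance()], [parse_lineage()]
#' @export
otu_table <- function(counts, lineages = NULL) {
  check_that(is.matrix(counts) && is.numeric(counts),
             "`counts` must be a numeric matrix (samples x OTUs)")
  check_that(!is.null(rownames(counts)) &&
               (ncol(counts) == 0L || !is.null(colnames(counts))),
             "`counts` must have sample ids as rownames and OTU ids as colnames")
  check_that(!anyDuplicated(rownames(counts)), "duplicate sample ids")
  check_that(!anyDuplicated(colnames(counts)), "duplicate OTU ids")
  check_that(!anyNA(counts) && all(counts >= 0),
             "counts must be non-negative and non-missing")
  check_that(all(counts == round(counts)),
             "counts must be whole numbers; normalise explicitly, not on input")
  storage.mode(counts) <- "double"

  if (!is.null(lineages)) {
    if (is.character(lineages)) {
      check_that(length(lineages) == ncol(counts),
                 "one lineage string per OTU required")
      lineages <- dplyr::bind_cols(
        tibble::tibble(otu_id = colnames(counts)),
        parse_lineage(lineages)
      )
    } else {
      lineages <- tibble::as_tibble(lineages)
      check_that("otu_id" %in% names(lineages),
                 "`lineages` data frame needs an `otu_id` column")
      check_that(setequal(lineages$otu_id, colnames(counts)) &&
                   !anyDuplicated(lineages$otu_id),
                 "`lineages` must cover each OTU exactly once")
      lineages <- lineages[match(colnames(counts), lineages$otu_id), ]
    }
  }
  structure(list(counts = counts, lineages = lineages), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs%s\n",
              n_samples(x), n_taxa(x),
              if (is.null(x$lineages)) "" else ", with taxonomy"))
  cat(sprintf("  total counts: %s; per-sample depth %s-%s\n",
              format(sum(x$counts), big.mark = ","),
              format(min(rowSums(x$counts)), big.mark = ","),
              format(max(rowSums(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_taxa <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' Total-sum-scaled view of an OTU table
#'
#' Converts counts to proportions by dividing each sample's counts by its
#' library size, so every row sums to 1.
#'
#' @param x An `otu_table`.
#' @return A numeric matrix (samples x OTUs) of relative abundances.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  bad <- tot == 0
  if (any(bad)) {
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(x$counts)[bad], collapse = ", ")))
  }
  x$counts / tot
}

# subset an otu_table to a set of OTU ids (order preserved as given)
subset_taxa <- function(x, otu_ids) {
  stopifnot(inherits(x, "otu_table"))
  check_that(all(otu_ids %in% taxon_ids(x)), "unknown OTU ids in subset")
  lin <- x$lineages
  if (!is.null(lin)) lin <- lin[match(otu_ids, lin$otu_id), ]
  structure(list(counts = x$counts[, otu_ids, drop = FALSE], lineages = lin),
            class = "otu_table")
}

#' @export
as_tibble.otu_table <- function(x, ...) {
  long <- tibble::as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "count")
  if (!is.null(x$lineages)) long <- dplyr::left_join(long, x$lineages,
                                                     by = "otu_id")
  long
}

#' Canonical taxonomy ranks handled by the lineage parser
#' @export
lineage_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse greengenes/SILVA-style lineage strings
#'
#' Splits semicolon-delimited lineage strings with `k__/p__/c__/o__/f__/g__`
#' rank prefixes (matched case-insensitively) into one column per rank,
#' kingdom through genus. An empty name after a prefix, or a rank absent from
#' the string, is recorded as `NA` (unassigned). Ranks below genus (e.g.
#' `s__`) are ignored.
#'
#' @param strings Character vector of lineage strings.
#' @return A tibble with columns `kingdom` ... `genus`.
#' @export
parse_lineage <- function(strings) {
  prefixes <- c(kingdom = "k", phylum = "p", class = "c",
                order = "o", family = "f", genus = "g")
  out <- matrix(NA_character_, nrow = length(strings),
                ncol = length(lineage_ranks),
                dimnames = list(NULL, lineage_ranks))
  for (i in seq_along(strings)) {
    s <- strings[i]
    if (is.na(s) || !nzchar(trimws(s))) next
    tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    last_rank <- 0L
    for (tok in tokens) {
      if (!nzchar(tok)) next
      m <- regmatches(tok, regexec("^([A-Za-z])__(.*)$", tok))[[1]]
      if (length(m) == 3L) {
        rank <- names(prefixes)[match(tolower(m[2]), prefixes)]
        if (is.na(rank)) next  # sub-genus ranks ignored
        name <- trimws(m[3])
        out[i, rank] <- if (nzchar(name)) name else NA_character_
        last_rank <- match(rank, lineage_ranks)
      } else {
        # bare names fill ranks positionally, in canonical order
        if (last_rank >= length(lineage_ranks)) {
          abort(sprintf("cannot place lineage token '%s' in '%s'", tok, s))
        }
        last_rank <- last_rank + 1L
        out[i, last_rank] <- tok
      }
    }
  }
  tibble::as_tibble(out)
}

#' Format lineages back into prefixed strings
#'
#' Inverse of [parse_lineage()]: emits ranks up to the deepest assigned one,
#' writing unassigned intermediate ranks as a bare prefix (`"c__"`), so that
#' `parse_lineage(format_lineage(x))` reproduces `x` for any rank subset.
#'
#' @param lineages A data frame with columns `kingdom` ... `genus`.
#' @return A character vector of lineage strings (`""` when no rank is
#'   assigned).
#' @export
format_lineage <- function(lineages) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  vapply(seq_len(nrow(lineages)), function(i) {
    vals <- as.character(unlist(lineages[i, lineage_ranks]))
    deepest <- max(c(0L, which(!is.na(vals))))
    if (deepest == 0L) return("")
    paste0(prefixes[seq_len(deepest)],
           ifelse(is.na(vals[seq_len(deepest)]), "",
                  vals[seq_len(deepest)]),
           collapse = "; ")
  }, character(1))
}
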