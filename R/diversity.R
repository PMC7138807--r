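#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads, removing library-size effects before diversity and dissimilarity
#' calculations. A single seeded draw at the minimum library size is the
#' pipeline default; `n_iter > 1` returns the element-wise mean of repeated
#' draws (no longer integer counts, diagnostic use only).
#'
#' @param table An [otu_table].
#' @param depth Target depth; defaults to the minimum per-sample total.
#' @param seed RNG seed for the draw.
#' @param n_iter Number of independent draws to average.
#' @return An [otu_table] whose rows each sum to `depth` (for `n_iter = 1`),
#'   or a numeric matrix of averaged counts otherwise.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L, n_iter = 1L) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  depth <- depth %||% min(totals)
  short <- totals < depth
  if (any(short)) {
    abort(sprintf("rarefaction depth %s exceeds the total of sample(s): %s",
                  format(depth), paste(names(totals)[short], collapse = ", ")))
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      vegan::rrarefy(table$counts, depth)
    })
  })
  if (n_iter == 1L) {
    otu_table(draws[[1]], lineages = table$lineages)
  } else {
    Reduce(`+`, draws) / n_iter
  }
}

#' Alpha diversity: observed richness and Shannon index
#'
#' Richness is the number of OTUs with nonzero count; the Shannon-Wiener
#' index is computed in natural log (nats) on within-sample proportions.
#'
#' @param table An [otu_table].
#' @return A tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  check_that(n_samples(table) >= 1L, "table has no samples")
  check_that(all(rowSums(table$counts) > 0), "all-zero sample in table")
  tibble::tibble(
    sample_id = sample_ids(table),
    richness  = as.integer(vegan::specnumber(table$counts)),
    shannon   = as.numeric(vegan::diversity(table$counts, index = "shannon"))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`. Computed on
#' total-sum-scaled relative abundances by default; `on = "counts"` uses the
#' raw (typically rarefied) counts, the mode the partitioned core statistic
#' shares.
#'
#' @param table An [otu_table].
#' @param on `"relative"` or `"counts"`.
#' @return A [dist_matrix] with units `"dissimilarity"`.
#' @export
bray_curtis <- function(table, on = c("relative", "counts")) {
  on <- match.arg(on)
  stopifnot(inherits(table, "otu_table"))
  check_that(n_samples(table) >= 2L, "need at least 2 samples")
  check_that(all(rowSums(table$counts) > 0),
             "sample with zero total counts")
  x <- if (on == "relative") relative_abundance(table) else table$counts
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  diag(d) <- 0
  d[d > 1] <- 1
  dist_matrix(d, units = "dissimilarity")
}

#' Weighted UniFrac distance between samples
#'
#' For each branch `b` with length `l_b`, let `A_b` and `B_b` be the
#' fractions of the two samples' total abundance descending from `b`; the
#' raw weighted UniFrac distance is `sum_b l_b |A_b - B_b|`. The normalized
#' variant divides by the pair's maximum attainable value,
#' `sum_i d_i (p_i + q_i)` with `d_i` the root-to-tip distance of tip `i`,
#' giving values in `[0, 1]` (the pipeline default, since distance-decay
#' works on `1 - dissimilarity`).
#'
#' @param table An [otu_table]; every OTU with a nonzero count must be a
#'   tree leaf.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param normalized Divide by the per-pair maximum (default `TRUE`).
#' @return A [dist_matrix] with units `"dissimilarity"` (normalized) or the
#'   raw branch-length scale.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  tree <- validate_tree(tree)
  present <- taxon_ids(table)[colSums(table$counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0L) {
    abort(sprintf("OTUs absent from the tree: %s%s",
                  paste(utils::head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  p <- relative_abundance(table)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # per-sample abundance fraction below every node, by postorder accumulation
  frac <- matrix(0, nrow = n_samples(table), ncol = ntip + nnode)
  shared <- intersect(tree$tip.label, colnames(p))
  frac[, match(shared, tree$tip.label)] <- p[, shared, drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    frac[, po$edge[e, 1]] <- frac[, po$edge[e, 1]] + frac[, po$edge[e, 2]]
  }
  ed_child <- po$edge[, 2]
  ed_len <- po$edge.length
  n <- n_samples(table)
  d <- matrix(0, n, n, dimnames = list(sample_ids(table), sample_ids(table)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      d[j, k] <- d[k, j] <-
        sum(ed_len * abs(frac[j, ed_child] - frac[k, ed_child]))
    }
  }
  if (normalized) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    depth_shared <- depth[match(shared, tree$tip.label)]
    s <- as.numeric(p[, shared, drop = FALSE] %*% depth_shared)
    denom <- outer(s, s, `+`)
    nz <- denom > 0
    d[nz] <- d[nz] / denom[nz]
    diag(d) <- 0
    d[d > 1] <- 1
    dist_matrix(d, units = "dissimilarity")
  } else {
    dist_matrix(d, units = "raw")
  }
}
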