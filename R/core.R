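#' Detect the core microbiome
#'
#' The core microbiome is the set of OTUs whose prevalence (fraction of
#' samples with a nonzero count) is at least `prevalence`; the default 1.0
#' requires presence in every sample.
#'
#' @param table An [otu_table].
#' @param prevalence Prevalence threshold in `(0, 1]`.
#' @return A `core_set` object with the core OTU ids, the threshold, the
#'   per-OTU prevalence table, and (when lineages are present) the per-genus
#'   aggregation of core membership.
#' @export
find_core <- function(table, prevalence = 1.0) {
  stopifnot(inherits(table, "otu_table"))
  check_that(n_taxa(table) > 0L && n_samples(table) > 0L, "empty table")
  check_that(prevalence > 0 && prevalence <= 1,
             "`prevalence` must be in (0, 1]")
  prev <- colMeans(table$counts > 0)
  core_ids <- taxon_ids(table)[prev >= prevalence]
  genus_summary <- NULL
  if (!is.null(table$lineages)) {
    genus_summary <- table$lineages |>
      dplyr::mutate(core = .data$otu_id %in% core_ids) |>
      dplyr::filter(!is.na(.data$genus)) |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(n_otus = dplyr::n(), n_core = sum(.data$core),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n_core))
  }
  structure(list(
    otu_ids = core_ids,
    threshold = prevalence,
    prevalence = tibble::tibble(otu_id = taxon_ids(table),
                                prevalence = unname(prev)),
    genus_summary = genus_summary,
    n_taxa_total = n_taxa(table)
  ), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d core OTUs of %d (%.2f%%) at prevalence >= %g\n",
              length(x$otu_ids), x$n_taxa_total,
              100 * length(x$otu_ids) / x$n_taxa_total, x$threshold))
  invisible(x)
}

#' Fraction of total OTU richness held by a core set
#'
#' @param core A `core_set`.
#' @return Core fraction in percent.
#' @export
core_fraction <- function(core) {
  stopifnot(inherits(core, "core_set"))
  100 * length(core$otu_ids) / core$n_taxa_total
}

#' Partitioned Bray-Curtis contribution of the core microbiome
#'
#' For each sample pair, the partitioned dissimilarity restricts the
#' Bray-Curtis numerator to the core taxa while the denominator scales over
#' all taxa:
#' `BC_core(j,k) = sum_{i in core} |x_ij - x_ik| / sum_{i in all} (x_ij + x_ik)`.
#' The contribution fraction is `BC_core / BC_all`, the share of each pair's
#' community dissimilarity attributable to the core. Numerators are additive
#' over any disjoint partition of taxa, so contribution fractions over a
#' partition sum to 1 for every pair.
#'
#' @param table An [otu_table] (typically rarefied counts).
#' @param core A `core_set` or a character vector of core OTU ids (must be a
#'   subset of the table's OTUs).
#' @param on `"counts"` (default, for rarefied tables) or `"relative"`.
#' @return A `core_contribution` object: per-pair tibble plus mean and range
#'   of the contribution fraction. Pairs with `BC_all = 0` are excluded with
#'   a warning.
#' @export
core_contribution <- function(table, core, on = c("counts", "relative")) {
  on <- match.arg(on)
  stopifnot(inherits(table, "otu_table"))
  core_ids <- if (inherits(core, "core_set")) core$otu_ids else core
  check_that(all(core_ids %in% taxon_ids(table)),
             "core contains OTUs absent from the table")
  x <- if (on == "relative") relative_abundance(table) else table$counts
  is_core <- taxon_ids(table) %in% core_ids
  n <- nrow(x)
  check_that(n >= 2L, "need at least 2 samples")

  pairs <- pair_index(rownames(x))
  num_core <- num_all <- denom <- numeric(nrow(pairs))
  idx <- 0L
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      idx <- idx + 1L
      diffs <- abs(x[j, ] - x[k, ])
      num_core[idx] <- sum(diffs[is_core])
      num_all[idx] <- sum(diffs)
      denom[idx] <- sum(x[j, ] + x[k, ])
    }
  }
  # pair_index runs column-major over the upper triangle; the double loop
  # above runs row-major, so rebuild the pair labels to match
  pairs <- tidyr::expand_grid(a = seq_len(n), b = seq_len(n)) |>
    dplyr::filter(.data$a < .data$b) |>
    dplyr::transmute(sample_1 = rownames(x)[.data$a],
                     sample_2 = rownames(x)[.data$b])

  check_that(all(denom > 0), "sample pair with zero combined total")
  bc_core <- num_core / denom
  bc_all <- num_all / denom
  ok <- bc_all > 0
  if (!all(ok)) {
    warn(sprintf("%d pair(s) with zero Bray-Curtis dissimilarity excluded",
                 sum(!ok)))
  }
  frac <- ifelse(ok, bc_core / bc_all, NA_real_)
  tab <- dplyr::mutate(pairs, bc_core = bc_core, bc_all = bc_all,
                       contribution = frac)
  structure(list(
    pairs = tab,
    mean_pct = mean(100 * frac[ok]),
    range_pct = range(100 * frac[ok]),
    n_core = sum(is_core),
    on = on
  ), class = "core_contribution")
}

#' @export
print.core_contribution <- function(x, ...) {
  cat(sprintf(
    "<core_contribution> %d core taxa: mean %.2f%% (range %.2f-%.2f%%) of pairwise dissimilarity\n",
    x$n_core, x$mean_pct, x$range_pct[1], x$range_pct[2]))
  invisible(x)
}

#' Correlations between core genera and environmental factors
#'
#' Aggregates core OTUs to genus level (relative abundance within the whole
#' community), computes the Spearman correlation of each core genus against
#' each environmental covariate, applies Benjamini-Hochberg FDR across all
#' genus-by-covariate tests, and retains only cells that are both strong
#' (`|r| > r_min`) and significant (`q < alpha`) — the heatmap contract:
#' everything else is masked.
#'
#' @param table An [otu_table] with lineages.
#' @param core A `core_set`.
#' @param metadata A `site_metadata` tibble covering the table's samples.
#' @param r_min Minimum absolute Spearman correlation to retain.
#' @param alpha FDR threshold.
#' @return A `core_env_cor` object: long tibble with `genus`, `covariate`,
#'   `r`, `p`, `q`, `retained`; constant covariates are dropped with a
#'   warning.
#' @export
core_env_correlations <- function(table, core, metadata, r_min = 0.6,
                                  alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"), inherits(core, "core_set"))
  check_that(!is.null(table$lineages), "table has no taxonomy lineages")
  metadata <- site_metadata(metadata)
  ids <- sample_ids(table)
  check_that(all(ids %in% metadata$sample_id),
             "metadata does not cover all samples")
  metadata <- metadata[match(ids, metadata$sample_id), ]

  lin <- table$lineages
  core_genera <- lin$genus[lin$otu_id %in% core$otu_ids & !is.na(lin$genus)]
  core_genera <- unique(core_genera)
  check_that(length(core_genera) > 0L, "no genus-assigned core OTUs")

  rel <- relative_abundance(table)
  genus_ab <- vapply(core_genera, function(g) {
    members <- lin$otu_id[!is.na(lin$genus) & lin$genus == g &
                            lin$otu_id %in% core$otu_ids]
    rowSums(rel[, members, drop = FALSE])
  }, numeric(length(ids)))

  covs <- env_covariates(metadata)
  keep <- vapply(covs, function(v) stats::sd(metadata[[v]]) > 0, logical(1))
  if (!all(keep)) {
    warn(sprintf("constant covariate(s) dropped: %s",
                 paste(covs[!keep], collapse = ", ")))
  }
  covs <- covs[keep]
  check_that(length(covs) > 0L, "no usable environmental covariates")

  grid <- tidyr::expand_grid(genus = core_genera, covariate = covs)
  res <- purrr::pmap(grid, function(genus, covariate) {
    ct <- suppressWarnings(
      stats::cor.test(genus_ab[, genus], metadata[[covariate]],
                      method = "spearman", exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  grid$r <- vapply(res, `[[`, numeric(1), "r")
  grid$p <- vapply(res, `[[`, numeric(1), "p")
  grid$q <- fdr_adjust(grid$p)
  grid$retained <- abs(grid$r) > r_min & grid$q < alpha
  structure(list(table = grid, r_min = r_min, alpha = alpha,
                 genera = core_genera, covariates = covs),
            class = "core_env_cor")
}

#' @export
print.core_env_cor <- function(x, ...) {
  cat(sprintf(
    "<core_env_cor> %d core genera x %d covariates; %d cell(s) retained (|r| > %g, q < %g)\n",
    length(x$genera), length(x$covariates), sum(x$table$retained),
    x$r_min, x$alpha))
  invisible(x)
}
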