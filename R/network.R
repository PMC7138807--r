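#' Pairwise Spearman correlations between taxa
#'
#' Computes tie-corrected Spearman correlations on total-sum-scaled relative
#' abundances (rank-then-Pearson on each taxon's cross-sample profile) and
#' two-sided p-values from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. Taxa with zero
#' cross-sample variance are excluded and reported.
#'
#' @param table An [otu_table] with at least 5 samples.
#' @param method Only `"spearman"` is implemented.
#' @param min_prevalence Drop taxa detected in fewer than this fraction of
#'   samples before correlating (default 0 = keep all). Sparse taxa produce
#'   heavy rank ties whose correlations and t-approximate p-values are
#'   unreliable; filtering them is standard co-occurrence practice.
#' @return A list with elements `r` and `p` (symmetric matrices over the
#'   retained taxa, unit/NA diagonal) and `dropped` (zero-variance or
#'   low-prevalence taxon ids).
#' @export
correlation_matrix <- function(table, method = c("spearman"),
                               min_prevalence = 0) {
  method <- match.arg(method)
  stopifnot(inherits(table, "otu_table"))
  n <- n_samples(table)
  check_that(n >= 5L,
             "need at least 5 samples for the p-value approximation")
  x <- relative_abundance(table)
  vars <- apply(x, 2, stats::var)
  prev <- colMeans(table$counts > 0)
  keep <- vars > 0 & prev >= min_prevalence
  dropped <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  check_that(ncol(x) >= 2L, "fewer than 2 taxa with nonzero variance")
  rk <- apply(x, 2, rank)
  r <- stats::cor(rk)
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA_real_
  list(r = r, p = p, dropped = dropped)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up control of the false discovery rate. Accepts a vector, or a
#' symmetric p-value matrix in which case the adjustment is applied over the
#' flattened upper triangle and mirrored back.
#'
#' @param p P-values in `[0, 1]` (NAs preserved).
#' @param method Only `"BH"`.
#' @return Adjusted q-values, same shape as the input.
#' @export
fdr_adjust <- function(p, method = c("BH")) {
  method <- match.arg(method)
  if (is.matrix(p)) {
    check_that(nrow(p) == ncol(p), "p-value matrix must be square")
    ut <- upper.tri(p)
    vals <- p[ut]
    check_that(all(is.na(vals) | (vals >= 0 & vals <= 1)),
               "p-values must lie in [0, 1]")
    q <- p
    q[ut] <- stats::p.adjust(vals, method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    q
  } else {
    check_that(all(is.na(p) | (p >= 0 & p <= 1)),
               "p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
  }
}

#' Build a thresholded co-occurrence network
#'
#' An undirected simple graph with an edge between two taxa iff their
#' correlation is strictly positive and strong (r above `r_min`) and
#' FDR-significant (q below `q_max`); negative correlations are excluded by
#' default, matching the strict positive-correlation criterion (set
#' `use_absolute = TRUE` for a `|r|` sensitivity analysis). Nodes carry
#' taxonomy and core-membership annotations; edges carry `r` and `q`.
#'
#' @param r,q Aligned symmetric correlation and q-value matrices, as from
#'   [correlation_matrix()] and [fdr_adjust()].
#' @param r_min,q_max Edge thresholds (defaults 0.6 and 0.01).
#' @param lineages Optional lineage tibble (`otu_id`, `phylum`, `genus`, ...)
#'   for node annotation.
#' @param core Optional `core_set` or character vector of core taxon ids.
#' @param drop_isolated Drop nodes with no edges (default keeps them).
#' @param use_absolute Threshold on `|r|` instead of `r`.
#' @return An [igraph::igraph] graph with vertex attributes `name`,
#'   `phylum`, `genus`, `core` and edge attributes `r`, `q`.
#' @export
build_network <- function(r, q, r_min = 0.6, q_max = 0.01, lineages = NULL,
                          core = NULL, drop_isolated = FALSE,
                          use_absolute = FALSE) {
  check_that(is.matrix(r) && is.matrix(q) &&
               identical(dim(r), dim(q)) &&
               identical(rownames(r), rownames(q)),
             "r and q matrices are not aligned")
  check_that(!is.null(rownames(r)), "correlation matrix must be labelled")
  taxa <- rownames(r)
  rv <- if (use_absolute) abs(r) else r
  keep <- rv > r_min & q < q_max
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]),
                           r = r[idx], q = q[idx])
  }
  if (!is.null(lineages)) {
    pos <- match(taxa, lineages$otu_id)
    for (col in intersect(c("phylum", "genus"), names(lineages))) {
      g <- igraph::set_vertex_attr(g, col, value = lineages[[col]][pos])
    }
  }
  if (!is.null(core)) {
    core_ids <- if (inherits(core, "core_set")) core$otu_ids else core
    g <- igraph::set_vertex_attr(g, "core", value = taxa %in% core_ids)
  }
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  g
}

#' Aggregate an OTU table to genus level
#'
#' Sums counts over OTUs sharing an assigned genus; OTUs without a genus
#' assignment are dropped (their number and count share is reported in a
#' message). Total assigned counts are conserved.
#'
#' @param table An [otu_table] with lineages.
#' @return An [otu_table] whose taxa are genera; each genus keeps a lineage
#'   row with the most frequent phylum among its member OTUs.
#' @export
aggregate_to_genus <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  check_that(!is.null(table$lineages), "table has no taxonomy lineages")
  lin <- table$lineages
  assigned <- !is.na(lin$genus)
  check_that(any(assigned), "no genus assignments in table")
  n_drop <- sum(!assigned)
  if (n_drop > 0) {
    message(sprintf("dropping %d OTUs without genus assignment (%.1f%% of counts)",
                    n_drop,
                    100 * sum(table$counts[, lin$otu_id[!assigned],
                                           drop = FALSE]) /
                      sum(table$counts)))
  }
  genera <- sort(unique(lin$genus[assigned]))
  counts <- vapply(genera, function(g) {
    members <- lin$otu_id[assigned & lin$genus == g]
    rowSums(table$counts[, members, drop = FALSE])
  }, numeric(n_samples(table)))
  counts <- matrix(counts, nrow = n_samples(table),
                   dimnames = list(sample_ids(table), genera))
  glin <- lin[assigned, ] |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      phylum = names(sort(table(.data$phylum), decreasing = TRUE))[1],
      .groups = "drop") |>
    dplyr::transmute(otu_id = .data$genus, kingdom = NA_character_,
                     phylum = .data$phylum, class = NA_character_,
                     order = NA_character_, family = NA_character_,
                     genus = .data$genus)
  otu_table(counts, lineages = glin)
}

#' Network-level topology summary
#'
#' Average path length (APL) and network diameter (ND) are computed over
#' connected node pairs only (the disconnected-pair fraction is reported);
#' graph density GD = 2m/(n(n-1)); the clustering coefficient CC is the mean
#' local clustering over nodes of degree >= 2.
#'
#' @param network An undirected [igraph::igraph] graph.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `mean_degree`, `apl`,
#'   `diameter`, `density`, `clustering`, `frac_disconnected_pairs`.
#' @export
topology <- function(network) {
  stopifnot(inherits(network, "igraph"))
  n <- igraph::vcount(network)
  check_that(n >= 2L, "need at least 2 nodes")
  m <- igraph::ecount(network)
  apl <- if (m > 0) igraph::mean_distance(network, unconnected = TRUE)
         else NA_real_
  nd <- if (m > 0) igraph::diameter(network, unconnected = TRUE)
        else NA_real_
  cc <- igraph::transitivity(network, type = "localaverage",
                             isolates = "NaN")
  if (is.nan(cc)) cc <- NA_real_
  comp <- igraph::components(network)
  n_conn_pairs <- sum(choose(comp$csize, 2))
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    mean_degree = 2 * m / n,
    apl = apl,
    diameter = as.numeric(nd),
    density = 2 * m / (n * (n - 1)),
    clustering = cc,
    frac_disconnected_pairs = 1 - n_conn_pairs / choose(n, 2)
  )
}

#' Erdős–Rényi G(n,m) null ensemble
#'
#' Generates uniform random simple graphs with the observed node and edge
#' counts and summarises their topology, the standard null against which a
#' co-occurrence network's structure is judged. Metrics can be restricted
#' (path-based metrics dominate the cost on large graphs).
#'
#' @param n_nodes,n_edges Size of the observed network.
#' @param n_reps Number of replicate graphs (the conventional ensemble is
#'   10,000; far fewer suffice for means and modal diameter).
#' @param seed RNG seed.
#' @param metrics Character subset of `c("apl", "diameter", "clustering",
#'   "density")`.
#' @return An `er_ensemble` object: per-replicate tibble `replicates`,
#'   `summary` (mean/sd per metric), and the analytic expectations
#'   `expected_density` (= expected clustering for G(n,m)).
#' @export
er_null_ensemble <- function(n_nodes, n_edges, n_reps = 10000, seed = 1L,
                             metrics = c("apl", "diameter", "clustering",
                                         "density")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  check_that(n_edges <= n_nodes * (n_nodes - 1) / 2,
             "more edges than a simple graph allows")
  reps <- with_seed(seed, {
    purrr::map(seq_len(n_reps), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      out <- list(replicate = i, n_edges = igraph::ecount(g))
      if ("apl" %in% metrics) {
        out$apl <- igraph::mean_distance(g, unconnected = TRUE)
      }
      if ("diameter" %in% metrics) {
        out$diameter <- as.numeric(igraph::diameter(g, unconnected = TRUE))
      }
      if ("clustering" %in% metrics) {
        out$clustering <- igraph::transitivity(g, type = "localaverage",
                                               isolates = "NaN")
      }
      if ("density" %in% metrics) {
        out$density <- 2 * igraph::ecount(g) / (n_nodes * (n_nodes - 1))
      }
      tibble::as_tibble(out)
    })
  })
  reps <- dplyr::bind_rows(reps)
  num <- setdiff(names(reps), c("replicate"))
  summ <- reps |>
    tidyr::pivot_longer(dplyr::all_of(num), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(
    replicates = reps,
    summary = summ,
    n_nodes = n_nodes, n_edges = n_edges, n_reps = n_reps,
    expected_density = 2 * n_edges / (n_nodes * (n_nodes - 1))
  ), class = "er_ensemble")
}

#' @export
print.er_ensemble <- function(x, ...) {
  cat(sprintf("<er_ensemble> %d G(%d, %d) replicates; expected density/CC = %.4f\n",
              x$n_reps, x$n_nodes, x$n_edges, x$expected_density))
  print(x$summary)
  invisible(x)
}

#' Modal diameter of an Erdős–Rényi ensemble
#' @param ensemble An `er_ensemble` computed with the `"diameter"` metric.
#' @return The most frequent diameter across replicates.
#' @export
modal_diameter <- function(ensemble) {
  stopifnot(inherits(ensemble, "er_ensemble"))
  check_that("diameter" %in% names(ensemble$replicates),
             "ensemble was computed without the diameter metric")
  tab <- table(ensemble$replicates$diameter)
  as.numeric(names(tab)[which.max(tab)])
}

#' Empirical z-score of an observed topology against the null ensemble
#' @param ensemble An `er_ensemble`.
#' @param observed A one-row topology tibble from [topology()].
#' @return A tibble with `metric`, `observed`, `null_mean`, `null_sd`, `z`.
#' @export
er_z_scores <- function(ensemble, observed) {
  stopifnot(inherits(ensemble, "er_ensemble"))
  s <- ensemble$summary[ensemble$summary$metric %in% names(observed), ]
  obs <- as.numeric(observed[1, s$metric])
  tibble::tibble(metric = s$metric, observed = obs, null_mean = s$mean,
                 null_sd = s$sd,
                 z = (obs - s$mean) / ifelse(s$sd > 0, s$sd, NA_real_))
}

#' Betweenness centrality of every node
#'
#' Unweighted shortest-path betweenness (Brandes counting), unnormalised,
#' endpoints excluded; isolated nodes score 0.
#'
#' @param network An undirected [igraph::igraph] graph with >= 3 nodes.
#' @return A tibble with `node`, `betweenness`, `degree`.
#' @export
betweenness_centrality <- function(network) {
  stopifnot(inherits(network, "igraph"))
  check_that(igraph::vcount(network) >= 3L, "need at least 3 nodes")
  b <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  tibble::tibble(node = igraph::V(network)$name %||%
                   as.character(seq_len(igraph::vcount(network))),
                 betweenness = as.numeric(b),
                 degree = as.numeric(igraph::degree(network)))
}

#' Keystone taxa by betweenness centrality
#'
#' Ranks nodes by betweenness centrality (ties broken by degree, then node
#' id) and returns the top `k` as the keystone candidates, annotated with
#' phylum and core membership where available.
#'
#' @param network An annotated co-occurrence graph (see [build_network()]).
#' @param k Number of keystone taxa to report (default 7).
#' @return A `keystone_report` with the full ranking and the top-`k` subset.
#' @export
keystone_taxa <- function(network, k = 7L) {
  bt <- betweenness_centrality(network)
  check_that(k >= 1L && k <= nrow(bt), "`k` must be between 1 and n_nodes")
  va <- igraph::vertex_attr(network)
  if (!is.null(va$phylum)) bt$phylum <- va$phylum
  if (!is.null(va$core)) bt$core <- va$core
  ranked <- dplyr::arrange(bt, dplyr::desc(.data$betweenness),
                           dplyr::desc(.data$degree), .data$node)
  ranked$rank <- seq_len(nrow(ranked))
  structure(list(ranking = ranked,
                 keystones = utils::head(ranked, k),
                 k = as.integer(k)),
            class = "keystone_report")
}

#' @export
print.keystone_report <- function(x, ...) {
  cat(sprintf("<keystone_report> top %d of %d nodes by betweenness\n",
              x$k, nrow(x$ranking)))
  print(x$keystones)
  invisible(x)
}

#' Compare core and non-core sub-networks
#'
#' Induces the sub-networks on core and non-core node sets, summarises each
#' topology, and compares the two groups' betweenness-centrality
#' distributions (computed on the full network) with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param network A graph whose nodes carry a logical `core` attribute, or
#'   provide `core` explicitly.
#' @param core Optional `core_set` or character vector of core node ids.
#' @return A list: `topology` (two-row tibble, core and other),
#'   `wilcoxon` (tibble with the W statistic and p-value), and the two
#'   induced igraph sub-networks.
#' @export
compare_core_subnetworks <- function(network, core = NULL) {
  stopifnot(inherits(network, "igraph"))
  nodes <- igraph::V(network)$name
  if (is.null(core)) {
    flags <- igraph::V(network)$core
    check_that(!is.null(flags), "network has no `core` node attribute")
  } else {
    core_ids <- if (inherits(core, "core_set")) core$otu_ids else core
    flags <- nodes %in% core_ids
  }
  check_that(any(flags) && any(!flags),
             "both core and non-core groups must be non-empty")
  g_core <- igraph::induced_subgraph(network, which(flags))
  g_other <- igraph::induced_subgraph(network, which(!flags))
  topo <- dplyr::bind_rows(
    dplyr::mutate(topology(g_core), group = "core", .before = 1),
    dplyr::mutate(topology(g_other), group = "other", .before = 1)
  )
  bt <- betweenness_centrality(network)
  wt <- suppressWarnings(
    stats::wilcox.test(bt$betweenness[flags], bt$betweenness[!flags],
                       alternative = "two.sided"))
  list(
    topology = topo,
    wilcoxon = tibble::tibble(
      statistic = unname(wt$statistic), p_value = wt$p.value,
      n_core = sum(flags), n_other = sum(!flags),
      median_core = stats::median(bt$betweenness[flags]),
      median_other = stats::median(bt$betweenness[!flags])),
    core_network = g_core,
    other_network = g_other
  )
}

#' Write a co-occurrence network
#'
#' @param network An igraph graph.
#' @param path Output path; `format = "graphml"` writes GraphML,
#'   `"edgelist"` a TSV of edges with their `r` and `q` attributes.
#' @param format Output format.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), path, progress = FALSE)
  }
  invisible(path)
}
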