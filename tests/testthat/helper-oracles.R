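# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where the package delegates to igraph/vegan,
# avoid those too) so that implementation and check stay decoupled.

# --- Spearman by definition: rank, then the explicit Pearson sum formula ---
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# --- betweenness by exhaustive geodesic enumeration ----------------------
# adj: symmetric 0/1 matrix. Enumerates every shortest path between every
# ordered pair via depth-first search on the BFS distance labels and counts
# interior visits; returns the undirected convention (each unordered pair
# counted once).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1)
        new <- nb[d[nb] == Inf]
        d[new] <- d[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    d
  }
  score <- rep(0, n)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(d[t]) || t == s) next
      # enumerate all shortest s->t paths by walking predecessors
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1]] <<- acc
          return(invisible(NULL))
        }
        preds <- which(adj[v, ] == 1 & d == d[v] - 1)
        for (u in preds) walk(u, c(u, acc))
      }
      walk(t, t)
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        score[idx] <- score[idx] + as.numeric(tab) / length(paths)
      }
    }
  }
  score
}

# random simple undirected graph as an adjacency matrix
random_adj <- function(n, p_edge) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "name",
                          value = paste0("v", seq_len(nrow(adj))))
}

# --- exhaustive permutation p-values -------------------------------------
# statistic computed by the supplied function for every permutation of
# sample labels; one- or two-sided on the raw statistic
oracle_exhaustive_p <- function(stat_fn, n, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  perms <- all_perms(n)
  obs <- stat_fn(seq_len(n))
  vals <- vapply(perms, stat_fn, numeric(1))
  if (sided == "greater") {
    mean(vals >= obs - 1e-12)
  } else {
    mean(abs(vals) >= abs(obs) - 1e-12)
  }
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# --- small fixtures ------------------------------------------------------
tiny_table <- function(counts, sample_ids = NULL, otu_ids = NULL,
                       lineages = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- sample_ids %||% paste0("S", seq_len(nrow(counts)))
  colnames(counts) <- otu_ids %||% paste0("OTU", seq_len(ncol(counts)))
  # explicit namespacing: phyloseq (a Suggests used as an oracle) masks
  # `otu_table` when attached
  soilbiogeo::otu_table(counts, lineages = lineages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n_samples = 6, n_otus = 12, seed = 1,
                         lambda = 40) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(n_samples * n_otus, lambda),
                     nrow = n_samples)
    counts[1, ] <- counts[1, ] + 1  # guard against all-zero rows
    tiny_table(counts)
  })
}

maize_metadata <- function() {
  read_metadata(system.file("extdata", "maize_sites.tsv",
                            package = "soilbiogeo"))
}
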