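test_that("Spearman matrix matches the rank-then-Pearson definition", {
  tb <- random_table(n_samples = 21, n_otus = 10, seed = 3, lambda = 12)
  cm <- correlation_matrix(tb)
  rel <- relative_abundance(tb)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(cm$r[i, j], oracle_spearman(rel[, i], rel[, j]),
                 tolerance = 1e-12)
  }
  # monotone and anti-monotone pairs hit the boundaries exactly; a filler
  # column equalises library sizes so proportions preserve monotonicity
  base <- cbind(1:6 * 10, (1:6)^2 * 3, 60:55 * 7, rep(10, 6))
  filler <- max(rowSums(base)) - rowSums(base) + 5
  cm2 <- correlation_matrix(tiny_table(cbind(base, filler)))
  expect_equal(cm2$r["OTU1", "OTU2"], 1)    # both strictly increasing
  expect_equal(cm2$r["OTU2", "OTU3"], -1)   # anti-monotone pair
  expect_equal(cm2$p["OTU2", "OTU3"], 0)
})

test_that("Spearman correlations are invariant to monotone transforms", {
  tb <- random_table(n_samples = 12, n_otus = 8, seed = 5, lambda = 20)
  cm1 <- correlation_matrix(tb)
  # uniform count scaling leaves relative abundances (hence ranks) intact
  cm7 <- correlation_matrix(tiny_table(tb$counts * 7))
  expect_equal(cm7$r, cm1$r, tolerance = 1e-12, ignore_attr = TRUE)
  # a strictly monotone transform of each taxon profile preserves ranks
  rel <- relative_abundance(tb)
  r_trans <- stats::cor(apply(exp(3 * rel), 2, rank))
  expect_equal(unname(cm1$r), unname(r_trans), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.123), 0.123)
  q <- fdr_adjust(c(0.001, 0.01, 0.9))
  expect_true(all(q >= c(0.001, 0.01, 0.9)))
  expect_true(all(order(q) == order(c(0.001, 0.01, 0.9))))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # matrix form adjusts over the flattened upper triangle and mirrors
  p <- matrix(c(NA, 0.01, 0.02, 0.01, NA, 0.03, 0.02, 0.03, NA), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  q2 <- fdr_adjust(p)
  expect_equal(q2[upper.tri(q2)], stats::p.adjust(p[upper.tri(p)], "BH"))
  expect_equal(q2[lower.tri(q2)], t(q2)[lower.tri(q2)])
})

test_that("edge thresholds are strict and one-sided", {
  ids <- c("t1", "t2")
  mk <- function(r, q) {
    rm <- matrix(c(1, r, r, 1), 2, dimnames = list(ids, ids))
    qm <- matrix(c(NA, q, q, NA), 2, dimnames = list(ids, ids))
    igraph::ecount(build_network(rm, qm))
  }
  expect_equal(mk(0.61, 0.005), 1)
  expect_equal(mk(0.61, 0.02), 0)
  expect_equal(mk(-0.9, 1e-6), 0)  # strong negative correlation: no edge
  expect_equal(mk(0.6, 0.005), 0)  # threshold is strict
  # |r| mode admits the negative edge
  rm <- matrix(c(1, -0.9, -0.9, 1), 2, dimnames = list(ids, ids))
  qm <- matrix(c(NA, 1e-6, 1e-6, NA), 2, dimnames = list(ids, ids))
  expect_equal(igraph::ecount(build_network(rm, qm, use_absolute = TRUE)), 1)
})

test_that("genus aggregation conserves assigned counts", {
  lin <- tibble::tibble(
    otu_id = paste0("OTU", 1:4), kingdom = "Bacteria",
    phylum = c("P1", "P1", "P2", "P2"), class = NA_character_,
    order = NA_character_, family = NA_character_,
    genus = c("Ga", "Ga", "Gb", NA))
  tb <- tiny_table(rbind(c(1, 3, 5, 7), c(2, 4, 6, 8)), lineages = lin)
  expect_message(gt <- aggregate_to_genus(tb), "1 OTUs without genus")
  expect_equal(gt$counts[, "Ga"], c(S1 = 4, S2 = 6))
  expect_equal(gt$counts[, "Gb"], c(S1 = 5, S2 = 6))
  assigned <- tb$counts[, 1:3]
  expect_equal(sum(gt$counts), sum(assigned))

  lin$genus <- NA_character_
  tb2 <- tiny_table(tb$counts, lineages = lin)
  expect_error(aggregate_to_genus(tb2), "no genus assignments")
})

test_that("topology matches closed forms on canonical small graphs", {
  tri <- igraph::make_full_graph(3)
  t_tri <- topology(tri)
  expect_equal(t_tri$apl, 1)
  expect_equal(t_tri$diameter, 1)
  expect_equal(t_tri$density, 1)
  expect_equal(t_tri$clustering, 1)

  path3 <- igraph::make_graph(~ a - b, b - c)
  t_p <- topology(path3)
  expect_equal(t_p$apl, 4 / 3)
  expect_equal(t_p$diameter, 2)
  expect_equal(t_p$clustering, 0)

  star5 <- igraph::make_star(5, mode = "undirected")
  t_s <- topology(star5)
  expect_equal(t_s$clustering, 0)
  expect_equal(t_s$density, 4 / 10)
  expect_equal(max(igraph::degree(star5)), 4)
})

test_that("betweenness matches exhaustive path enumeration", {
  # closed forms first
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:7)
  bt <- betweenness_centrality(star)
  expect_equal(bt$betweenness[1], (7 - 1) * (7 - 2) / 2)
  expect_equal(bt$betweenness[-1], rep(0, 6))

  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(betweenness_centrality(path3)$betweenness, c(0, 1, 0))

  # random graphs up to 8 nodes against the enumeration oracle
  withr::with_seed(55, {
    for (rep in 1:12) {
      n <- sample(3:8, 1)
      adj <- random_adj(n, p_edge = runif(1, 0.2, 0.8))
      g <- adj_to_igraph(adj)
      expect_equal(betweenness_centrality(g)$betweenness,
                   oracle_betweenness(adj), tolerance = 1e-10,
                   info = paste("rep", rep))
    }
    # one denser spot check
    adj30 <- random_adj(30, 0.12)
    g30 <- adj_to_igraph(adj30)
    expect_equal(betweenness_centrality(g30)$betweenness,
                 oracle_betweenness(adj30), tolerance = 1e-8)
  })
})

test_that("G(n,m) replicates have exact edge counts and ER-consistent clustering", {
  ens <- er_null_ensemble(60, 177, n_reps = 40, seed = 3,
                          metrics = c("clustering", "density"))
  expect_true(all(ens$replicates$n_edges == 177))
  expect_equal(unique(ens$replicates$density), 2 * 177 / (60 * 59))
  cc <- dplyr::filter(ens$summary, metric == "clustering")
  expect_lt(abs(cc$mean - ens$expected_density),
            3 * cc$sd / sqrt(ens$n_reps) + 0.01)
  expect_error(er_null_ensemble(5, 100), "more edges")
})

test_that("a planted bridge node ranks first by betweenness", {
  # two dense blocks joined only through one bridge node
  block <- function(ids) {
    cmb <- utils::combn(ids, 2)
    as.vector(cmb)
  }
  b1 <- paste0("a", 1:5)
  b2 <- paste0("b", 1:5)
  edges <- c(block(b1), block(b2),
             "bridge", b1[1], "bridge", b2[1])
  g <- igraph::make_graph(edges, directed = FALSE)
  ks <- keystone_taxa(g, k = 1)
  expect_equal(ks$keystones$node, "bridge")
  ks_all <- keystone_taxa(g, k = igraph::vcount(g))
  expect_equal(nrow(ks_all$keystones), igraph::vcount(g))
  expect_true(all(diff(ks_all$keystones$betweenness) <= 1e-12))
  expect_error(keystone_taxa(g, k = 100), "between 1 and n_nodes")
})

test_that("core/other sub-network comparison uses an exact Wilcoxon", {
  # symmetric construction: two identical components, one labelled core
  comp <- function(prefix) {
    c(paste0(prefix, 1), paste0(prefix, 2),
      paste0(prefix, 2), paste0(prefix, 3),
      paste0(prefix, 3), paste0(prefix, 4))
  }
  g <- igraph::make_graph(c(comp("c"), comp("o")), directed = FALSE)
  core_ids <- paste0("c", 1:4)
  res <- compare_core_subnetworks(g, core_ids)
  expect_gt(res$wilcoxon$p_value, 0.05)  # identical distributions
  expect_equal(res$topology$n_nodes, c(4, 4))

  expect_error(compare_core_subnetworks(g, c(core_ids, paste0("o", 1:4))),
               "non-empty")
})

test_that("reported Wilcoxon p equals exact 4-vs-4 enumeration", {
  # fixed 8-node graph whose betweenness values are all distinct, so the
  # exact rank-sum distribution applies without tie corrections
  edges <- c(2, 3, 1, 4, 3, 4, 1, 5, 1, 6, 5, 6, 1, 7, 5, 7, 2, 8, 5, 8,
             6, 8)
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  bt <- betweenness_centrality(g)
  expect_equal(length(unique(bt$betweenness)), 8)
  core_ids <- paste0("n", 1:4)
  res <- compare_core_subnetworks(g, core_ids)

  # enumeration oracle: all C(8,4) assignments of the observed values
  vals <- bt$betweenness
  flags <- bt$node %in% core_ids
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, `>`))
  }
  u_obs <- u_stat(vals[flags], vals[!flags])
  combos <- utils::combn(8, 4)
  u_all <- apply(combos, 2, function(idx) {
    u_stat(vals[idx], vals[-idx])
  })
  mu <- 4 * 4 / 2
  p_exact <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  expect_equal(res$wilcoxon$p_value, p_exact, tolerance = 1e-12)
})
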