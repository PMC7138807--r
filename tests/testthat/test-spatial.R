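test_that("haversine distances match known great-circle values", {
  md <- site_metadata(tibble::tibble(
    sample_id = c("a", "b", "c"),
    latitude = c(0, 0, 0), longitude = c(0, 180, 90)))
  d <- as.matrix(haversine_matrix(md))
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(d["a", "c"], pi * 6371 / 2, tolerance = 1e-6)

  same <- site_metadata(tibble::tibble(sample_id = c("x", "y"),
                                       latitude = c(30, 30),
                                       longitude = c(100, 100)))
  expect_equal(as.matrix(haversine_matrix(same))["x", "y"], 0)
})

test_that("haversine satisfies metric axioms on random coordinate triples", {
  withr::with_seed(11, {
    for (i in 1:20) {
      md <- site_metadata(tibble::tibble(
        sample_id = c("p", "q", "r"),
        latitude = runif(3, -89, 89), longitude = runif(3, -179, 179)))
      d <- as.matrix(haversine_matrix(md))
      expect_equal(d, t(d), tolerance = 1e-9)
      expect_true(all(d >= 0))
      expect_true(d["p", "r"] <= d["p", "q"] + d["q", "r"] + 1e-9)
    }
  })
})

test_that("survey site distances span the reported 87-4130 km range", {
  d <- as.matrix(haversine_matrix(maize_metadata()))
  pairs <- d[upper.tri(d)]
  expect_equal(min(pairs), 87, tolerance = 0.005)
  expect_equal(max(pairs), 4130, tolerance = 0.005)
  # the closest pair is sites 11 and 12
  d2 <- d
  diag(d2) <- Inf
  idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(d)[idx], c("11", "12"))
})

test_that("DDR fit recovers exact linear similarity structures", {
  md <- maize_metadata()
  geo <- haversine_matrix(md)
  g <- as.matrix(geo)
  sim <- 0.9 - 1e-4 * g
  diag(sim) <- 1
  dis <- dist_matrix(1 - sim, units = "raw")
  fit <- ddr_fit(geo, dis)
  expect_equal(fit$slope, -1e-4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 21 * 20 / 2)

  flat <- dist_matrix(matrix(0.3, 21, 21,
                             dimnames = dimnames(g)) - diag(0.3, 21),
                      units = "raw")
  expect_equal(ddr_fit(geo, flat)$slope, 0, tolerance = 1e-12)
})

test_that("DDR fit is invariant to a common reordering of both matrices", {
  md <- maize_metadata()
  geo <- haversine_matrix(md)
  syn <- generate_synthetic(synthetic_config(n_otus = 60, seed = 3))
  bc <- bray_curtis(syn$table)
  geo2 <- haversine_matrix(syn$metadata)
  fit1 <- ddr_fit(geo2, bc)
  perm <- rev(rownames(as.matrix(bc)))
  bc_p <- dist_matrix(as.matrix(bc)[perm, perm], units = "dissimilarity")
  geo_p <- dist_matrix(as.matrix(geo2)[perm, perm], units = "km")
  fit2 <- ddr_fit(geo_p, bc_p)
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-12)
  expect_equal(fit2$r_squared, fit1$r_squared, tolerance = 1e-12)
})

test_that("per-phylum DDR on a single-phylum table equals the whole fit", {
  syn <- generate_synthetic(synthetic_config(n_otus = 50, seed = 8))
  tb <- syn$table
  tb$lineages$phylum <- "Monophylum"
  geo <- haversine_matrix(syn$metadata)
  whole <- ddr_fit(geo, bray_curtis(tb))
  per <- ddr_by_phylum(tb, geo, "Monophylum")
  expect_equal(per$slope, whole$slope, tolerance = 1e-12)
  expect_equal(per$r_squared, whole$r_squared, tolerance = 1e-12)
  expect_equal(per$n_dropped, 0)
  expect_error(ddr_by_phylum(tb, geo, "Nosuchphylum"), "absent")
})

test_that("phyla with longer spatial range show flatter distance decay", {
  cfg <- synthetic_config(
    n_otus = 400, n_core = 0, n_guilds = 0, n_env_responders = 0,
    noise_sd = 0.2, spatial_sd = 1.5,
    # the low-dispersal phylum turns over inside the sampled window; the
    # high-dispersal one has a correlation length far beyond it, so its
    # similarity barely decays across the sampled distances
    phylum_range_km = list(Proteobacteria = 50000, Actinobacteria = 1500),
    seed = 21)
  syn <- generate_synthetic(cfg)
  geo <- haversine_matrix(syn$metadata)
  w_long <- ddr_by_phylum(syn$table, geo, "Proteobacteria")$slope
  w_short <- ddr_by_phylum(syn$table, geo, "Actinobacteria")$slope
  expect_lt(abs(w_long), abs(w_short))
})

test_that("Mantel statistic and p behave on monotone-related matrices", {
  md <- maize_metadata()
  geo <- haversine_matrix(md)
  double <- dist_matrix(2 * as.matrix(geo), units = "km")
  mt <- mantel(geo, double, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, 1)
  expect_equal(mt$p_value, 1 / 100)
  mt_p <- mantel(geo, double, method = "pearson", n_perm = 99, seed = 1)
  expect_equal(mt_p$statistic, 1)
})

test_that("exhaustive Mantel p equals brute-force enumeration at n = 4", {
  withr::with_seed(17, {
    m1 <- as.matrix(dist(matrix(rnorm(8), 4)))
    m2 <- as.matrix(dist(matrix(rnorm(8), 4)))
    dimnames(m1) <- dimnames(m2) <- list(letters[1:4], letters[1:4])
  })
  d1 <- dist_matrix(m1, units = "raw")
  d2 <- dist_matrix(m2, units = "raw")
  for (meth in c("pearson", "spearman")) {
    mt <- mantel(d1, d2, method = meth, exhaustive = TRUE)
    ut <- upper.tri(m1)
    stat_fn <- function(p) {
      x <- m1[ut]
      y <- m2[p, p][ut]
      if (meth == "spearman") oracle_spearman(x, y) else
        sum(scale(x) * scale(y)) / (length(x) - 1)
    }
    p_oracle <- oracle_exhaustive_p(stat_fn, 4, sided = "two")
    expect_equal(mt$p_value, p_oracle, tolerance = 1e-12)
    expect_equal(mt$n_permutations, 24)
  }
})

test_that("Mantel agrees with an independent implementation", {
  syn <- generate_synthetic(synthetic_config(n_otus = 40, seed = 12))
  geo <- haversine_matrix(syn$metadata)
  bc <- bray_curtis(syn$table)
  ours <- mantel(geo, bc, method = "pearson", n_perm = 999, seed = 2)
  ref <- vegan::mantel(stats::as.dist(as.matrix(geo)),
                       stats::as.dist(as.matrix(bc)),
                       method = "pearson", permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})
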