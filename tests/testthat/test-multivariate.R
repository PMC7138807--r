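euclid_dm <- function(x, ids = NULL) {
  m <- as.matrix(stats::dist(x))
  ids <- ids %||% paste0("S", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  dist_matrix(m, units = "raw")
}

test_that("PCoA reconstructs Euclidean configurations", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  d <- euclid_dm(pts)
  ord <- pcoa(d)
  emb <- as.matrix(stats::dist(ord$scores))
  expect_equal(emb, unname(as.matrix(d)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # two samples at distance d -> one axis, scores +/- d/2
  d2 <- euclid_dm(matrix(c(0, 6), ncol = 1))
  ord2 <- pcoa(d2)
  expect_equal(ncol(ord2$scores), 1)
  expect_equal(sort(as.numeric(ord2$scores)), c(-3, 3), tolerance = 1e-10)
})

test_that("PCoA eigenvalues sum to the trace of the Gower matrix", {
  withr::with_seed(4, {
    x <- matrix(rnorm(8 * 3), nrow = 8)
  })
  d <- euclid_dm(x)
  ord <- pcoa(d)
  g <- soilbiogeo:::gower_center(as.matrix(d))
  expect_equal(sum(ord$all_eigenvalues), sum(diag(g)), tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-10))   # non-increasing
  expect_lte(sum(ord$proportion), 1 + 1e-12)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "square|symmetric|names")
})

test_that("PERMANOVA matches classical one-way ANOVA on univariate data", {
  withr::with_seed(9, {
    y <- rnorm(12) + rep(c(0, 1, 3), each = 4)
    grp <- factor(rep(c("a", "b", "c"), each = 4))
  })
  d <- euclid_dm(matrix(y, ncol = 1))
  res <- permanova(d, tibble::tibble(grp = grp), ~ grp, n_perm = 99,
                   seed = 1)
  f_classic <- summary(stats::aov(y ~ grp))[[1]]$`F value`[1]
  expect_equal(res$table$statistic, f_classic, tolerance = 1e-8)
  expect_equal(res$table$df, 2L)
})

test_that("PERMANOVA gives R2 = 1 when groups exactly duplicate samples", {
  x <- rbind(c(1, 2), c(1, 2), c(5, 7), c(5, 7))
  d <- euclid_dm(x)
  res <- permanova(d, tibble::tibble(g = factor(c("a", "a", "b", "b"))),
                   ~ g, n_perm = 99, seed = 1)
  expect_equal(res$table$r_squared, 1, tolerance = 1e-10)
})

test_that("PERMANOVA agrees with an independent implementation", {
  syn <- generate_synthetic(synthetic_config(n_otus = 40, seed = 13))
  bc <- bray_curtis(syn$table)
  md <- syn$metadata
  res <- permanova(bc, md, ~ PRE + pH, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(as.matrix(bc)) ~ PRE + pH,
                        data = md, permutations = 99, by = "terms")
  expect_equal(res$table$statistic, ref$F[1:2], tolerance = 1e-8)
  expect_equal(res$table$r_squared, ref$R2[1:2], tolerance = 1e-8)
  expect_equal(res$table$sum_sq, ref$SumOfSqs[1:2], tolerance = 1e-8)

  resm <- permanova(bc, md, ~ PRE + pH, n_perm = 99, seed = 1,
                    by = "margin")
  refm <- vegan::adonis2(stats::as.dist(as.matrix(bc)) ~ PRE + pH,
                         data = md, permutations = 99, by = "margin")
  expect_equal(resm$table$statistic, refm$F[1:2], tolerance = 1e-8)
})

test_that("exhaustive PERMANOVA p equals brute-force enumeration at n = 6", {
  withr::with_seed(23, {
    x <- matrix(rnorm(12), nrow = 6)
    grp <- factor(c("a", "a", "a", "b", "b", "b"))
  })
  d <- euclid_dm(x)
  res <- permanova(d, tibble::tibble(g = grp), ~ g, exhaustive = TRUE)

  m <- as.matrix(d)
  g_mat <- soilbiogeo:::gower_center(m)
  f_of_groups <- function(gg) {
    xmod <- stats::model.matrix(~gg)
    h <- xmod %*% solve(crossprod(xmod)) %*% t(xmod)
    ss_m <- sum(diag(h %*% g_mat)) # intercept part vanishes: G is centered
    ss_r <- sum(diag(g_mat)) - ss_m
    (ss_m / 1) / (ss_r / 4)
  }
  p_oracle <- oracle_exhaustive_p(function(p) f_of_groups(grp[p]), 6,
                                  sided = "greater")
  expect_equal(res$table$p_value, p_oracle, tolerance = 1e-12)
})

test_that("ANOSIM equals 1 under maximal group separation and matches vegan", {
  # two tight clusters far apart: all between > all within
  x <- rbind(matrix(rnorm(6, 0, 0.01), ncol = 2),
             matrix(rnorm(6, 10, 0.01), ncol = 2))
  d <- euclid_dm(x)
  grp <- factor(rep(c("a", "b"), each = 3))
  res <- anosim(d, grp, n_perm = 99, seed = 1)
  expect_equal(res$table$statistic, 1, tolerance = 1e-12)

  syn <- generate_synthetic(synthetic_config(n_otus = 30, seed = 14))
  bc <- bray_curtis(syn$table)
  grp2 <- factor(rep(c("x", "y", "z"), each = 7))
  ours <- anosim(bc, grp2, n_perm = 99, seed = 2)
  ref <- vegan::anosim(stats::as.dist(as.matrix(bc)), grp2,
                       permutations = 99)
  expect_equal(ours$table$statistic, unname(ref$statistic),
               tolerance = 1e-10)
})

test_that("exhaustive ANOSIM p equals brute-force enumeration at n = 6", {
  withr::with_seed(31, {
    x <- matrix(rnorm(12), nrow = 6)
  })
  d <- euclid_dm(x)
  grp <- factor(c("a", "a", "a", "b", "b", "b"))
  res <- anosim(d, grp, exhaustive = TRUE)
  m <- as.matrix(d)
  ut <- upper.tri(m)
  rk <- rank(m[ut])
  r_of <- function(gg) {
    same <- outer(gg, gg, `==`)[ut]
    (mean(rk[!same]) - mean(rk[same])) / (length(rk) / 2)
  }
  p_oracle <- oracle_exhaustive_p(function(p) r_of(grp[p]), 6,
                                  sided = "greater")
  expect_equal(res$table$p_value, p_oracle, tolerance = 1e-12)
})

test_that("random labels give near-zero mean ANOSIM R", {
  withr::with_seed(77, {
    rs <- replicate(300, {
      x <- matrix(rnorm(20), nrow = 10)
      d <- euclid_dm(x)
      grp <- factor(sample(rep(c("a", "b"), each = 5)))
      m <- as.matrix(d)
      ut <- upper.tri(m)
      rk <- rank(m[ut])
      same <- outer(grp, grp, `==`)[ut]
      (mean(rk[!same]) - mean(rk[same])) / (length(rk) / 2)
    })
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("CAP recovers projections and conserves inertia", {
  syn <- generate_synthetic(synthetic_config(n_otus = 50, seed = 15))
  bc <- bray_curtis(syn$table)
  ord <- pcoa(bc)

  # constraining on the first PCoA axis recovers exactly that eigenvalue
  df <- tibble::tibble(sample_id = ord$sample_ids,
                       ax1 = as.numeric(ord$scores[, 1]))
  fit <- cap(bc, df, ~ ax1, n_perm = 99, seed = 1)
  expect_equal(fit$constrained_inertia, ord$eigenvalues[1],
               tolerance = 1e-8)

  # a constraint orthogonal to all axis scores captures nothing; this needs
  # low-rank distances (planar points -> 2 axes) so such a direction exists
  withr::with_seed(5, {
    pts <- matrix(rnorm(16), ncol = 2)
  })
  d_low <- euclid_dm(pts)
  ord_low <- pcoa(d_low)
  expect_equal(ncol(ord_low$scores), 2)
  basis <- cbind(1, ord_low$scores)
  v <- withr::with_seed(6, rnorm(8))
  orth <- as.numeric(stats::residuals(stats::lm(v ~ basis)))
  fit0 <- cap(d_low, tibble::tibble(orth = orth), ~ orth,
              n_perm = 99, seed = 1)
  expect_lt(fit0$constrained_inertia, 1e-8)

  # constrained + unconstrained inertia equals the total PCoA inertia
  md <- syn$metadata
  fit2 <- cap(bc, md, ~ PRE + pH, n_perm = 99, seed = 1)
  expect_equal(fit2$constrained_inertia + fit2$unconstrained_inertia,
               ord$total_inertia, tolerance = 1e-8)
})

test_that("CAP agrees with an independent db-RDA implementation", {
  syn <- generate_synthetic(synthetic_config(n_otus = 50, seed = 16))
  bc <- bray_curtis(syn$table)
  md <- syn$metadata
  fit <- cap(bc, md, ~ PRE + pH, n_perm = 99, seed = 1)
  ref <- vegan::capscale(stats::as.dist(as.matrix(bc)) ~ PRE + pH,
                         data = md)
  expect_equal(fit$constrained_inertia, unname(ref$CCA$tot.chi),
               tolerance = 1e-6)
  expect_equal(fit$total_inertia,
               unname(ref$CCA$tot.chi + ref$CA$tot.chi), tolerance = 1e-6)
  expect_equal(fit$ordination$eigenvalues, unname(ref$CCA$eig),
               tolerance = 1e-6)
})

test_that("permutation engines are reproducible and never report p = 0", {
  syn <- generate_synthetic(synthetic_config(n_otus = 30, seed = 17))
  bc <- bray_curtis(syn$table)
  md <- syn$metadata
  r1 <- permanova(bc, md, ~ PRE, n_perm = 199, seed = 42)
  r2 <- permanova(bc, md, ~ PRE, n_perm = 199, seed = 42)
  expect_identical(r1$table$p_value, r2$table$p_value)
  expect_gt(r1$table$p_value, 0)
  m1 <- mantel(haversine_matrix(md), bc, n_perm = 199, seed = 42)
  m2 <- mantel(haversine_matrix(md), bc, n_perm = 199, seed = 42)
  expect_identical(m1$p_value, m2$p_value)
  expect_gt(m1$p_value, 0)
})
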