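#' Great-circle distance matrix between sites
#'
#' Haversine distances on a sphere of mean radius 6,371 km, computed from
#' the decimal-degree coordinates of a metadata table. At continental scales
#' this deviates from ellipsoidal geodesics by well under 0.2%.
#'
#' @param metadata A `site_metadata` tibble with `latitude` and `longitude`.
#' @return A [dist_matrix] in kilometres.
#' @export
haversine_matrix <- function(metadata) {
  metadata <- site_metadata(metadata)
  check_that(!anyNA(metadata$latitude) && !anyNA(metadata$longitude),
             "missing coordinates")
  xy <- cbind(metadata$longitude, metadata$latitude)
  hav <- function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
  m <- geosphere::distm(xy, fun = hav) / 1000
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  dist_matrix(m, units = "km")
}

#' Distance-decay relationship of community similarity
#'
#' Ordinary least-squares regression of community similarity
#' (`1 - dissimilarity`) on geographic distance over all unordered sample
#' pairs. The slope `w` is the spatial turnover rate (similarity per km).
#' The default p-value is the OLS slope t-test, as distance-decay studies
#' conventionally report; because pairs sharing a sample are not
#' independent, a Mantel-style permutation p-value is available with
#' `p_method = "permutation"`.
#'
#' @param geo Geographic [dist_matrix] (km).
#' @param dissim Community dissimilarity [dist_matrix] on the same samples.
#' @param p_method `"ols"` (slope t-test) or `"permutation"`.
#' @param n_perm,seed Permutation settings when `p_method = "permutation"`.
#' @return A `ddr_fit` object; see [tidy.ddr_fit()], [glance.ddr_fit()] and
#'   [autoplot.ddr_fit()].
#' @export
ddr_fit <- function(geo, dissim, p_method = c("ols", "permutation"),
                    n_perm = 999, seed = 1L) {
  p_method <- match.arg(p_method)
  al <- align_dist(geo, dissim)
  n <- length(al$ids)
  check_that(n >= 3L, "need at least 3 samples")
  x <- upper_tri_vec(al$d1)
  y <- 1 - upper_tri_vec(al$d2)
  check_that(stats::sd(x) > 0, "constant distance vector")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact linear input is legitimate
  p_ols <- unname(sm$coefficients["x", "Pr(>|t|)"])
  p_val <- p_ols
  if (p_method == "permutation") {
    mt <- mantel(dist_matrix(al$d1, units = "km"),
                 dist_matrix(al$d2, units = "raw"),
                 method = "pearson", n_perm = n_perm, seed = seed)
    p_val <- mt$p_value
  }
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slope_se = unname(sm$coefficients["x", "Std. Error"]),
    p_value = p_val,
    p_method = p_method,
    r_squared = sm$r.squared,
    n_pairs = length(x),
    n_samples = n,
    pairs = dplyr::mutate(pair_index(al$ids), distance_km = x,
                          similarity = y)
  ), class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf(
    "<ddr_fit> w = %.4g similarity/km (SE %.3g), R2 = %.3f, p = %.3g (%s), %d pairs\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$p_method, x$n_pairs))
  invisible(x)
}

#' Distance-decay relationship of a single phylum
#'
#' Subsets the OTUs assigned to `phylum`, renormalises relative abundances
#' within the subset, computes Bray-Curtis similarity and fits the
#' distance-decay regression. Samples where the phylum is entirely absent
#' are dropped (their number is reported in the fit).
#'
#' @param table An [otu_table] with lineages.
#' @param geo Geographic [dist_matrix] covering the table's samples.
#' @param phylum Phylum name to subset.
#' @inheritParams ddr_fit
#' @return A `ddr_fit` with extra fields `phylum` and `n_dropped`.
#' @export
ddr_by_phylum <- function(table, geo, phylum, p_method = c("ols", "permutation"),
                          n_perm = 999, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  check_that(!is.null(table$lineages), "table has no taxonomy lineages")
  otus <- table$lineages$otu_id[!is.na(table$lineages$phylum) &
                                  table$lineages$phylum == phylum]
  if (length(otus) == 0L) {
    abort(sprintf("phylum '%s' absent from table", phylum))
  }
  sub <- subset_taxa(table, otus)
  keep <- rowSums(sub$counts) > 0
  n_dropped <- sum(!keep)
  check_that(sum(keep) >= 3L,
             sprintf("phylum '%s' present in fewer than 3 samples", phylum))
  sub$counts <- sub$counts[keep, , drop = FALSE]
  bc <- bray_curtis(sub, on = "relative")
  ids <- rownames(sub$counts)
  geo_sub <- dist_matrix(as.matrix(geo)[ids, ids], units = "km")
  fit <- ddr_fit(geo_sub, bc, p_method = p_method, n_perm = n_perm,
                 seed = seed)
  fit$phylum <- phylum
  fit$n_dropped <- n_dropped
  fit
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices and assesses
#' significance by simultaneous row/column permutation of the second matrix.
#' The two-sided p-value uses the +1 correction,
#' `p = (1 + #|r*| >= |r|) / (1 + n_perm)`, and so is never zero. With
#' `exhaustive = TRUE` (feasible up to ~8 samples) all `n!` relabelings are
#' enumerated and `p = #|r*| >= |r| / n!` (identity included).
#'
#' @param d1,d2 [dist_matrix] objects over the same samples.
#' @param method Correlation of the triangle vectors: `"spearman"`
#'   (default) or `"pearson"`.
#' @param n_perm Number of random permutations (>= 99).
#' @param seed RNG seed.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return A `mantel_result` with fields `statistic`, `p_value`,
#'   `n_permutations`, `method`.
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"), n_perm = 999,
                   seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  al <- align_dist(d1, d2)
  n <- length(al$ids)
  ut <- upper.tri(al$d1)
  x <- al$d1[ut]
  y0 <- al$d2[ut]
  check_that(stats::sd(x) > 0 && stats::sd(y0) > 0,
             "zero-variance distance triangle")
  if (method == "spearman") x <- rank(x)
  stat_for <- function(perm) {
    yp <- al$d2[perm, perm][ut]
    if (method == "spearman") yp <- rank(yp)
    stats::cor(x, yp)
  }
  r_obs <- stat_for(seq_len(n))
  if (exhaustive) {
    check_that(n <= 8L, "exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, stat_for, numeric(1))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_used <- length(perms)
  } else {
    check_that(n_perm >= 99L, "use at least 99 permutations")
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(n)),
             numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p_value = p, n_permutations = n_used,
                 method = method, exhaustive = exhaustive, n_samples = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f (%s), p = %.4g (%s permutations)\n",
              x$statistic, x$method, x$p_value,
              if (x$exhaustive) "exhaustive" else x$n_permutations))
  invisible(x)
}

# all permutations of 1..n as a list (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
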