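# Gower-centered inner-product matrix from a distance matrix:
# G = C (-0.5 D^2) C with C = I - 11'/n
gower_center <- function(m) {
  a <- -0.5 * m^2
  n <- nrow(m)
  rm <- rowMeans(a)
  g <- a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a)
  (g + t(g)) / 2
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition. Axes
#' with eigenvalue above `eig_tol` are retained and scores are scaled by the
#' square root of their eigenvalue, so Euclidean distances between scores
#' reproduce the input distances when the input is Euclidean-embeddable.
#' Negative eigenvalues (semi-metric input) are reported but dropped from
#' the axes, mirroring default `capscale` behaviour.
#'
#' @param d A [dist_matrix].
#' @param eig_tol Smallest eigenvalue retained as an axis.
#' @return An `ordination` object with sample scores, eigenvalues and the
#'   proportion of (positive) inertia explained per axis.
#' @export
pcoa <- function(d, eig_tol = 1e-10) {
  m <- as.matrix(as_dist_matrix(d, units = "raw"))
  g <- gower_center(m)
  eg <- eigen(g, symmetric = TRUE)
  keep <- eg$values > eig_tol
  check_that(any(keep), "no positive eigenvalues; degenerate distances")
  scores <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), nrow = sum(keep))
  dimnames(scores) <- list(rownames(m), paste0("Axis", seq_len(sum(keep))))
  pos_sum <- sum(eg$values[eg$values > 0])
  structure(list(
    scores = scores,
    eigenvalues = eg$values[keep],
    all_eigenvalues = eg$values,
    proportion = eg$values[keep] / pos_sum,
    total_inertia = pos_sum,
    type = "unconstrained",
    sample_ids = rownames(m)
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, %d samples, %d axes; first axes explain %s\n",
              x$type, length(x$sample_ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion, 3)),
                    collapse = ", ")))
  invisible(x)
}

# align a metadata-like data frame to distance-matrix sample ids and return
# the model matrix pieces for a one-sided formula
design_matrix <- function(data, formula, ids) {
  data <- tibble::as_tibble(data)
  if ("sample_id" %in% names(data)) {
    check_that(all(ids %in% data$sample_id),
               "design rows do not cover all samples")
    data <- data[match(ids, data$sample_id), ]
  } else {
    check_that(nrow(data) == length(ids),
               "design rows do not align with samples")
  }
  trm <- stats::terms(formula, data = data)
  labels <- attr(trm, "term.labels")
  check_that(length(labels) >= 1L, "formula has no terms")
  for (v in all.vars(formula)) {
    col <- data[[v]]
    check_that(!is.null(col), sprintf("covariate '%s' not in data", v))
    if (is.numeric(col)) {
      check_that(stats::sd(col) > 0, sprintf("constant covariate '%s'", v))
    }
  }
  list(data = data, labels = labels, formula = formula)
}

# hat matrix (projector) of a model matrix, via QR
hat_of <- function(x) {
  qx <- qr(x)
  q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(q)
}

#' Permutational multivariate analysis of variance (PERMANOVA / ADONIS)
#'
#' Partitions the inertia of a dissimilarity matrix among model terms using
#' trace forms of the Gower-centered matrix `G`: for hat matrix `H`,
#' `pseudo-F = [tr(HGH)/df_model] / [tr((I-H)G(I-H))/df_resid]` and
#' `R^2 = tr(HGH)/tr(G)`. Terms are added sequentially (Type I) in formula
#' order by default; `by = "margin"` tests each term after all others.
#' Significance is assessed by raw permutation of the rows/columns of the
#' distance matrix, with the +1-corrected p-value; `exhaustive = TRUE`
#' enumerates every relabeling (small n).
#'
#' @param d A [dist_matrix].
#' @param data Data frame of covariates/factors, matched to samples via a
#'   `sample_id` column or row order.
#' @param formula One-sided formula of terms, e.g. `~ PRE + pH`.
#' @param n_perm Number of permutations (>= 99); default 999.
#' @param seed RNG seed.
#' @param by `"terms"` (sequential) or `"margin"`.
#' @param exhaustive Enumerate all `n!` permutations (n <= 8).
#' @return A `perm_test` object whose `table` has one row per term with
#'   `df`, `sum_sq`, `r_squared`, `statistic` (pseudo-F) and `p_value`.
#' @export
permanova <- function(d, data, formula, n_perm = 999, seed = 1L,
                      by = c("terms", "margin"), exhaustive = FALSE) {
  by <- match.arg(by)
  m <- as.matrix(as_dist_matrix(d, units = "raw"))
  ids <- rownames(m)
  n <- length(ids)
  des <- design_matrix(data, formula, ids)
  g <- gower_center(m)
  tr_g <- sum(diag(g))

  mk_model <- function(labels) {
    if (length(labels) == 0L) {
      x <- matrix(1, n, 1)
    } else {
      f <- stats::reformulate(labels)
      x <- stats::model.matrix(f, data = des$data)
    }
    list(hat = hat_of(x), rank = qr(x)$rank)
  }
  full <- mk_model(des$labels)
  check_that(full$rank < n, "design saturates the samples (no residual df)")
  df_res <- n - full$rank
  if (length(des$labels) > 1L && by == "terms") {
    nested <- lapply(seq_along(des$labels),
                     function(j) mk_model(des$labels[seq_len(j)]))
  }
  if (by == "margin") {
    reduced <- lapply(seq_along(des$labels),
                      function(j) mk_model(des$labels[-j]))
  }

  # per-term model/residual traces for a (permuted) G; intercept term of the
  # hat matrix contributes nothing because G is doubly centered
  stats_for <- function(gp) {
    tr_full <- sum(full$hat * gp)
    ss_res <- tr_g - tr_full
    if (by == "terms") {
      if (length(des$labels) == 1L) {
        ss <- tr_full
        df <- full$rank - 1L
      } else {
        trs <- vapply(nested, function(mdl) sum(mdl$hat * gp), numeric(1))
        ss <- diff(c(0, trs))
        df <- diff(c(1L, vapply(nested, `[[`, integer(1), "rank")))
      }
    } else {
      ss <- df <- numeric(length(des$labels))
      for (j in seq_along(des$labels)) {
        ss[j] <- tr_full - sum(reduced[[j]]$hat * gp)
        df[j] <- full$rank - reduced[[j]]$rank
      }
    }
    check_that(all(df >= 1), "rank-deficient design (aliased term)")
    list(ss = ss, df = df,
         f = (ss / df) / (ss_res / df_res), ss_res = ss_res)
  }
  obs <- stats_for(g)

  k <- length(des$labels)
  if (exhaustive) {
    check_that(n <= 8L, "exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    fperm <- vapply(perms, function(p) stats_for(g[p, p])$f, numeric(k))
    fperm <- matrix(fperm, nrow = k)
    p_val <- rowMeans(fperm >= obs$f - 1e-12)
    n_used <- length(perms)
  } else {
    check_that(n_perm >= 99L, "use at least 99 permutations")
    fperm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        stats_for(g[p, p])$f
      }, numeric(k))
    })
    fperm <- matrix(fperm, nrow = k)
    p_val <- (1 + rowSums(fperm >= obs$f - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }

  tab <- tibble::tibble(
    term = des$labels,
    df = as.integer(obs$df),
    sum_sq = obs$ss,
    r_squared = obs$ss / tr_g,
    statistic = obs$f,
    p_value = p_val
  )
  structure(list(test = "permanova", table = tab, by = by,
                 residual = tibble::tibble(df = df_res, sum_sq = obs$ss_res),
                 total_ss = tr_g, n_permutations = n_used,
                 exhaustive = exhaustive, n_samples = n),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s (%s permutations)\n", x$test,
              if (isTRUE(x$exhaustive)) "exhaustive" else x$n_permutations))
  print(x$table)
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities and computes
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`. R near 1 means groups are well separated; significance by
#' permutation of group labels (one-sided, large R).
#'
#' @param d A [dist_matrix].
#' @param groups Group labels aligned with the samples (length n, >= 2
#'   groups, each of size >= 2).
#' @inheritParams permanova
#' @return A `perm_test` object with statistic `R`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  m <- as.matrix(as_dist_matrix(d, units = "raw"))
  n <- nrow(m)
  groups <- as.factor(groups)
  check_that(length(groups) == n, "groups must align with samples")
  check_that(nlevels(droplevels(groups)) >= 2L, "need at least 2 groups")
  check_that(all(table(groups) >= 2L), "every group needs >= 2 samples")
  ut <- upper.tri(m)
  rk <- rank(m[ut])
  big_m <- n * (n - 1) / 2
  same <- outer(groups, groups, `==`)[ut]
  r_for <- function(g) {
    same_g <- outer(g, g, `==`)[ut]
    (mean(rk[!same_g]) - mean(rk[same_g])) / (big_m / 2)
  }
  r_obs <- (mean(rk[!same]) - mean(rk[same])) / (big_m / 2)
  if (exhaustive) {
    check_that(n <= 8L, "exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) r_for(groups[p]), numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    check_that(n_perm >= 99L, "use at least 99 permutations")
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) r_for(groups[sample.int(n)]),
             numeric(1))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tab <- tibble::tibble(term = "groups", df = NA_integer_,
                        sum_sq = NA_real_, r_squared = NA_real_,
                        statistic = r_obs, p_value = p)
  structure(list(test = "anosim", table = tab, n_permutations = n_used,
                 exhaustive = exhaustive, n_samples = n),
            class = "perm_test")
}

#' Constrained analysis of principal coordinates (CAP / db-RDA)
#'
#' PCoA axes (positive eigenvalues) are regressed on the constraint matrix;
#' the eigen-analysis of the fitted values yields the constrained axes and
#' the constrained inertia, which is tested by row permutation with a
#' pseudo-F of the constrained versus residual inertia fraction (as in
#' [permanova()]).
#'
#' @param d A [dist_matrix].
#' @param data Covariate data frame (see [permanova()]).
#' @param formula One-sided formula of constraints.
#' @param n_perm,seed,exhaustive Permutation settings.
#' @param eig_tol Eigenvalue cutoff passed to [pcoa()].
#' @return A list with elements `ordination` (constrained axes) and `test`
#'   (a `perm_test`), plus inertia bookkeeping.
#' @export
cap <- function(d, data, formula, n_perm = 999, seed = 1L,
                exhaustive = FALSE, eig_tol = 1e-10) {
  ord <- pcoa(d, eig_tol = eig_tol)
  y <- ord$scores
  n <- nrow(y)
  ids <- ord$sample_ids
  des <- design_matrix(data, formula, ids)
  x <- stats::model.matrix(stats::reformulate(des$labels), data = des$data)
  x <- x[, -1, drop = FALSE]             # drop intercept;
  x <- scale(x, center = TRUE, scale = FALSE)  # scores are centered already
  q_rank <- qr(x)$rank
  check_that(q_rank <= n - 2L, "more constraints than samples - 1")
  h <- hat_of(x)

  total <- sum(y^2)
  ci_for <- function(yp) sum((h %*% yp)^2)
  ci_obs <- ci_for(y)
  df_res <- n - 1L - q_rank
  f_for <- function(ci) (ci / q_rank) / ((total - ci) / df_res)
  f_obs <- f_for(ci_obs)

  if (exhaustive) {
    check_that(n <= 8L, "exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) f_for(ci_for(y[p, , drop = FALSE])),
                     numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    check_that(n_perm >= 99L, "use at least 99 permutations")
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        f_for(ci_for(y[sample.int(n), , drop = FALSE]))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }

  yhat <- h %*% y
  sv <- svd(yhat)
  keep <- sv$d^2 > eig_tol
  cap_scores <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = sum(keep))
  dimnames(cap_scores) <- list(ids, if (any(keep))
    paste0("CAP", seq_len(sum(keep))) else character(0))
  constrained <- structure(list(
    scores = cap_scores,
    eigenvalues = sv$d[keep]^2,
    all_eigenvalues = sv$d^2,
    proportion = sv$d[keep]^2 / total,
    total_inertia = total,
    type = "constrained",
    sample_ids = ids
  ), class = "ordination")

  tab <- tibble::tibble(term = deparse(formula), df = as.integer(q_rank),
                        sum_sq = ci_obs, r_squared = ci_obs / total,
                        statistic = f_obs, p_value = p)
  test <- structure(list(test = "cap", table = tab, n_permutations = n_used,
                         exhaustive = exhaustive, n_samples = n),
                    class = "perm_test")
  list(ordination = constrained, test = test,
       constrained_inertia = ci_obs,
       unconstrained_inertia = total - ci_obs,
       total_inertia = total, pcoa = ord)
}
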