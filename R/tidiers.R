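#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a distance-decay fit
#'
#' @param x A `ddr_fit`.
#' @param ... Unused.
#' @return One row per coefficient (`intercept`, `slope`).
#' @export
tidy.ddr_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(NA_real_, x$slope_se))
}

#' @rdname tidy.ddr_fit
#' @export
glance.ddr_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 intercept = x$intercept, r_squared = x$r_squared,
                 p_value = x$p_value, n_pairs = x$n_pairs,
                 n_samples = x$n_samples)
}

#' Tidy a Mantel test result
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_permutations = x$n_permutations)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- tidy.mantel_result

#' Tidy a permutation test (PERMANOVA / ANOSIM / CAP)
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return The per-term table: `term`, `df`, `sum_sq`, `r_squared`,
#'   `statistic`, `p_value`.
#' @export
tidy.perm_test <- function(x, ...) x$table

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(test = x$test, n_permutations = x$n_permutations,
                 n_samples = x$n_samples,
                 min_p = min(x$table$p_value))
}

#' Tidy an ordination
#' @param x An `ordination`.
#' @param ... Unused.
#' @return Sample scores in long-friendly wide form (one row per sample).
#' @export
tidy.ordination <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname tidy.ordination
#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(type = x$type, n_axes = ncol(x$scores),
                 total_inertia = x$total_inertia,
                 prop_axis1 = x$proportion[1],
                 prop_axis2 = if (length(x$proportion) > 1)
                   x$proportion[2] else NA_real_)
}

#' Tidy a core-contribution result
#' @param x A `core_contribution`.
#' @param ... Unused.
#' @export
tidy.core_contribution <- function(x, ...) x$pairs

#' @rdname tidy.core_contribution
#' @export
glance.core_contribution <- function(x, ...) {
  tibble::tibble(n_core = x$n_core, mean_pct = x$mean_pct,
                 min_pct = x$range_pct[1], max_pct = x$range_pct[2],
                 on = x$on)
}

#' Tidy a core set
#' @param x A `core_set`.
#' @param ... Unused.
#' @export
tidy.core_set <- function(x, ...) {
  dplyr::mutate(x$prevalence, core = .data$otu_id %in% x$otu_ids)
}

#' @rdname tidy.core_set
#' @export
glance.core_set <- function(x, ...) {
  tibble::tibble(n_core = length(x$otu_ids), n_taxa = x$n_taxa_total,
                 fraction_pct = core_fraction(x), threshold = x$threshold)
}

#' Tidy a core-genus/environment correlation result
#' @param x A `core_env_cor`.
#' @param ... Unused.
#' @export
tidy.core_env_cor <- function(x, ...) x$table

#' Tidy a keystone report
#' @param x A `keystone_report`.
#' @param ... Unused.
#' @export
tidy.keystone_report <- function(x, ...) x$ranking

#' @rdname tidy.keystone_report
#' @export
glance.keystone_report <- function(x, ...) {
  tibble::tibble(k = x$k, n_nodes = nrow(x$ranking),
                 top = x$keystones$node[1],
                 top_betweenness = x$keystones$betweenness[1])
}

#' Tidy an Erdős–Rényi null ensemble
#' @param x An `er_ensemble`.
#' @param ... Unused.
#' @export
tidy.er_ensemble <- function(x, ...) x$replicates

#' @rdname tidy.er_ensemble
#' @export
glance.er_ensemble <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summary, names_from = "metric",
                            values_from = c("mean", "sd"))
  dplyr::mutate(out, n_nodes = x$n_nodes, n_edges = x$n_edges,
                n_reps = x$n_reps, expected_density = x$expected_density)
}
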