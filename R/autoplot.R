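#' @import ggplot2
NULL

#' Plot a distance-decay relationship
#'
#' Scatter of pairwise community similarity against geographic distance with
#' the fitted least-squares line.
#'
#' @param object A `ddr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddr_fit <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$distance_km, y = .data$similarity)) +
    geom_point(alpha = 0.5, colour = "grey30") +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "firebrick", linewidth = 0.8) +
    labs(
      x = "Geographic distance (km)",
      y = "Community similarity (1 - dissimilarity)",
      title = sprintf("Distance decay: w = %.3g /km, R² = %.2f, p = %.3g",
                      object$slope, object$r_squared, object$p_value)
    ) +
    theme_minimal()
}

#' Plot an ordination
#'
#' First two axes of a PCoA or CAP ordination, optionally coloured by a
#' metadata column.
#'
#' @param object An `ordination`.
#' @param metadata Optional `site_metadata` to join on `sample_id`.
#' @param colour Optional metadata column name used for point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ordination <- function(object, metadata = NULL, colour = NULL,
                                ...) {
  df <- tidy(object)
  axes <- colnames(object$scores)[1:min(2L, ncol(object$scores))]
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, tibble::as_tibble(metadata), by = "sample_id")
  }
  p <- ggplot(df, aes(x = .data[[axes[1]]],
                      y = .data[[axes[length(axes)]]])) +
    labs(
      x = sprintf("%s (%.1f%%)", axes[1], 100 * object$proportion[1]),
      y = if (length(axes) > 1)
        sprintf("%s (%.1f%%)", axes[2], 100 * object$proportion[2])
      else axes[1],
      title = sprintf("%s ordination",
                      if (object$type == "constrained") "CAP" else "PCoA")
    ) +
    theme_minimal()
  if (!is.null(colour)) {
    p + geom_point(aes(colour = .data[[colour]]), size = 2.5)
  } else {
    p + geom_point(size = 2.5, colour = "grey30")
  }
}

#' Heatmap of core-genus/environment correlations
#'
#' Reproduces the masked-heatmap contract: only strong, FDR-significant
#' cells are coloured; all others are blank.
#'
#' @param object A `core_env_cor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.core_env_cor <- function(object, ...) {
  df <- dplyr::mutate(object$table,
                      r_shown = ifelse(.data$retained, .data$r, NA_real_))
  ggplot(df, aes(x = .data$covariate, y = .data$genus,
                 fill = .data$r_shown)) +
    geom_tile(colour = "grey80") +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", limits = c(-1, 1),
                         na.value = "white",
                         name = "Spearman r") +
    labs(x = NULL, y = NULL,
         title = sprintf("Core genera vs environment (|r| > %g, q < %g)",
                         object$r_min, object$alpha)) +
    theme_minimal()
}

#' Distribution of a topology metric across the Erdős–Rényi null ensemble
#'
#' @param object An `er_ensemble`.
#' @param metric Metric column to plot (default `"diameter"`).
#' @param observed Optional observed value drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.er_ensemble <- function(object, metric = "diameter",
                                 observed = NULL, ...) {
  check_that(metric %in% names(object$replicates),
             sprintf("metric '%s' not in ensemble", metric))
  p <- ggplot(object$replicates, aes(x = .data[[metric]])) +
    geom_histogram(bins = 30, fill = "grey60", colour = "grey30") +
    labs(x = metric, y = "replicates",
         title = sprintf("G(%d, %d) null ensemble", object$n_nodes,
                         object$n_edges)) +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_vline(xintercept = observed, colour = "firebrick",
                        linewidth = 0.8)
  }
  p
}

#' Compare betweenness of core and other nodes
#'
#' Boxplot of betweenness-centrality distributions for core versus non-core
#' nodes of a co-occurrence network.
#'
#' @param network An annotated co-occurrence graph with a `core` vertex
#'   attribute.
#' @return A ggplot.
#' @export
plot_core_betweenness <- function(network) {
  flags <- igraph::V(network)$core
  check_that(!is.null(flags), "network has no `core` node attribute")
  bt <- betweenness_centrality(network)
  bt$group <- ifelse(flags, "core", "other")
  ggplot(bt, aes(x = .data$group, y = .data$betweenness + 1,
                 fill = .data$group)) +
    geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    scale_y_log10() +
    scale_fill_manual(values = c(core = "steelblue", other = "firebrick")) +
    labs(x = NULL, y = "betweenness centrality + 1") +
    theme_minimal()
}
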