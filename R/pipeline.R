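#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Supply
#' either `input` (paths to an OTU table, metadata and optionally a newick
#' tree) or `synthetic` (a [synthetic_config()] or a list of its overrides).
#' Can also be loaded from a YAML file via [read_pipeline_config()].
#'
#' @param out_dir Output directory for the results bundle.
#' @param input Optional list with `otu_table`, `metadata`, and optionally
#'   `tree` file paths.
#' @param synthetic Optional [synthetic_config()] (or override list) used
#'   when no `input` is given.
#' @param rarefy_depth `"min"` or a fixed depth.
#' @param r_min,q_max Network edge thresholds.
#' @param core_prevalence Core prevalence threshold.
#' @param keystone_k Number of keystone genera to report.
#' @param n_perm Permutations for Mantel/PERMANOVA/ANOSIM/CAP.
#' @param er_reps Erdős–Rényi null replicates.
#' @param permanova_terms Covariate names for the PERMANOVA/CAP formula
#'   (default: all environmental covariates).
#' @param anosim_group Metadata column of group labels (default
#'   `"soil_type"` when present).
#' @param seed Master seed; every stochastic stage derives its own child
#'   seed from it via [child_seed()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input = NULL, synthetic = NULL,
                            rarefy_depth = "min", r_min = 0.6, q_max = 0.01,
                            core_prevalence = 1.0, keystone_k = 7L,
                            n_perm = 999L, er_reps = 100L,
                            permanova_terms = NULL,
                            anosim_group = "soil_type", seed = 1L) {
  check_that(is.character(out_dir) && length(out_dir) == 1L,
             "`out_dir` must be a single path")
  if (is.null(input)) {
    if (is.null(synthetic)) synthetic <- list()
    if (!inherits(synthetic, "synthetic_config")) {
      if (is.null(synthetic$seed)) {
        synthetic$seed <- child_seed(seed, "synthetic")
      }
      synthetic <- do.call(synthetic_config, synthetic)
    }
  } else {
    check_that(all(c("otu_table", "metadata") %in% names(input)),
               "`input` needs `otu_table` and `metadata` paths")
  }
  check_that(identical(rarefy_depth, "min") ||
               (is.numeric(rarefy_depth) && rarefy_depth > 0),
             "`rarefy_depth` must be \"min\" or a positive number")
  check_that(r_min >= -1 && r_min <= 1 && q_max > 0 && q_max <= 1,
             "thresholds out of range")
  check_that(core_prevalence > 0 && core_prevalence <= 1,
             "`core_prevalence` must be in (0, 1]")
  structure(list(out_dir = out_dir, input = input, synthetic = synthetic,
                 rarefy_depth = rarefy_depth, r_min = r_min, q_max = q_max,
                 core_prevalence = core_prevalence,
                 keystone_k = as.integer(keystone_k),
                 n_perm = as.integer(n_perm), er_reps = as.integer(er_reps),
                 permanova_terms = permanova_terms,
                 anosim_group = anosim_group, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys are `pipeline_config()`
#'   arguments (`synthetic` as a nested map of [synthetic_config()] fields).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data ingestion or synthesis, rarefaction to even
#' depth, alpha diversity and its environmental correlations, beta diversity
#' (Bray-Curtis and, when a tree is present, weighted UniFrac), geographic
#' distances and the distance-decay regression (community-wide and
#' per-phylum), Mantel/PERMANOVA/CAP/ANOSIM tests, core-microbiome detection
#' with partitioned Bray-Curtis contribution and core-genus/environment
#' correlations, and OTU- and genus-level co-occurrence networks with an
#' Erdős–Rényi null comparison and keystone identification. All tables are
#' written as TSV under `out_dir`, test results additionally as one JSON
#' document, plus a manifest recording config and seed so the run can be
#' reproduced bit-identically.
#'
#' @param config A [pipeline_config()] or a path to a YAML config file.
#' @return A `results_bundle` list (invisibly) with every intermediate
#'   result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list(config = config)

  # -- data -----------------------------------------------------------------
  res$data <- stage("data", {
    if (is.null(config$input)) {
      generate_synthetic(config$synthetic)
    } else {
      list(
        table = read_otu_table(config$input$otu_table),
        metadata = read_metadata(config$input$metadata),
        tree = if (!is.null(config$input$tree))
          read_newick(config$input$tree),
        truth = NULL
      )
    }
  })
  table <- res$data$table
  metadata <- res$data$metadata
  tree <- res$data$tree

  # -- rarefaction ----------------------------------------------------------
  res$rarefied <- stage("rarefy", {
    depth <- if (identical(config$rarefy_depth, "min")) {
      min(rowSums(table$counts))
    } else config$rarefy_depth
    rarefy(table, depth = depth, seed = child_seed(config$seed, "rarefy"))
  })

  # -- alpha diversity ------------------------------------------------------
  res$alpha <- stage("alpha", alpha_diversity(res$rarefied))
  res$alpha_env <- stage("alpha_env", {
    covs <- env_covariates(metadata)
    md <- metadata[match(res$alpha$sample_id, metadata$sample_id), ]
    purrr::map_dfr(c("richness", "shannon"), function(idx) {
      purrr::map_dfr(covs, function(v) {
        ct <- suppressWarnings(stats::cor.test(res$alpha[[idx]], md[[v]],
                                               method = "spearman",
                                               exact = FALSE))
        tibble::tibble(index = idx, covariate = v,
                       r = unname(ct$estimate), p = ct$p.value)
      })
    })
  })

  # -- beta diversity -------------------------------------------------------
  res$bray_curtis <- stage("beta", bray_curtis(res$rarefied))
  if (!is.null(tree)) {
    res$weighted_unifrac <- stage("beta",
                                  weighted_unifrac(res$rarefied, tree))
  }
  beta <- res$weighted_unifrac %||% res$bray_curtis

  # -- spatial --------------------------------------------------------------
  res$geo <- stage("spatial", haversine_matrix(metadata))
  res$ddr <- stage("ddr", ddr_fit(res$geo, beta))
  res$ddr_by_phylum <- stage("ddr_phylum", {
    if (is.null(table$lineages)) return(NULL)
    counts_by_phylum <- table(table$lineages$phylum)
    phyla <- names(counts_by_phylum)[counts_by_phylum >= 5]
    purrr::map_dfr(phyla, function(ph) {
      fit <- tryCatch(ddr_by_phylum(res$rarefied, res$geo, ph),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      dplyr::mutate(glance(fit), phylum = ph, .before = 1)
    })
  })
  res$mantel_env_geo <- stage("mantel", {
    covs <- env_covariates(metadata)
    edaphic <- setdiff(covs, c("PRE", "TEM"))
    if (length(edaphic) < 1L) edaphic <- covs
    md <- metadata[match(rownames(res$geo), metadata$sample_id), ]
    env_d <- as.matrix(stats::dist(scale(as.matrix(md[, edaphic]))))
    dimnames(env_d) <- list(md$sample_id, md$sample_id)
    mantel(res$geo, dist_matrix(env_d, units = "raw"),
           n_perm = config$n_perm, seed = child_seed(config$seed, "mantel"))
  })

  # -- multivariate ---------------------------------------------------------
  terms <- config$permanova_terms %||% env_covariates(metadata)
  form <- stats::reformulate(terms)
  res$pcoa <- stage("pcoa", pcoa(beta))
  res$permanova <- stage("permanova", {
    permanova(beta, metadata, form, n_perm = config$n_perm,
              seed = child_seed(config$seed, "permanova"))
  })
  res$cap <- stage("cap", {
    cap(beta, metadata, form, n_perm = config$n_perm,
        seed = child_seed(config$seed, "cap"))
  })
  if (!is.null(config$anosim_group) &&
        config$anosim_group %in% names(metadata)) {
    res$anosim <- stage("anosim", {
      md <- metadata[match(rownames(beta), metadata$sample_id), ]
      groups <- factor(md[[config$anosim_group]])
      ok <- table(groups)[groups] >= 2
      ids <- md$sample_id[ok]
      if (length(unique(groups[ok])) >= 2L && sum(ok) >= 4L) {
        b <- dist_matrix(as.matrix(beta)[ids, ids], units = "raw")
        anosim(b, droplevels(groups[ok]), n_perm = config$n_perm,
               seed = child_seed(config$seed, "anosim"))
      }
    })
  }

  # -- core microbiome ------------------------------------------------------
  res$core <- stage("core", find_core(res$rarefied,
                                      prevalence = config$core_prevalence))
  res$core_contribution <- stage("core_contribution",
                                 core_contribution(res$rarefied, res$core))
  res$core_env <- stage("core_env", {
    if (is.null(table$lineages)) return(NULL)
    core_env_correlations(res$rarefied, res$core, metadata)
  })

  # -- co-occurrence networks ----------------------------------------------
  res$network <- stage("network", {
    cm <- correlation_matrix(res$rarefied)
    q <- fdr_adjust(cm$p)
    build_network(cm$r, q, r_min = config$r_min, q_max = config$q_max,
                  lineages = table$lineages, core = res$core)
  })
  res$topology <- stage("topology", topology(res$network))
  res$er_null <- stage("er_null", {
    er_null_ensemble(res$topology$n_nodes, max(res$topology$n_edges, 1L),
                     n_reps = config$er_reps,
                     seed = child_seed(config$seed, "er_null"))
  })
  res$er_z <- stage("er_null", er_z_scores(res$er_null, res$topology))
  res$core_vs_other <- stage("subnetworks", {
    tryCatch(compare_core_subnetworks(res$network),
             error = function(e) NULL)
  })
  res$genus_network <- stage("genus_network", {
    if (is.null(table$lineages)) return(NULL)
    gt <- aggregate_to_genus(res$rarefied)
    cm <- correlation_matrix(gt)
    q <- fdr_adjust(cm$p)
    build_network(cm$r, q, r_min = config$r_min, q_max = config$q_max,
                  lineages = gt$lineages,
                  core = unique(table$lineages$genus[
                    table$lineages$otu_id %in% res$core$otu_ids]))
  })
  res$keystones <- stage("keystones", {
    if (is.null(res$genus_network)) return(NULL)
    keystone_taxa(res$genus_network,
                  k = min(config$keystone_k,
                          igraph::vcount(res$genus_network)))
  })

  stage("write", write_bundle(res, out))
  class(res) <- "results_bundle"
  invisible(res)
}

write_bundle <- function(res, out) {
  config <- res$config
  readr::write_tsv(res$alpha, out("alpha_diversity.tsv"), progress = FALSE)
  readr::write_tsv(res$alpha_env, out("alpha_env_correlations.tsv"),
                   progress = FALSE)
  write_distance_matrix(res$bray_curtis, out("bray_curtis.tsv"))
  if (!is.null(res$weighted_unifrac)) {
    write_distance_matrix(res$weighted_unifrac, out("weighted_unifrac.tsv"))
  }
  write_distance_matrix(res$geo, out("geographic_km.tsv"))
  ddr_tab <- glance(res$ddr)
  if (!is.null(res$ddr_by_phylum) && nrow(res$ddr_by_phylum) > 0) {
    ddr_tab <- dplyr::bind_rows(
      dplyr::mutate(ddr_tab, phylum = "(all)", .before = 1),
      res$ddr_by_phylum)
  }
  readr::write_tsv(ddr_tab, out("ddr_fits.tsv"), progress = FALSE)
  tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(res$permanova), test = "permanova", .before = 1),
    dplyr::mutate(tidy(res$cap$test), test = "cap", .before = 1),
    if (!is.null(res$anosim))
      dplyr::mutate(tidy(res$anosim), test = "anosim", .before = 1),
    tibble::tibble(test = "mantel_env_geo", term = "edaphic~geographic",
                   statistic = res$mantel_env_geo$statistic,
                   p_value = res$mantel_env_geo$p_value)
  )
  readr::write_tsv(tests, out("permutation_tests.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(otu_id = res$core$otu_ids),
                   out("core_otus.tsv"), progress = FALSE)
  readr::write_tsv(res$core_contribution$pairs,
                   out("core_contribution_pairs.tsv"), progress = FALSE)
  if (!is.null(res$core_env)) {
    readr::write_tsv(res$core_env$table, out("core_env_correlations.tsv"),
                     progress = FALSE)
  }
  write_network(res$network, out("network_otu.graphml"))
  write_network(res$network, out("network_otu_edges.tsv"),
                format = "edgelist")
  if (!is.null(res$genus_network)) {
    write_network(res$genus_network, out("network_genus.graphml"))
  }
  readr::write_tsv(res$topology, out("network_topology.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$er_z, out("er_null_comparison.tsv"),
                   progress = FALSE)
  if (!is.null(res$keystones)) {
    readr::write_tsv(res$keystones$keystones, out("keystone_genera.tsv"),
                     progress = FALSE)
  }

  results_json <- list(
    seed = config$seed,
    ddr = as.list(glance(res$ddr)),
    mantel_env_geo = list(r = res$mantel_env_geo$statistic,
                          p = res$mantel_env_geo$p_value),
    permanova = res$permanova$table,
    cap = res$cap$test$table,
    anosim = if (!is.null(res$anosim)) res$anosim$table,
    core = list(n_core = length(res$core$otu_ids),
                fraction_pct = core_fraction(res$core),
                contribution_mean_pct = res$core_contribution$mean_pct,
                contribution_range_pct = res$core_contribution$range_pct),
    topology = as.list(res$topology),
    er_null = res$er_z,
    wilcoxon_core_betweenness = if (!is.null(res$core_vs_other))
      res$core_vs_other$wilcoxon,
    keystones = if (!is.null(res$keystones)) res$keystones$keystones$node
  )
  jsonlite::write_json(results_json, out("results.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  manifest <- list(
    package = "soilbiogeo",
    package_version = as.character(utils::packageVersion("soilbiogeo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "input")]),
    created = "run manifest"
  )
  manifest$config$synthetic <- unclass(manifest$config$synthetic)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10, null = "null")
  invisible(NULL)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat(sprintf("  out_dir: %s\n", x$config$out_dir))
  cat(sprintf("  samples: %d, OTUs: %d (rarefied depth %d)\n",
              n_samples(x$rarefied), n_taxa(x$rarefied),
              min(rowSums(x$rarefied$counts))))
  cat(sprintf("  DDR slope: %.3g/km (p = %.3g)\n", x$ddr$slope,
              x$ddr$p_value))
  cat(sprintf("  core: %d OTUs, %.1f%% mean contribution\n",
              length(x$core$otu_ids), x$core_contribution$mean_pct))
  cat(sprintf("  network: %d nodes, %d edges\n", x$topology$n_nodes,
              x$topology$n_edges))
  invisible(x)
}
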