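#' Configuration for the synthetic community generator
#'
#' Defaults emulate the post-clustering state of a 21-site continental soil
#' survey: latitude-correlated climate, log-normal OTU abundances, a core
#' set present in every sample, spatially autocorrelated composition
#' producing a near-linear distance decay over the sampled range, a handful
#' of environmental responder OTUs, and correlated "guilds" that a
#' co-occurrence network should recover as edges. Library sizes are drawn
#' log-normally within roughly 18,000-37,000 reads to motivate rarefaction.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_sites = 21L,
    n_otus = 300L,
    n_core = NULL,  # default: ~8% of n_otus, the share real surveys report
    n_guilds = 5L,
    guild_size = 6L,
    n_env_responders = 8L,
    env_responder_covariates = c("pH", "PRE", "TEM", "AN"),
    lat_range = c(18.5, 46.5),
    lon_range = c(77, 127),
    spatial_range_km = 1500,
    spatial_sd = 1,
    guild_sd = 2,
    guild_mu_offset = 0,
    env_effect = 1,
    noise_sd = 0.5,
    base_sd = 1.5,
    core_mu_boost = 1.5,
    library_meanlog = log(26000),
    library_sdlog = 0.12,
    library_range = c(18000, 37000),
    phylum_range_km = NULL,
    frac_genus_unassigned = 0.15,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  check_that(length(unknown) == 0L,
             paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (is.null(cfg$n_core)) cfg$n_core <- max(1L, round(0.08 * cfg$n_otus))
  check_that(cfg$n_sites >= 3L, "n_sites must be >= 3")
  check_that(cfg$n_otus >= 2L && cfg$n_core >= 0L &&
               cfg$n_core <= cfg$n_otus, "need 0 <= n_core <= n_otus")
  check_that(cfg$n_guilds * cfg$guild_size <= cfg$n_otus,
             "guild members exceed n_otus")
  check_that(cfg$noise_sd >= 0 && cfg$guild_sd >= 0 && cfg$spatial_sd >= 0,
             "effect SDs must be non-negative")
  structure(cfg, class = "synthetic_config")
}

# phylum pool with realistic continental-soil relative frequencies
.phylum_pool <- function() {
  c(Proteobacteria = 0.431, Actinobacteria = 0.244, Acidobacteria = 0.107,
    Chloroflexi = 0.060, Gemmatimonadetes = 0.055, Bacteroidetes = 0.040,
    Planctomycetes = 0.030, Firmicutes = 0.020, Verrucomicrobia = 0.013)
}

.genus_names <- c(
  "Rhodococcus", "Skermanella", "Pedobacter", "Aeromicrobium", "Nitrospira",
  "Streptomyces", "Nocardioides", "Lysobacter", "Ramlibacter", "Kaistobacter",
  "Thermomonas", "Janthinobacterium", "Friedmanniella", "Saccharothrix",
  "Sinorhizobium", "Rubellimicrobium", "Nonomuraea", "Pilimelia",
  "Nannocystis", "Lamia")

#' Generate a synthetic site landscape
#'
#' Sites span the configured bounding box; mean annual precipitation (PRE)
#' and temperature (TEM) decrease with latitude plus noise, so their
#' Spearman correlation with latitude is negative (exactly -1 at
#' `noise_sd = 0`); pH is drawn within 5.2-8.9 and the remaining edaphic
#' covariates within field-realistic ranges.
#'
#' @param config A [synthetic_config()].
#' @return A `site_metadata` tibble with `n_sites` rows.
#' @export
generate_landscape <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  check_that(diff(config$lat_range) > 0 && diff(config$lon_range) > 0,
             "degenerate bounding box")
  n <- config$n_sites
  with_seed(child_seed(config$seed, "landscape"), {
    lat <- sort(stats::runif(n, config$lat_range[1], config$lat_range[2]))
    lon <- stats::runif(n, config$lon_range[1], config$lon_range[2])
    pre <- 2200 - 68 * (lat - config$lat_range[1]) +
      stats::rnorm(n, 0, 120 * config$noise_sd)
    tem <- 25.5 - 0.72 * (lat - config$lat_range[1]) +
      stats::rnorm(n, 0, 1.6 * config$noise_sd)
    site_metadata(tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      latitude = lat,
      longitude = lon,
      pH = round(stats::runif(n, 5.2, 8.9), 2),
      AK = round(stats::runif(n, 50, 325), 1),
      OC = round(stats::rlnorm(n, log(15), 0.5), 2),
      TN = round(stats::runif(n, 0.15, 1.25), 2),
      AN = round(stats::runif(n, 3, 176), 2),
      AP = round(pmin(stats::rlnorm(n, log(25), 0.8), 180), 2),
      PRE = pmax(pre, 5),  # full precision: rounding could tie the
      TEM = tem,           # noiseless monotone construction

      soil_type = sample(c("sandy clay loam", "clay loam", "loamy clay",
                           "sandy loam", "silty clay loam", "loam"),
                         n, replace = TRUE)
    ))
  })
}

# exponential spatial covariance factor; range <= 0 disables autocorrelation
.spatial_chol <- function(d_km, range_km) {
  n <- nrow(d_km)
  if (range_km <= 0) return(diag(n))
  c_mat <- exp(-d_km / range_km)
  chol(c_mat + diag(1e-8, n))
}

#' Generate a synthetic OTU table with planted structure
#'
#' Per-OTU expected log-abundance is the sum of (a) a log-normal baseline,
#' (b) a spatial Gaussian random field with exponential correlation of
#' length `spatial_range_km` (this is what produces the distance decay),
#' (c) a shared latent factor for each guild (`guild_sd`), (d) a linear
#' response to one environmental covariate for the responder OTUs
#' (`env_effect`), and (e) i.i.d. log-scale noise (`noise_sd`). Counts are
#' multinomial per site at a log-normal library size; each core OTU
#' additionally receives one guaranteed read per sample (a floor that fixes
#' its prevalence at exactly 1), and core baselines are boosted by
#' `core_mu_boost` so the core is abundant as well as ubiquitous. The tree
#' is a random coalescent over the OTU ids.
#'
#' The returned `truth` records the planted core set, guild edge list,
#' environmental effects, and the planted distance-decay slope — defined as
#' the OLS slope of Bray-Curtis similarity against distance computed on the
#' noiseless expected relative-abundance profiles.
#'
#' @param config A [synthetic_config()].
#' @param landscape A `site_metadata` from [generate_landscape()].
#' @return A list with elements `table` ([otu_table]), `tree`
#'   ([ape::phylo]), and `truth` (a `synthetic_truth` list).
#' @export
generate_community <- function(config = synthetic_config(),
                               landscape = generate_landscape(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  landscape <- site_metadata(landscape)
  n <- nrow(landscape)
  p <- config$n_otus
  otu_ids <- sprintf("OTU_%04d", seq_len(p))
  d_km <- as.matrix(haversine_matrix(landscape))

  with_seed(child_seed(config$seed, "community"), {
    # taxonomy: phylum by pool frequency, genus from a per-phylum pool
    pool <- .phylum_pool()
    phylum <- sample(names(pool), p, replace = TRUE, prob = pool)
    n_genera <- max(4L, ceiling(p / 4))
    genus_pool <- c(.genus_names,
                    sprintf("Genus_%03d", seq_len(max(0, n_genera -
                                                        length(.genus_names)))))
    genus_pool <- genus_pool[seq_len(n_genera)]
    genus_phylum <- sample(names(pool), n_genera, replace = TRUE, prob = pool)
    genus <- vapply(seq_len(p), function(i) {
      candidates <- genus_pool[genus_phylum == phylum[i]]
      if (length(candidates) == 0L) candidates <- genus_pool
      sample(candidates, 1)
    }, character(1))
    genus[stats::runif(p) < config$frac_genus_unassigned] <- NA_character_
    lineages <- tibble::tibble(
      otu_id = otu_ids, kingdom = "Bacteria", phylum = phylum,
      class = NA_character_, order = NA_character_, family = NA_character_,
      genus = genus)

    # roles
    core_idx <- sort(sample.int(p, config$n_core))
    guild_members <- if (config$n_guilds > 0) {
      split(sample(seq_len(p), config$n_guilds * config$guild_size),
            rep(seq_len(config$n_guilds), each = config$guild_size))
    } else list()
    non_guild <- setdiff(seq_len(p), unlist(guild_members))
    resp_idx <- sort(sample(non_guild,
                            min(config$n_env_responders, length(non_guild))))
    resp_cov <- sample(config$env_responder_covariates, length(resp_idx),
                       replace = TRUE)
    resp_sign <- sample(c(-1, 1), length(resp_idx), replace = TRUE)

    # expected log abundance
    mu <- stats::rnorm(p, 0, config$base_sd)
    mu[core_idx] <- mu[core_idx] + config$core_mu_boost
    # an offset below 0 keeps guilds off the community's dominant mass, so
    # their shared factor does not move the total-sum denominator for
    # everyone else (compositional closure)
    mu[unlist(guild_members)] <- mu[unlist(guild_members)] +
      config$guild_mu_offset
    loglam <- matrix(mu, nrow = n, ncol = p, byrow = TRUE)

    ranges <- rep(config$spatial_range_km, p)
    if (!is.null(config$phylum_range_km)) {
      for (ph in names(config$phylum_range_km)) {
        ranges[phylum == ph] <- config$phylum_range_km[[ph]]
      }
    }
    for (rg in unique(ranges)) {
      cols <- which(ranges == rg)
      r_chol <- .spatial_chol(d_km, rg)
      z <- matrix(stats::rnorm(n * length(cols)), nrow = n)
      loglam[, cols] <- loglam[, cols] +
        config$spatial_sd * crossprod(r_chol, z)
    }

    for (g in seq_along(guild_members)) {
      f_g <- stats::rnorm(n)
      loglam[, guild_members[[g]]] <- loglam[, guild_members[[g]]] +
        config$guild_sd * f_g
    }

    for (j in seq_along(resp_idx)) {
      v <- as.numeric(scale(landscape[[resp_cov[j]]]))
      loglam[, resp_idx[j]] <- loglam[, resp_idx[j]] +
        config$env_effect * resp_sign[j] * v
    }

    loglam <- loglam + matrix(stats::rnorm(n * p, 0, config$noise_sd),
                              nrow = n)
    lambda <- exp(loglam)
    expected_profile <- lambda / rowSums(lambda)
    dimnames(expected_profile) <- list(landscape$sample_id, otu_ids)

    lib <- round(stats::rlnorm(n, config$library_meanlog,
                               config$library_sdlog))
    lib <- pmin(pmax(lib, config$library_range[1]), config$library_range[2])
    if (any(lib - config$n_core < 0)) {
      abort("library size smaller than the core floor requirement")
    }
    counts <- t(vapply(seq_len(n), function(s) {
      as.numeric(stats::rmultinom(1, lib[s] - config$n_core,
                                  expected_profile[s, ]))
    }, numeric(p)))
    counts[, core_idx] <- counts[, core_idx] + 1
    dimnames(counts) <- list(landscape$sample_id, otu_ids)

    tree <- ape::rcoal(p, tip.label = otu_ids)

    guild_edges <- purrr::imap_dfr(guild_members, function(members, g) {
      ids <- otu_ids[sort(members)]
      cmb <- utils::combn(ids, 2)
      tibble::tibble(guild = as.integer(g),
                     otu_1 = cmb[1, ], otu_2 = cmb[2, ])
    })

    sim <- 1 - as.matrix(vegan::vegdist(expected_profile, method = "bray"))
    planted_slope <- unname(stats::coef(
      stats::lm(sim[upper.tri(sim)] ~ d_km[upper.tri(d_km)]))[2])

    truth <- structure(list(
      core_otu_ids = otu_ids[core_idx],
      guilds = purrr::imap_dfr(guild_members, function(members, g) {
        tibble::tibble(guild = as.integer(g), otu_id = otu_ids[sort(members)])
      }),
      guild_edges = guild_edges,
      env_effects = tibble::tibble(
        otu_id = otu_ids[resp_idx], covariate = resp_cov,
        effect = config$env_effect * resp_sign),
      ddr_slope = planted_slope,
      expected_profile = expected_profile,
      seed = config$seed
    ), class = "synthetic_truth")

    list(table = otu_table(counts, lineages = lineages), tree = tree,
         truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d core OTUs, %d guild edges, %d env responders, planted DDR slope %.3g/km\n",
    length(x$core_otu_ids), nrow(x$guild_edges), nrow(x$env_effects),
    x$ddr_slope))
  invisible(x)
}

#' Generate landscape, community, tree and truth in one call
#'
#' @param config A [synthetic_config()].
#' @return A list: `metadata`, `table`, `tree`, `truth`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  landscape <- generate_landscape(config)
  comm <- generate_community(config, landscape)
  c(list(metadata = landscape), comm)
}
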