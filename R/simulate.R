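#' Configuration for the synthetic community generator
#'
#' Defaults emulate the depth-stratified arid-grassland survey the package
#' targets: 66 soil profiles (sites) sampled at three depth layers
#' (topsoil/middle/subsoil), a few thousand taxa, reads per sample at the
#' survey's rarefaction depth, a south-to-north precipitation gradient,
#' and nutrient stocks that decline with depth.
#'
#' @param n_taxa number of taxa in the regional pool.
#' @param n_sites number of soil profiles (each contributes one sample per
#'   layer).
#' @param n_layers depth layers (default 3: `"T"`, `"M"`, `"S"`).
#' @param reads_per_sample sequencing reads drawn per sample.
#' @param regime one of `"homogeneous_selection"`, `"variable_selection"`,
#'   `"dispersal_limitation"`, `"neutral_drift"`, `"mixed"`. `"mixed"`
#'   applies selection in the topsoil, weakened selection (doubled niche
#'   breadth) in the middle layer, and neutral drift in the subsoil.
#' @param selection_strength niche breadth sigma of the Gaussian
#'   environmental filter, in niche-trait units (tip trait sd is
#'   `sqrt(phylo_signal)`); smaller means stronger selection.
#' @param local_noise_sd standard deviation of the per-sample lognormal
#'   perturbation applied to selection weights: microscale habitat and
#'   sampling variability that gives samples realistic taxon turnover
#'   while leaving expected composition proportional to pool x kernel.
#' @param migration Sloan immigration probability m in (0, 1]. `NULL`
#'   defaults to 0.1, or 0.01 under `dispersal_limitation`.
#' @param phylo_signal Brownian-motion rate of niche evolution on the
#'   depth-1 tree.
#' @param spatial_extent north-south extent of the site grid, km.
#' @param seed integer master seed; fans out to per-component child seeds.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 2000, n_sites = 66, n_layers = 3,
                       reads_per_sample = 16611,
                       regime = c("mixed", "homogeneous_selection",
                                  "variable_selection", "dispersal_limitation",
                                  "neutral_drift"),
                       selection_strength = 0.3, local_noise_sd = 0.5,
                       migration = NULL,
                       phylo_signal = 1, spatial_extent = 400, seed = 1) {
  regime <- match.arg(regime)
  if (is.null(migration))
    migration <- if (regime == "dispersal_limitation") 0.01 else 0.1
  stopifnot(n_taxa >= 3, n_sites >= 2, n_layers >= 1, reads_per_sample >= 1,
            selection_strength > 0, local_noise_sd >= 0, migration > 0,
            migration <= 1, phylo_signal >= 0, spatial_extent > 0)
  structure(list(n_taxa = n_taxa, n_sites = n_sites, n_layers = n_layers,
                 reads_per_sample = reads_per_sample, regime = regime,
                 selection_strength = selection_strength,
                 local_noise_sd = local_noise_sd,
                 migration = migration, phylo_signal = phylo_signal,
                 spatial_extent = spatial_extent, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric Yule phylogeny scaled to unit depth
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @return a `phylo` with tip labels `t1..tn`, root-to-tip depth 1.
#' @export
simulate_tree <- function(n_taxa, seed) {
  stopifnot(n_taxa >= 3)
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Simulate phylogenetically conserved niche optima
#'
#' Brownian motion from a root value of 0 with rate `phylo_signal`; the
#' covariance of two tips' optima equals the rate times their shared
#' root-ward path length, which is what gives the phylogenetic null model
#' a real signal of niche conservatism to detect.
#'
#' @param tree a `phylo` with branch lengths.
#' @param phylo_signal BM rate (variance per unit branch length).
#' @param seed integer seed.
#' @return named numeric vector of optima, one per tip.
#' @export
simulate_niches <- function(tree, phylo_signal, seed) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (phylo_signal == 0) {
    out <- stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label)
    return(out)
  }
  with_seed(seed, ape::rTraitCont(tree, model = "BM",
                                  sigma = sqrt(phylo_signal), root.value = 0))
}

# Site coordinates on a south-north gradient with longitudinal jitter.
simulate_coordinates <- function(n_sites, spatial_extent, seed) {
  with_seed(seed, {
    lat0 <- 36.0
    lat <- lat0 + sort(stats::runif(n_sites)) * spatial_extent / 111.32
    lon <- 106.0 + stats::rnorm(n_sites, sd = 0.6)
    tibble(site = paste0("site", seq_len(n_sites)),
           latitude = lat, longitude = lon)
  })
}

# Depth multipliers for nutrient stocks: topsoil / middle / subsoil.
layer_nutrient_multiplier <- c(T = 1, M = 0.6, S = 0.35)

simulate_env_table <- function(coords, n_layers, seed) {
  layers <- c("T", "M", "S")[seq_len(n_layers)]
  with_seed(seed, {
    n <- nrow(coords)
    northness <- (coords$latitude - min(coords$latitude)) /
      max(diff(range(coords$latitude)), 1e-9)
    # Precipitation declines to the north in this steppe; temperature rises.
    map_site <- 430 - 260 * northness + stats::rnorm(n, sd = 15)
    mat_site <- 6.0 + 3.0 * northness + stats::rnorm(n, sd = 0.4)
    soc_site <- exp(log(12) + 0.8 * (map_site - mean(map_site)) / 100 +
                      stats::rnorm(n, sd = 0.25))
    grid <- tidyr::expand_grid(site = coords$site, layer = layers)
    grid <- dplyr::left_join(grid, coords, by = "site")
    mult <- layer_nutrient_multiplier[grid$layer]
    idx <- match(grid$site, coords$site)
    m <- nrow(grid)
    tibble(
      sample_id = paste0(grid$site, "_", grid$layer),
      site = grid$site, layer = grid$layer,
      latitude = grid$latitude, longitude = grid$longitude,
      SWC = pmax(2, 8 + 10 * (map_site[idx] - 170) / 260 *
                   ifelse(grid$layer == "T", 1.1, 0.9) +
                   stats::rnorm(m, sd = 1.2)),
      pH = pmin(9.6, pmax(7.6, 8.4 + 0.15 * (grid$layer != "T") +
                            stats::rnorm(m, sd = 0.15))),
      SOC = soc_site[idx] * mult * exp(stats::rnorm(m, sd = 0.15)),
      TN = soc_site[idx] / 10 * mult * exp(stats::rnorm(m, sd = 0.15)),
      TP = 0.6 * mult^0.7 * exp(stats::rnorm(m, sd = 0.12)),
      TC = soc_site[idx] * 1.6 * (1 - 0.3 * (grid$layer != "T")) *
        exp(stats::rnorm(m, sd = 0.1)),
      AN = soc_site[idx] * 4 * mult * exp(stats::rnorm(m, sd = 0.2)),
      AP = pmax(1, 6 * mult^0.5 + stats::rnorm(m, sd = 0.8)),
      AK = pmax(40, 160 * mult^0.4 + stats::rnorm(m, sd = 12)),
      BD = pmin(1.8, pmax(1.0, 1.25 + 0.12 * (grid$layer == "S") +
                            0.06 * (grid$layer == "M") +
                            stats::rnorm(m, sd = 0.05))),
      EC = pmax(50, 180 + 120 * northness[idx] + stats::rnorm(m, sd = 25)),
      MAT = mat_site[idx],
      MAP = map_site[idx]
    )
  })
}

# Sequential Polya-urn sampler for Sloan-style neutral drift. Each read is
# either an immigrant drawn from the metacommunity pool or a copy of a
# uniformly chosen earlier read of the same sample. The immigration
# probability declines as the urn fills, A / (A + reads so far) with prior
# mass A = N m: the final composition is then Dirichlet-multinomial with
# concentration N m, exactly the stationary distribution the Sloan
# occurrence-frequency model asserts, so the fitted migration rate
# estimates m. At m = 1 every read is an immigrant (iid multinomial).
draw_urn_sample <- function(n_reads, m, pool_prob, start_counts = NULL) {
  n0 <- 0L
  prefix <- integer(0)
  if (!is.null(start_counts) && sum(start_counts) > 0) {
    prefix <- rep.int(seq_along(start_counts), start_counts)
    n0 <- length(prefix)
  }
  if (m >= 1) {
    draw <- sample.int(length(pool_prob), n_reads, replace = TRUE,
                       prob = pool_prob)
    return(tabulate(draw, nbins = length(pool_prob)))
  }
  A <- n_reads * m
  flags <- stats::runif(n_reads) < A / (A + n0 + seq_len(n_reads) - 1)
  if (n0 == 0L) flags[1L] <- TRUE
  n_imm <- sum(flags)
  imm <- if (n_imm > 0)
    sample.int(length(pool_prob), n_imm, replace = TRUE, prob = pool_prob)
  else integer(0)
  anc <- floor(stats::runif(n_reads) * (n0 + seq_len(n_reads) - 1)) + 1L
  taxa <- c(prefix, integer(n_reads))
  j <- 0L
  for (t in seq_len(n_reads)) {
    k <- n0 + t
    if (flags[t]) {
      j <- j + 1L
      taxa[k] <- imm[j]
    } else {
      taxa[k] <- taxa[anc[t]]
    }
  }
  tabulate(taxa[(n0 + 1L):(n0 + n_reads)], nbins = length(pool_prob))
}

# Gaussian environmental filter on niche optima, with optional per-sample
# lognormal noise (microscale variability; mean composition unchanged).
selection_weights <- function(pool, optima, env_value, sigma,
                              local_noise_sd = 0) {
  w <- pool * exp(-(optima - env_value)^2 / (2 * sigma^2))
  if (local_noise_sd > 0)
    w <- w * exp(stats::rnorm(length(w), 0, local_noise_sd))
  if (sum(w) == 0) abort("Selection kernel annihilated the pool; widen sigma.")
  w / sum(w)
}

#' Simulate a full depth-stratified dataset under a named assembly regime
#'
#' Produces a community table (one sample per site x layer), the phylogeny,
#' an environment table, and a `sim_truth` list recording everything the
#' generator knew: the niche optima, per-sample filter environment, the
#' regime and niche breadth per layer, the metacommunity pool, and the true
#' immigration rate where drift regimes apply.
#'
#' Regimes: under selection, expected abundance is the pool weighted by a
#' Gaussian kernel `exp(-(optimum - E)^2 / (2 sigma^2))` and reads are a
#' multinomial draw; `homogeneous_selection` gives every sample the same
#' filter environment while `variable_selection` spreads environments across
#' the realized niche range (tracking the latitude/precipitation gradient).
#' Drift regimes draw reads through a sequential Polya urn with immigration
#' probability m; `dispersal_limitation` additionally seeds each urn with a
#' spatially autocorrelated starting composition so nearby sites resemble
#' each other.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `community`, `tree`, `env`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  layers <- c("T", "M", "S")[seq_len(cfg$n_layers)]
  tree <- simulate_tree(cfg$n_taxa, child_seed(cfg$seed, "tree"))
  optima <- simulate_niches(tree, cfg$phylo_signal,
                            child_seed(cfg$seed, "niches"))
  coords <- simulate_coordinates(cfg$n_sites, cfg$spatial_extent,
                                 child_seed(cfg$seed, "coords"))
  env <- simulate_env_table(coords, cfg$n_layers, child_seed(cfg$seed, "env"))

  pool <- with_seed(child_seed(cfg$seed, "pool"), {
    ab <- stats::rlnorm(cfg$n_taxa, meanlog = 0, sdlog = 1.5)
    ab / sum(ab)
  })

  layer_regime <- if (cfg$regime == "mixed") {
    stats::setNames(c("homogeneous_selection", "homogeneous_selection",
                      "neutral_drift")[seq_len(cfg$n_layers)], layers)
  } else stats::setNames(rep(cfg$regime, cfg$n_layers), layers)
  layer_sigma <- stats::setNames(rep(cfg$selection_strength, cfg$n_layers),
                                 layers)
  if (cfg$regime == "mixed" && cfg$n_layers >= 2)
    layer_sigma[2] <- 2 * cfg$selection_strength

  # Filter environments in niche-trait units: constant under homogeneous
  # selection, spread along the latitude gradient under variable selection.
  e_star <- mean(optima)
  northness <- rank(coords$latitude) / (cfg$n_sites + 1)
  e_var <- stats::quantile(optima, 0.05 + 0.9 * northness, names = FALSE)

  # Spatially autocorrelated local pools for dispersal limitation: one
  # exponential-covariance field per taxon across sites.
  local_pools <- NULL
  if (any(layer_regime == "dispersal_limitation")) {
    local_pools <- with_seed(child_seed(cfg$seed, "field"), {
      dkm <- geographic_distance_km(coords$latitude, coords$longitude)
      C <- exp(-dkm / (cfg$spatial_extent / 4))
      L <- t(chol(C + diag(1e-8, nrow(C))))
      Z <- matrix(stats::rnorm(cfg$n_sites * cfg$n_taxa), cfg$n_sites)
      G <- L %*% Z                     # sites x taxa, autocorrelated
      lp <- sweep(exp(1.5 * G), 2, pool, "*")
      sweep(lp, 1, rowSums(lp), "/")
    })
  }

  counts <- matrix(0L, nrow(env), cfg$n_taxa,
                   dimnames = list(env$sample_id, tree$tip.label))
  env_value <- stats::setNames(numeric(nrow(env)), env$sample_id)
  with_seed(child_seed(cfg$seed, "sampling"), {
    for (r in seq_len(nrow(env))) {
      site_i <- match(env$site[r], coords$site)
      lay <- env$layer[r]
      reg <- layer_regime[[lay]]
      if (reg %in% c("homogeneous_selection", "variable_selection")) {
        ev <- if (reg == "homogeneous_selection") e_star else e_var[site_i]
        w <- selection_weights(pool, optima, ev, layer_sigma[[lay]],
                               cfg$local_noise_sd)
        counts[r, ] <- stats::rmultinom(1, cfg$reads_per_sample, w)[, 1]
        env_value[r] <- ev
      } else if (reg == "neutral_drift") {
        counts[r, ] <- draw_urn_sample(cfg$reads_per_sample, cfg$migration,
                                       pool)
        env_value[r] <- NA_real_
      } else if (reg == "dispersal_limitation") {
        start <- stats::rmultinom(1, max(50, round(0.02 * cfg$reads_per_sample)),
                                  local_pools[site_i, ])[, 1]
        counts[r, ] <- draw_urn_sample(cfg$reads_per_sample, cfg$migration,
                                       pool, start_counts = start)
        env_value[r] <- NA_real_
      } else {
        abort(paste0("Unknown regime: ", reg))
      }
    }
  })

  taxonomy <- synthetic_taxonomy(tree, child_seed(cfg$seed, "taxonomy"))
  grass_types <- c("AM", "TG", "DG", "GD")
  meta <- tibble(
    sample_id = env$sample_id, site = env$site, layer = env$layer,
    type = grass_types[(match(env$site, coords$site) - 1L) %%
                         length(grass_types) + 1L]
  )
  community <- community_table(counts, meta, taxonomy)
  truth <- structure(list(
    tree = tree, optima = optima, env_value = env_value,
    coordinates = coords, layer_regime = layer_regime,
    layer_sigma = layer_sigma, migration = cfg$migration, pool = pool,
    config = cfg
  ), class = "sim_truth")
  list(community = community, tree = tree, env = env, truth = truth)
}

# Synthetic taxonomy: phyla are the deepest clades, genera shallow clades,
# so genus-level aggregation and the >1%-phylum filter are exercisable.
synthetic_taxonomy <- function(tree, seed, n_phyla = 8) {
  n <- length(tree$tip.label)
  d <- ape::cophenetic.phylo(tree)
  h <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- stats::cutree(h, k = min(n_phyla, n))
  n_gen <- max(2L, min(round(n / 6), n))
  gen <- stats::cutree(h, k = n_gen)
  tibble(taxon_id = tree$tip.label,
         phylum = paste0("Phylum", phy[tree$tip.label]),
         genus = paste0("Genus", gen[tree$tip.label]))
}
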