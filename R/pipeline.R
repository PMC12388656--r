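#' Assemble a pipeline run configuration
#'
#' Either `sim` (a [sim_config()]) or all three input paths must be given.
#' Every stage draws its seed from the master seed through a named child
#' stream, so reruns with the same configuration are bit-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional [sim_config()] for synthetic input.
#' @param counts_path,metadata_path,tree_path,env_path input files when not
#'   simulating (delimited tables + newick; env needs lat/lon).
#' @param taxonomy_path optional taxonomy table (needed for networks).
#' @param rarefy_depth rarefaction depth; `NULL` uses the minimum sample
#'   total.
#' @param n_null nulls for betaNTI / RC-bray.
#' @param n_perm permutations for ANOSIM/PERMANOVA/decay/MRM.
#' @param rho_min,p_max_taxa,p_max_env network thresholds.
#' @param top_n_genera genus cap for networks.
#' @param stages character vector choosing stages; default all.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, sim = NULL, counts_path = NULL,
                       metadata_path = NULL, tree_path = NULL,
                       env_path = NULL, taxonomy_path = NULL,
                       rarefy_depth = NULL, n_null = 999, n_perm = 999,
                       rho_min = 0.8, p_max_taxa = 0.05, p_max_env = 0.01,
                       top_n_genera = 200,
                       stages = c("diversity", "assembly", "ncm", "network",
                                  "decay", "attribution"),
                       seed = 1) {
  if (is.null(sim) &&
      (is.null(counts_path) || is.null(metadata_path) ||
       is.null(env_path)))
    abort("Provide either `sim` or counts/metadata/env paths.")
  if (is.null(sim) && is.null(tree_path) && "assembly" %in% stages)
    abort("The assembly stage needs a tree.")
  structure(list(out_dir = out_dir, sim = sim, counts_path = counts_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 env_path = env_path, taxonomy_path = taxonomy_path,
                 rarefy_depth = rarefy_depth, n_null = n_null,
                 n_perm = n_perm, rho_min = rho_min,
                 p_max_taxa = p_max_taxa, p_max_env = p_max_env,
                 top_n_genera = top_n_genera, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

write_matrix_out <- function(m, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(data.frame(sample_id = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE)
  path
}

#' Run the full depth-stratified analysis pipeline
#'
#' Stages, in dependency order: input (simulate or load), rarefaction,
#' alpha/beta diversity + NMDS + ANOSIM/PERMANOVA by layer, null-model
#' assembly inference per layer x type group, neutral-model fits per
#' layer, genus networks per layer (co-occurrence + taxon-environment),
#' distance-decay per layer (geographic and environmental predictors),
#' and attribution (MRM + PLS-PM on betaNTI pairs). Outputs are CSV/JSON
#' under `cfg$out_dir`, and a `manifest.json` records package version,
#' seeds, parameters and an input digest. A failing stage is recorded in
#' the manifest and subsequent dependent stages are skipped; completed
#' outputs are kept.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "assemblyscape",
    version = as.character(utils::packageVersion("assemblyscape")),
    seed = cfg$seed,
    parameters = cfg[c("rarefy_depth", "n_null", "n_perm", "rho_min",
                       "p_max_taxa", "p_max_env", "top_n_genera")],
    stages = list()
  )
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
  }
  ok <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(status = "ok", outputs = outputs)
  }

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- simulate_dataset(cfg$sim)
    ct <- sim$community
    tree <- sim$tree
    env <- sim$env
    manifest$input <- list(kind = "simulated",
                           sim_seed = cfg$sim$seed,
                           regime = cfg$sim$regime,
                           n_taxa = cfg$sim$n_taxa,
                           n_sites = cfg$sim$n_sites)
  } else {
    ct <- read_community(cfg$counts_path, cfg$metadata_path,
                         cfg$taxonomy_path)
    tree <- if (!is.null(cfg$tree_path)) read_tree(cfg$tree_path)
    env <- as_tibble(utils::read.csv(cfg$env_path))
    manifest$input <- list(
      kind = "files",
      digest = vapply(c(cfg$counts_path, cfg$metadata_path, cfg$env_path),
                      function(p) as.character(file.size(p)), character(1)))
  }
  depth <- cfg$rarefy_depth %||% min(rowSums(ct$counts))
  ct <- rarefy(ct, depth, child_seed(cfg$seed, "rarefy"))
  manifest$rarefaction <- list(depth = depth,
                               n_zero_taxa_after = length(
                                 drop_zero_taxa(ct)$zero_taxa))
  write_community(ct, file.path(cfg$out_dir, "counts_rarefied.csv"),
                  file.path(cfg$out_dir, "metadata.csv"))
  md <- ct$metadata
  layers <- unique(md$layer)

  bc <- NULL
  if ("diversity" %in% cfg$stages) {
    tryCatch({
      alpha <- alpha_diversity(ct, tree)
      bc <- beta_matrix(ct, "bray_curtis")
      outs <- c(write_csv_out(alpha, cfg$out_dir, "alpha_diversity.csv"),
                write_matrix_out(bc, cfg$out_dir, "bray_curtis.csv"))
      if (!is.null(tree)) {
        wu <- beta_matrix(ct, "weighted_unifrac", tree)
        outs <- c(outs, write_matrix_out(wu, cfg$out_dir,
                                         "weighted_unifrac.csv"))
      }
      if (nrow(bc) > 3) {
        nm <- nmds(bc, seed = child_seed(cfg$seed, "nmds"))
        outs <- c(outs,
                  write_csv_out(dplyr::mutate(nm$points,
                                              stress = nm$stress),
                                cfg$out_dir, "nmds.csv"))
        tests <- dplyr::bind_rows(
          dplyr::mutate(anosim(bc, md$layer,
                               n_perm = cfg$n_perm,
                               seed = child_seed(cfg$seed, "anosim")),
                        test = "anosim", grouping = "layer"),
          dplyr::mutate(permanova(bc, md$layer,
                                  n_perm = cfg$n_perm,
                                  seed = child_seed(cfg$seed, "adonis")),
                        test = "permanova", grouping = "layer"))
        outs <- c(outs, write_csv_out(tests, cfg$out_dir,
                                      "beta_group_tests.csv"))
      }
      ok("diversity", outs)
    }, error = function(e) fail("diversity", e))
  }

  assembly <- NULL
  if ("assembly" %in% cfg$stages) {
    tryCatch({
      if (is.null(tree)) abort("Assembly stage needs a tree.")
      assembly <- assembly_analysis(ct, tree, n_null = cfg$n_null,
                                    seed = child_seed(cfg$seed, "assembly"))
      ok("assembly",
         c(write_csv_out(assembly$pairs, cfg$out_dir,
                         "assembly_pairs.csv"),
           write_csv_out(assembly$fractions, cfg$out_dir,
                         "assembly_fractions.csv")))
    }, error = function(e) fail("assembly", e))
  }

  if ("ncm" %in% cfg$stages) {
    tryCatch({
      fits <- lapply(layers, function(l) {
        sub <- subset_samples(ct, md$sample_id[md$layer == l])
        dplyr::mutate(glance(fit_ncm(sub)), layer = l)
      })
      ok("ncm", write_csv_out(dplyr::bind_rows(fits), cfg$out_dir,
                              "ncm_fits.csv"))
    }, error = function(e) fail("ncm", e))
  }

  genus_ct <- NULL
  if ("network" %in% cfg$stages) {
    tryCatch({
      genus_ct <- select_taxa(ct, top_n = cfg$top_n_genera)
      topo <- lapply(layers, function(l) {
        sub <- subset_samples(genus_ct, md$sample_id[md$layer == l])
        net <- correlation_network(sub, rho_min = cfg$rho_min,
                                   p_max = cfg$p_max_taxa)
        write_network(net,
                      file.path(cfg$out_dir,
                                paste0("network_", l, ".graphml")),
                      file.path(cfg$out_dir,
                                paste0("network_edges_", l, ".csv")))
        envnet <- taxon_env_network(sub, env, rho_min = cfg$rho_min,
                                    p_max = cfg$p_max_env)
        write_network(envnet, NULL,
                      file.path(cfg$out_dir,
                                paste0("taxon_env_edges_", l, ".csv")))
        dplyr::mutate(topology(net), layer = l)
      })
      ok("network", write_csv_out(dplyr::bind_rows(topo), cfg$out_dir,
                                  "network_topology.csv"))
    }, error = function(e) fail("network", e))
  }

  if ("decay" %in% cfg$stages) {
    tryCatch({
      if (is.null(bc)) bc <- beta_matrix(ct, "bray_curtis")
      geo <- geographic_distance(env)
      ed <- environmental_distance(env)
      fits <- list()
      for (l in layers) {
        ids <- md$sample_id[md$layer == l]
        for (kind in c("geographic_km", "environmental_euclidean")) {
          pred <- if (kind == "geographic_km") geo else ed
          f <- fit_decay(bc[ids, ids], pred[ids, ids],
                         n_perm = cfg$n_perm,
                         seed = child_seed(cfg$seed,
                                           paste0("decay.", l, kind)))
          fits[[paste(l, kind)]] <-
            dplyr::mutate(glance(f), layer = l, predictor = kind)
        }
      }
      ok("decay", write_csv_out(dplyr::bind_rows(fits), cfg$out_dir,
                                "distance_decay.csv"))
    }, error = function(e) fail("decay", e))
  }

  if ("attribution" %in% cfg$stages) {
    tryCatch({
      if (is.null(assembly)) abort("Attribution needs the assembly stage.")
      if (is.null(genus_ct)) genus_ct <- select_taxa(ct, top_n =
                                                       cfg$top_n_genera)
      geo <- geographic_distance(env)
      ed <- environmental_distance(env)
      bio <- biotic_distance(genus_ct)
      out_rows <- list()
      pls_rows <- list()
      for (l in layers) {
        ids <- md$sample_id[md$layer == l]
        pr <- assembly$pairs[assembly$pairs$sample_1 %in% ids &
                               assembly$pairs$sample_2 %in% ids, ]
        if (nrow(pr) < 10) next
        # Cross-type pairs within the layer were not computed; they stay NA
        # and are dropped by mrm / the PLS-PM pair table.
        resp <- matrix(NA_real_, length(ids), length(ids),
                       dimnames = list(ids, ids))
        diag(resp) <- 0
        for (r in seq_len(nrow(pr)))
          resp[pr$sample_1[r], pr$sample_2[r]] <-
            resp[pr$sample_2[r], pr$sample_1[r]] <- pr$betanti[r]
        fitm <- mrm(as_dist_matrix(resp, nonnegative = FALSE),
                    list(environment = ed[ids, ids],
                         space = geo[ids, ids],
                         biotic = bio[ids, ids]),
                    n_perm = cfg$n_perm,
                    seed = child_seed(cfg$seed, paste0("mrm.", l)))
        out_rows[[l]] <- dplyr::mutate(tidy(fitm), layer = l,
                                       r_squared = fitm$r_squared)
        pair_df <- tibble(
          betanti = lower_vec(resp),
          environment = lower_vec(ed[ids, ids]),
          space = lower_vec(geo[ids, ids]),
          biotic = lower_vec(bio[ids, ids])
        )
        pair_df <- pair_df[is.finite(pair_df$betanti), ]
        inner <- matrix(0, 4, 4)
        inner[1, 3] <- inner[2, 3] <- 1      # env, space -> biotic
        inner[1, 4] <- inner[2, 4] <- inner[3, 4] <- 1  # ... -> betanti
        pfit <- tryCatch(
          pls_pm(pair_df,
                 blocks = list(environment = "environment",
                               space = "space", biotic = "biotic",
                               betanti = "betanti"),
                 inner = inner, n_boot = min(cfg$n_perm, 199),
                 seed = child_seed(cfg$seed, paste0("pls.", l))),
          error = function(e) NULL)
        if (!is.null(pfit))
          pls_rows[[l]] <- dplyr::mutate(tidy(pfit), layer = l,
                                         gof = pfit$gof)
      }
      ok("attribution",
         c(write_csv_out(dplyr::bind_rows(out_rows), cfg$out_dir,
                         "mrm_results.csv"),
           if (length(pls_rows))
             write_csv_out(dplyr::bind_rows(pls_rows), cfg$out_dir,
                           "plspm_paths.csv")))
    }, error = function(e) fail("attribution", e))
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  failed <- vapply(manifest$stages, function(s)
    identical(s$status, "failed"), logical(1))
  if (any(failed))
    warn(paste0("Failed stages: ",
                paste(names(manifest$stages)[failed], collapse = ", ")))
  invisible(manifest)
}
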