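#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For a sample pair (k, l):
#' `betaMNTD = 1/2 [ sum_{i in k} f_ik min_{j in l} d(i, j)
#'                 + sum_{j in l} f_jl min_{i in k} d(j, i) ]`
#' with `f` relative abundances (or uniform weights over present taxa when
#' `weighted = FALSE`) and `d` the patristic distance on the tree. Shared
#' taxa have a nearest neighbor at distance zero, so identical communities
#' score 0. All-zero taxa are dropped before computation.
#'
#' @param ct a [community_table()].
#' @param tree `phylo` whose tips cover the present taxa.
#' @param weighted abundance-weight the taxon contributions (default TRUE).
#' @return a [as_dist_matrix()] of samples, in branch-length units.
#' @export
beta_mntd <- function(ct, tree, weighted = TRUE) {
  ct <- drop_zero_taxa(ct)
  if (any(rowSums(ct$counts) == 0)) abort("Empty community in table.")
  prune_check(tree, ct)
  D <- patristic_matrix(tree, colnames(ct$counts))
  Fw <- mntd_weights(ct, weighted)
  b <- beta_mntd_engine(Fw, ct$counts > 0, D)
  as_dist_matrix(b)
}

mntd_weights <- function(ct, weighted) {
  if (weighted) relative_abundance(ct)
  else {
    pres <- (ct$counts > 0) * 1
    sweep(pres, 1, rowSums(pres), "/")
  }
}

# Fw: samples x taxa weights; pres: samples x taxa logical; D: taxa x taxa.
# Returns the full betaMNTD matrix via M[i, l] = min_{j in l} D[i, j].
beta_mntd_engine <- function(Fw, pres, D) {
  S <- nrow(Fw)
  M <- matrix(0, ncol(Fw), S)
  for (l in seq_len(S)) {
    cols <- which(pres[l, ])
    M[, l] <- if (length(cols) == 1L) D[, cols]
    else do.call(pmin, lapply(cols, function(j) D[, j]))
  }
  Tm <- Fw %*% M
  out <- (Tm + t(Tm)) / 2
  dimnames(out) <- list(rownames(Fw), rownames(Fw))
  diag(out) <- 0
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a null that shuffles taxon
#' labels across the tree tips, preserving the tree shape and the abundance
#' matrix: `betaNTI = (obs - mean_null) / sd_null` per sample pair. The
#' same shuffle is applied to all pairs within an iteration. Values below
#' -2 indicate homogeneous selection, above +2 variable selection.
#'
#' The shuffle universe is the table's full taxon roster (all columns that
#' are tree tips), not just the taxa observed in the supplied samples:
#' when selection is homogeneous, every sample draws from the same clade
#' and a null restricted to the observed union would see no clustering at
#' all. Supplying the regional roster in the table (zero-count columns
#' retained) is therefore what gives the index its meaning.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `betanti`, `betamntd_obs`, `null_mean`, `null_sd`
#'   distance matrices (betanti is signed; degenerate pairs are `NaN` with
#'   a warning).
#' @export
beta_nti <- function(ct, tree, n_null = 999, seed = 1, weighted = TRUE) {
  if (n_null < 99) abort("n_null must be at least 99.")
  missing <- setdiff(colnames(ct$counts), tree$tip.label)
  if (length(missing))
    abort(paste0("Taxa absent from the tree: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  taxa <- colnames(ct$counts)
  D <- patristic_matrix(tree, taxa)
  Fw <- mntd_weights(ct, weighted)
  pres <- ct$counts > 0
  obs <- beta_mntd_engine(Fw, pres, D)
  nt <- length(taxa)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(r) sample.int(nt), integer(nt)))
  })
  acc <- .bmntd_null_cpp(Fw, pres, D, perms)
  s1 <- acc$sum
  s2 <- acc$sumsq
  dimnames(s1) <- dimnames(s2) <- dimnames(obs)
  mu <- s1 / n_null
  sd <- sqrt(pmax((s2 - n_null * mu^2) / (n_null - 1), 0))
  z <- (obs - mu) / sd
  z[sd == 0] <- NaN
  diag(z) <- 0
  if (any(is.nan(z[lower.tri(z)])))
    warn(sprintf("betaNTI undefined (null sd = 0) for %d pairs; set to NaN.",
                 sum(is.nan(z[lower.tri(z)]))))
  dimnames(z) <- dimnames(obs)
  list(betanti = as_dist_matrix(z, nonnegative = FALSE),
       betamntd_obs = as_dist_matrix(obs),
       null_mean = as_dist_matrix(mu - diag(diag(mu))),
       null_sd = structure(sd, dimnames = dimnames(obs)))
}

#' Bray-Curtis-based Raup-Crick metric (RC-bray)
#'
#' Each null community fixes the sample's observed richness and read total:
#' taxa are drawn without replacement with probability proportional to
#' regional occupancy (fraction of samples containing the taxon); one read
#' is assigned to each drawn taxon and the remainder are allocated with
#' probability proportional to regional relative abundance. The observed
#' Bray-Curtis of a pair is ranked within its null distribution (ties take
#' half weight) and rescaled to `[-1, 1]`:
#' `RC = 2 ((#null < obs) + 0.5 (#null = obs)) / n_null - 1`.
#'
#' @param ct a [community_table()] of integer counts.
#' @param n_null null draws per pair (default 999).
#' @param seed integer seed.
#' @param block nulls are generated in blocks of this size to bound memory.
#' @return a signed [as_dist_matrix()] with entries in `[-1, 1]`.
#' @export
rc_bray <- function(ct, n_null = 999, seed = 1, block = 100) {
  ct <- drop_zero_taxa(ct)
  cnt <- ct$counts
  if (any(cnt != round(cnt))) abort("RC-bray needs integer counts.")
  S <- nrow(cnt)
  if (S < 2) abort("Need at least 2 samples.")
  pool <- ncol(cnt)
  occupancy <- colSums(cnt > 0) / S
  reg_ab <- colSums(cnt) / sum(cnt)
  rich <- rowSums(cnt > 0)
  tot <- rowSums(cnt)
  if (any(rich > pool))
    abort("Sample richness exceeds the regional pool.")
  obs <- matrix(0, S, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S)
    obs[i, j] <- obs[j, i] <-
      sum(abs(cnt[i, ] - cnt[j, ])) / sum(cnt[i, ] + cnt[j, ])
  less <- matrix(0, S, S)
  ties <- matrix(0, S, S)
  draw_null_block <- function(k, nb) {
    out <- matrix(0, pool, nb)
    for (r in seq_len(nb)) {
      # weighted draw without replacement via the exponential race
      taxa_r <- order(stats::rexp(pool) / occupancy)[seq_len(rich[k])]
      x <- numeric(pool)
      x[taxa_r] <- 1
      extra <- tot[k] - rich[k]
      if (extra > 0) {
        p <- reg_ab[taxa_r]
        if (sum(p) == 0) p <- rep(1, length(taxa_r))
        add <- stats::rmultinom(1, extra, p)[, 1]
        x[taxa_r] <- x[taxa_r] + add
      }
      out[, r] <- x
    }
    out
  }
  with_seed(seed, {
    done <- 0
    while (done < n_null) {
      nb <- min(block, n_null - done)
      nulls <- lapply(seq_len(S), draw_null_block, nb = nb)
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        num <- colSums(abs(nulls[[i]] - nulls[[j]]))
        bc <- num / (tot[i] + tot[j])
        less[i, j] <- less[i, j] + sum(bc < obs[i, j] - 1e-12)
        ties[i, j] <- ties[i, j] + sum(abs(bc - obs[i, j]) <= 1e-12)
      }
      done <- done + nb
    }
  })
  rc <- matrix(0, S, S)
  ut <- upper.tri(rc)
  rc[ut] <- 2 * ((less[ut] + ties[ut] / 2) / n_null) - 1
  rc <- rc + t(rc)
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(cnt), rownames(cnt))
  as_dist_matrix(rc, nonnegative = FALSE)
}

process_levels <- c("homogeneous_selection", "variable_selection",
                    "homogeneous_dispersal", "dispersal_limitation", "drift")

classify_pair <- function(bnti, rc) {
  dplyr::case_when(
    is.nan(bnti) ~ NA_character_,
    bnti < -2 ~ "homogeneous_selection",
    bnti > 2 ~ "variable_selection",
    rc < -0.95 ~ "homogeneous_dispersal",
    rc > 0.95 ~ "dispersal_limitation",
    TRUE ~ "drift"
  )
}

#' Classify assembly processes from betaNTI and RC-bray
#'
#' Applies the five-way threshold scheme: betaNTI < -2 homogeneous
#' selection; betaNTI > 2 variable selection; otherwise RC-bray < -0.95
#' homogeneous dispersal, RC-bray > 0.95 dispersal limitation, and
#' |RC-bray| <= 0.95 drift (boundary values fall to the stochastic side,
#' matching the strict inequalities of the framework). Pairs with undefined
#' betaNTI are excluded from fractions and counted.
#'
#' @param betanti signed distance matrix of betaNTI values.
#' @param rc signed distance matrix of RC-bray values.
#' @param metadata optional per-sample tibble (needs `sample_id`) used to
#'   restrict fraction summaries to within-group pairs.
#' @param group_by metadata columns defining groups (default layer, type).
#' @return an `assembly_result`: list with `pairs` (tibble of per-pair
#'   metrics and process), `fractions` (per-group process fractions over
#'   within-group pairs; one group `all` when no metadata), `n_undefined`.
#' @export
classify_processes <- function(betanti, rc, metadata = NULL,
                               group_by = c("layer", "type")) {
  check_matching_labels(betanti, rc, "betaNTI and RC matrices")
  pairs <- dm_pairs(betanti, "betanti")
  pairs$rc_bray <- dm_pairs(rc, "rc")$rc
  pairs$process <- classify_pair(pairs$betanti, pairs$rc_bray)
  n_und <- sum(is.na(pairs$process))
  if (n_und > 0)
    inform(sprintf("%d pairs with undefined betaNTI excluded from fractions.",
                   n_und))
  if (!is.null(metadata)) {
    md <- metadata[, c("sample_id", group_by)]
    g1 <- md[match(pairs$sample_1, md$sample_id), group_by, drop = FALSE]
    g2 <- md[match(pairs$sample_2, md$sample_id), group_by, drop = FALSE]
    pairs$group <- ifelse(
      rowSums(as.matrix(g1) != as.matrix(g2)) == 0,
      apply(as.matrix(g1), 1, paste, collapse = "."),
      NA_character_
    )
  } else {
    pairs$group <- "all"
  }
  frac <- pairs |>
    dplyr::filter(!is.na(.data$group), !is.na(.data$process)) |>
    dplyr::count(.data$group, process = factor(.data$process,
                                               levels = process_levels),
                 .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(pairs = pairs, fractions = frac, n_undefined = n_und),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> %d pairs (%d undefined betaNTI)\n",
              nrow(x$pairs), x$n_undefined))
  print(tidyr::pivot_wider(x$fractions[, c("group", "process", "fraction")],
                           names_from = "process", values_from = "fraction"))
  invisible(x)
}

#' @export
tidy.assembly_result <- function(x, ...) x$pairs

#' @export
glance.assembly_result <- function(x, ...) {
  tidyr::pivot_wider(x$fractions[, c("group", "process", "fraction")],
                     names_from = "process", values_from = "fraction")
}

#' Full null-model assembly analysis, grouped the way the study reports it
#'
#' Runs betaNTI and RC-bray within each depth-layer x grassland-type group
#' (or on all samples at once with `within_groups = FALSE`) and classifies
#' every within-group pair.
#'
#' @param ct a [community_table()] (metadata must carry the grouping cols).
#' @param tree `phylo` covering the taxa.
#' @param n_null nulls for both betaNTI and RC-bray.
#' @param seed integer seed.
#' @param group_by metadata columns (default `c("layer", "type")`).
#' @param within_groups compute nulls inside each group (default TRUE).
#' @return an `assembly_result` (pairs carry the group id).
#' @export
assembly_analysis <- function(ct, tree, n_null = 999, seed = 1,
                              group_by = c("layer", "type"),
                              within_groups = TRUE) {
  md <- ct$metadata
  if (!within_groups || is.null(md) ||
      !all(group_by %in% names(md))) {
    bn <- beta_nti(ct, tree, n_null = n_null, seed = seed)
    rc <- rc_bray(ct, n_null = n_null, seed = seed + 1)
    return(classify_processes(bn$betanti, rc,
                              metadata = if (all(group_by %in% names(md)))
                                md else NULL,
                              group_by = group_by))
  }
  grp <- apply(as.matrix(md[, group_by, drop = FALSE]), 1, paste,
               collapse = ".")
  results <- list()
  for (gv in unique(grp)) {
    ids <- md$sample_id[grp == gv]
    if (length(ids) < 3) next
    sub <- subset_samples(ct, ids)
    bn <- beta_nti(sub, tree, n_null = n_null,
                   seed = child_seed(seed, paste0("bnti.", gv)))
    rc <- rc_bray(sub, n_null = n_null,
                  seed = child_seed(seed, paste0("rc.", gv)))
    results[[gv]] <- classify_processes(bn$betanti, rc, metadata = md,
                                        group_by = group_by)
  }
  pairs <- dplyr::bind_rows(lapply(results, function(r) r$pairs))
  frac <- pairs |>
    dplyr::filter(!is.na(.data$group), !is.na(.data$process)) |>
    dplyr::count(.data$group, process = factor(.data$process,
                                               levels = process_levels),
                 .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(pairs = pairs, fractions = frac,
                 n_undefined = sum(is.na(pairs$process))),
            class = "assembly_result")
}
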