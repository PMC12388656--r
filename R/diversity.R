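#' Alpha diversity per sample
#'
#' Computes observed richness, bias-corrected Chao1, Shannon entropy (in
#' nats), Pielou evenness, Good's coverage and (when a tree is supplied)
#' Faith's phylogenetic diversity. Chao1 uses the bias-corrected form
#' `S + F1(F1 - 1) / (2 (F2 + 1))` so it is defined when no doubletons
#' occur. Faith's PD is the total branch length of the subtree spanning the
#' present taxa and the root.
#'
#' @param ct a [community_table()] of integer counts.
#' @param tree optional `phylo` covering the taxa; adds `faith_pd`.
#' @return a tibble with one row per sample.
#' @export
alpha_diversity <- function(ct, tree = NULL) {
  cnt <- ct$counts
  if (any(rowSums(cnt) == 0))
    abort(paste0("Samples with zero total count: ",
                 paste(rownames(cnt)[rowSums(cnt) == 0], collapse = ", ")))
  if (any(cnt != round(cnt)))
    abort("Chao1 and coverage need integer counts.")
  n <- rowSums(cnt)
  sobs <- rowSums(cnt > 0)
  f1 <- rowSums(cnt == 1)
  f2 <- rowSums(cnt == 2)
  chao1 <- sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- apply(cnt, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  pielou <- ifelse(sobs > 1, shannon / log(sobs), NA_real_)
  goods <- 1 - f1 / n
  out <- tibble(
    sample_id = rownames(cnt),
    sobs = as.integer(sobs), chao1 = unname(chao1),
    shannon = unname(shannon), pielou = unname(pielou),
    goods_coverage = unname(goods)
  )
  if (!is.null(tree)) {
    tree <- prune_check(tree, ct)
    out$faith_pd <- unname(faith_pd(cnt, tree))
  }
  out
}

prune_check <- function(tree, ct) {
  present <- colnames(ct$counts)[colSums(ct$counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    abort(paste0("Taxa absent from the tree: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  tree
}

# Total branch length of the subtree spanning present tips and the root.
faith_pd <- function(cnt, tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  tip_idx <- match(colnames(cnt), tr$tip.label)
  apply(cnt, 1, function(x) {
    present <- rep(FALSE, ntip + tr$Nnode)
    present[tip_idx[x > 0]] <- TRUE
    pd <- 0
    for (e in seq_len(nrow(tr$edge))) {
      child <- tr$edge[e, 2]
      if (present[child]) {
        pd <- pd + tr$edge.length[e]
        present[tr$edge[e, 1]] <- TRUE
      }
    }
    pd
  })
}

#' Pairwise beta-diversity matrix
#'
#' Bray-Curtis on counts, `sum|x - y| / sum(x + y)`, or normalized weighted
#' UniFrac, `sum_b l_b |A_b - B_b| / sum_b l_b (A_b + B_b)` with `A_b` the
#' relative abundance descending branch `b`; both lie in `[0, 1]`.
#'
#' @param ct a [community_table()].
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree required for weighted UniFrac.
#' @return a [as_dist_matrix()] of samples.
#' @export
beta_matrix <- function(ct, metric = c("bray_curtis", "weighted_unifrac"),
                        tree = NULL) {
  metric <- match.arg(metric)
  if (n_samples(ct) < 2) abort("Need at least 2 samples.")
  if (metric == "bray_curtis") {
    cnt <- ct$counts
    n <- nrow(cnt)
    d <- matrix(0, n, n, dimnames = list(rownames(cnt), rownames(cnt)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(cnt[i, ] - cnt[j, ])) / sum(cnt[i, ] + cnt[j, ])
    }
    return(as_dist_matrix(d))
  }
  if (is.null(tree)) abort("Weighted UniFrac needs a tree.")
  prune_check(tree, ct)
  P <- relative_abundance(ct)
  ba <- branch_abundance(P, tree)
  len <- ba$lengths
  A <- ba$abund                       # samples x edges
  n <- nrow(A)
  d <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(len * abs(A[i, ] - A[j, ]))
    den <- sum(len * (A[i, ] + A[j, ]))
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  as_dist_matrix(d)
}

# Relative abundance descending each branch, all samples at once.
branch_abundance <- function(P, tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nodes <- matrix(0, nrow(P), ntip + tr$Nnode)
  idx <- match(tr$tip.label, colnames(P))
  has <- !is.na(idx)
  nodes[, which(has)] <- P[, idx[has], drop = FALSE]
  for (e in seq_len(nrow(tr$edge)))
    nodes[, tr$edge[e, 1]] <- nodes[, tr$edge[e, 1]] + nodes[, tr$edge[e, 2]]
  list(abund = nodes[, tr$edge[, 2], drop = FALSE], lengths = tr$edge.length)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS (monotone regression, best of `n_starts` random
#' starts) via [vegan::metaMDS()].
#'
#' @param dm a distance matrix from [beta_matrix()].
#' @param k target dimension (default 2).
#' @param n_starts random starts.
#' @param seed integer seed; fixing it makes the embedding reproducible.
#' @return list with `points` (tibble: sample_id, NMDS1..NMDSk) and `stress`.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, seed = 1) {
  if (k >= nrow(dm)) abort("k must be smaller than the number of samples.")
  fit <- with_seed(seed,
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE))
  pts <- as_tibble(fit$points, rownames = "sample_id")
  names(pts)[-1] <- paste0("NMDS", seq_len(k))
  list(points = pts, stress = fit$stress)
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2`; significance by permuting group labels. Groups with a
#' single member contribute no within-group pairs (warned). When every
#' off-diagonal distance is tied the statistic is undefined and 0 is
#' returned with a warning.
#'
#' @param dm distance matrix over samples.
#' @param groups factor-like vector aligned with the matrix labels.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return tibble with columns `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = 1) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  if (length(unique(groups)) < 2) abort("Need at least 2 groups.")
  if (any(table(groups) == 1))
    warn("Groups with a single member contribute no within-group pairs.")
  lt <- lower.tri(dm)
  dvec <- dm[lt]
  if (length(unique(dvec)) == 1) {
    warn("All pairwise distances tied; ANOSIM R undefined, returning 0.")
    return(tibble(statistic = 0, p_value = 1, n_perm = n_perm))
  }
  ranks <- rank(dvec)
  M <- length(dvec)
  same <- outer(groups, groups, "==")[lt]
  stat_fun <- function(same) {
    if (!any(same) || all(same)) return(NA_real_)
    (mean(ranks[!same]) - mean(ranks[same])) / (M / 2)
  }
  r_obs <- stat_fun(same)
  r_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    stat_fun(outer(g, g, "==")[lt])
  }, numeric(1)))
  p <- (1 + sum(r_null >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  tibble(statistic = r_obs, p_value = p, n_perm = n_perm)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions squared distances: `SS_total = sum(d^2) / n` over all pairs,
#' `SS_within` from within-group pairs (each group divided by its size),
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`,
#' `R^2 = SS_between / SS_total`; p by label permutation.
#'
#' @inheritParams anosim
#' @return tibble with `pseudo_f`, `r_squared`, `p_value`, `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  g <- length(unique(groups))
  if (g < 2) abort("Need at least 2 groups.")
  n <- nrow(dm)
  d2 <- dm^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within_fun <- function(grp) {
    s <- 0
    for (lev in unique(grp)) {
      idx <- which(grp == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_stat <- function(grp) {
    ssw <- ss_within_fun(grp)
    ssb <- ss_total - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(groups)
  ssw <- ss_within_fun(groups)
  r2 <- (ss_total - ssw) / ss_total
  f_null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(sample(groups)), numeric(1)))
  p <- (1 + sum(f_null >= f_obs)) / (n_perm + 1)
  tibble(pseudo_f = f_obs, r_squared = r2, p_value = p, n_perm = n_perm)
}
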