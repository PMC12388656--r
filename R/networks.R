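env_variables <- c("SWC", "pH", "SOC", "TN", "TP", "TC", "AN", "AP", "AK",
                   "BD", "EC", "MAT", "MAP")

#' Aggregate to genus level and apply the abundance filters
#'
#' Counts are summed to genus; genera are restricted to phyla whose mean
#' relative abundance across samples exceeds `phylum_min`, then capped at
#' the `top_n` most abundant genera by summed counts (ties at the cap
#' broken lexicographically, logged).
#'
#' @param ct a [community_table()] with taxonomy to genus rank.
#' @param phylum_min phylum mean-relative-abundance threshold (default 1%).
#' @param top_n genus cap (default 200).
#' @return a genus-level `community_table`.
#' @export
select_taxa <- function(ct, phylum_min = 0.01, top_n = 200) {
  if (is.null(ct$taxonomy) ||
      !all(c("phylum", "genus") %in% names(ct$taxonomy)))
    abort("Taxonomy with phylum and genus ranks is required.")
  rel <- relative_abundance(ct)
  tax <- ct$taxonomy
  phy_mean <- tapply(colMeans(rel), tax$phylum, sum)
  keep_phyla <- names(phy_mean)[phy_mean > phylum_min]
  keep_taxa <- tax$taxon_id[tax$phylum %in% keep_phyla]
  if (length(keep_taxa) == 0) abort("No phyla pass the abundance filter.")
  sub <- ct$counts[, keep_taxa, drop = FALSE]
  gen <- tax$genus[match(keep_taxa, tax$taxon_id)]
  agg <- t(rowsum(t(sub), gen))
  totals <- colSums(agg)
  ord <- order(-totals, colnames(agg))
  if (length(ord) > top_n && totals[ord[top_n]] == totals[ord[top_n + 1]])
    inform("Ties at the genus cap broken lexicographically.")
  sel <- sort(colnames(agg)[ord[seq_len(min(top_n, length(ord)))]])
  if (length(sel) < 2) abort("Fewer than 2 genera survive the filters.")
  gen_tax <- tibble(
    taxon_id = sel,
    phylum = tax$phylum[match(sel, tax$genus)]
  )
  community_table(agg[, sel, drop = FALSE], ct$metadata, gen_tax)
}

# Spearman rho (tie-corrected via ranks) and two-sided p from the
# t-approximation, for all column pairs of x (and optionally vs columns of y).
spearman_matrix <- function(x, y = NULL) {
  rx <- apply(x, 2, rank)
  n <- nrow(x)
  if (is.null(y)) {
    rho <- stats::cor(rx)
  } else {
    ry <- apply(y, 2, rank)
    rho <- stats::cor(rx, ry)
  }
  tval <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Build a network object from explicit node and edge tables
#'
#' Mainly useful for constructing reference graphs whose topology is known
#' in closed form.
#'
#' @param edges tibble with `from`, `to` and optionally `rho`, `p_value`,
#'   `sign` (sign defaults to +1).
#' @param nodes optional tibble with `name` (defaults to the union of edge
#'   endpoints) and `mean_rel_abundance`.
#' @param bipartite mark the graph as bipartite.
#' @return an `assembly_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL, bipartite = FALSE) {
  edges <- as_tibble(edges)
  if (!"sign" %in% names(edges)) edges$sign <- 1
  if (is.null(nodes))
    nodes <- tibble(name = unique(c(edges$from, edges$to)),
                    mean_rel_abundance = NA_real_)
  make_network(nodes, edges, bipartite = bipartite)
}

make_network <- function(nodes, edges, bipartite = FALSE) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(list(nodes = nodes, edges = edges, graph = g,
                 bipartite = bipartite),
            class = "assembly_network")
}

#' @export
print.assembly_network <- function(x, ...) {
  cat(sprintf("<assembly_network>%s %d nodes, %d edges (%.0f%% positive)\n",
              if (x$bipartite) " bipartite" else "",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign > 0) else NA))
  invisible(x)
}

#' @export
tidy.assembly_network <- function(x, ...) x$edges

#' Genus co-occurrence network under hard correlation thresholds
#'
#' Spearman correlations between genus relative-abundance profiles; an
#' (undirected) edge is kept iff `|rho| > rho_min` and `p < p_max`
#' (t-approximation, no multiple-testing correction by default, matching
#' the construction this package emulates; set `adjust = "BH"` to correct).
#' Constant genera are excluded with a warning.
#'
#' @param ct genus-level [community_table()] (see [select_taxa()]).
#' @param rho_min correlation magnitude threshold (default 0.8).
#' @param p_max p-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return an `assembly_network` (nodes, edges, igraph graph).
#' @export
correlation_network <- function(ct, rho_min = 0.8, p_max = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (n_samples(ct) < 4) abort("Need at least 4 samples.")
  rel <- relative_abundance(ct)
  const <- apply(rel, 2, function(z) stats::sd(z) == 0)
  if (any(const)) {
    warn(paste0("Excluding constant genera: ",
                paste(colnames(rel)[const], collapse = ", ")))
    rel <- rel[, !const, drop = FALSE]
  }
  sp <- spearman_matrix(rel)
  idx <- which(upper.tri(sp$rho), arr.ind = TRUE)
  p <- sp$p[idx]
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  keep <- abs(sp$rho[idx]) > rho_min & p < p_max
  edges <- tibble(
    from = colnames(rel)[idx[keep, 1]],
    to = colnames(rel)[idx[keep, 2]],
    rho = sp$rho[idx][keep],
    p_value = p[keep],
    sign = sign(sp$rho[idx][keep])
  )
  nodes <- tibble(name = colnames(rel),
                  mean_rel_abundance = colMeans(rel))
  make_network(nodes, edges)
}

#' Bipartite genus-environment correlation network
#'
#' Same Spearman machinery as [correlation_network()], between genus
#' relative abundances and environmental variables. The default p threshold
#' is stricter (0.01). Constant environment variables are excluded with a
#' warning; node sizes carry mean relative abundance for genera.
#'
#' @param ct genus-level [community_table()].
#' @param env environment tibble with `sample_id` and the variables.
#' @param rho_min,p_max edge thresholds (defaults 0.8, 0.01).
#' @param variables environment columns to use.
#' @return a bipartite `assembly_network`.
#' @export
taxon_env_network <- function(ct, env, rho_min = 0.8, p_max = 0.01,
                              variables = intersect(env_variables,
                                                    names(env))) {
  if (!all(rownames(ct$counts) %in% env$sample_id))
    abort("Samples missing from the environment table.")
  ev <- as.matrix(env[match(rownames(ct$counts), env$sample_id), variables])
  rel <- relative_abundance(ct)
  const_g <- apply(rel, 2, function(z) stats::sd(z) == 0)
  if (any(const_g)) {
    warn(paste0("Excluding constant genera: ",
                paste(colnames(rel)[const_g], collapse = ", ")))
    rel <- rel[, !const_g, drop = FALSE]
  }
  const_e <- apply(ev, 2, function(z) stats::sd(z) == 0)
  if (any(const_e)) {
    warn(paste0("Excluding constant environment variables: ",
                paste(colnames(ev)[const_e], collapse = ", ")))
    ev <- ev[, !const_e, drop = FALSE]
  }
  sp <- spearman_matrix(rel, ev)
  idx <- which(abs(sp$rho) > rho_min & sp$p < p_max, arr.ind = TRUE)
  edges <- tibble(
    from = colnames(rel)[idx[, 1]],
    to = colnames(ev)[idx[, 2]],
    rho = sp$rho[idx],
    p_value = sp$p[idx],
    sign = sign(sp$rho[idx])
  )
  nodes <- dplyr::bind_rows(
    tibble(name = colnames(rel), kind = "genus",
           mean_rel_abundance = colMeans(rel)),
    tibble(name = colnames(ev), kind = "environment",
           mean_rel_abundance = NA_real_)
  )
  make_network(nodes, edges, bipartite = TRUE)
}

#' Topology summary of a network
#'
#' Average degree `2E/N`; global clustering as the mean local clustering
#' over nodes of degree >= 2; average path length over the largest
#' connected component; modularity by greedy modularity maximization on
#' the unsigned graph; fraction of positive edges.
#'
#' @param net an `assembly_network`.
#' @return one-row tibble of topology metrics (plus the size of the
#'   largest component the path length was computed on).
#' @export
topology <- function(net) {
  g <- igraph::simplify(net$graph)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (e == 0) {
    warn("Empty graph; topology metrics are 0.")
    return(tibble(n_nodes = n, n_edges = 0, average_degree = 0,
                  clustering_coefficient = 0, average_path_length = 0,
                  modularity = 0, positive_edge_fraction = NA_real_,
                  largest_component = 0))
  }
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc <- if (any(deg >= 2)) mean(loc[deg >= 2]) else 0
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- igraph::mean_distance(sub, directed = FALSE)
  com <- igraph::cluster_fast_greedy(g)
  tibble(
    n_nodes = n, n_edges = e, average_degree = 2 * e / n,
    clustering_coefficient = cc, average_path_length = apl,
    modularity = igraph::modularity(com),
    positive_edge_fraction = if (nrow(net$edges))
      mean(net$edges$sign > 0) else NA_real_,
    largest_component = max(comp$csize)
  )
}

#' @export
glance.assembly_network <- function(x, ...) topology(x)

#' Write a network as a GraphML file and an edge-list CSV
#' @param net an `assembly_network`.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(as.data.frame(net$edges), edges_path, row.names = FALSE)
  invisible(net)
}
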