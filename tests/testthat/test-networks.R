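genus_fixture <- function(n_samples = 12, seed = 31) {
  set.seed(seed)
  # 3 phyla; Phylum3 held below 1% mean relative abundance
  taxa <- paste0("asv", 1:9)
  tax <- tibble::tibble(
    taxon_id = taxa,
    phylum = rep(c("Phylum1", "Phylum2", "Phylum3"), each = 3),
    genus = paste0("G", c(1, 1, 2, 3, 4, 5, 6, 7, 8))
  )
  base <- matrix(rpois(n_samples * 9, 120) + 1, n_samples, 9,
                 dimnames = list(paste0("s", 1:n_samples), taxa))
  base[, 7:9] <- 1  # Phylum3 stays below 1% mean relative abundance
  community_table(base, tibble::tibble(sample_id = rownames(base)), tax)
}

test_that("taxon selection applies the phylum filter and genus cap", {
  ct <- genus_fixture()
  sel <- select_taxa(ct, phylum_min = 0.01, top_n = 200)
  # Phylum3 genera (G6..G8) dropped; remaining 5 genera all kept (cap not
  # binding)
  expect_setequal(colnames(sel$counts), paste0("G", 1:5))
  # counts are summed to genus: G1 = asv1 + asv2
  expect_equal(sel$counts[, "G1"],
               ct$counts[, "asv1"] + ct$counts[, "asv2"])

  # hand-ranked selection with a binding cap
  sel2 <- select_taxa(ct, phylum_min = 0.01, top_n = 2)
  totals <- colSums(sel$counts)
  expect_setequal(colnames(sel2$counts),
                  names(sort(totals, decreasing = TRUE))[1:2])

  expect_error(select_taxa(ct, phylum_min = 0.99), "phyla")
})

test_that("perfect monotone relations produce signed edges at rho = +/-1", {
  set.seed(33)
  a <- sort(rpois(10, 30)) + seq_len(10)  # strictly increasing, no ties
  # constant row totals so relative-abundance ranks equal count ranks
  cnt <- cbind(A = a, B = 2 * a, C = 3 * max(a) + 10 - 3 * a)
  rownames(cnt) <- paste0("s", 1:10)
  ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
  net <- correlation_network(ct, rho_min = 0.8, p_max = 0.05)
  e <- net$edges
  ab <- e[(e$from == "A" & e$to == "B") | (e$from == "B" & e$to == "A"), ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$rho, 1)
  expect_equal(ab$sign, 1)
  ac <- e[(e$from == "A" & e$to == "C") | (e$from == "C" & e$to == "A"), ]
  expect_equal(ac$rho, -1)
  expect_equal(ac$sign, -1)
})

test_that("constant genera are excluded with a warning", {
  cnt <- cbind(A = c(5, 6, 7, 8, 9, 10), B = c(10, 9, 8, 7, 6, 5),
               K = rep(8, 6))
  # K is constant in relative abundance only if row sums are constant
  rownames(cnt) <- paste0("s", 1:6)
  cnt <- cnt[, c("A", "B", "K")]
  cnt["s1", ] <- c(5, 10, 8)
  ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
  rel <- relative_abundance(ct)
  skip_if(stats::sd(rel[, "K"]) > 0)  # guard the construction
  expect_warning(correlation_network(ct), "constant")
})

test_that("topology identities hold on reference graphs", {
  k4 <- t(utils::combn(paste0("v", 1:4), 2))
  net_k4 <- network_from_edges(tibble::tibble(from = k4[, 1], to = k4[, 2]))
  t4 <- topology(net_k4)
  expect_equal(t4$clustering_coefficient, 1)
  expect_equal(t4$average_degree, 3)
  expect_equal(t4$average_path_length, 1)

  path <- network_from_edges(tibble::tibble(from = c("A", "B"),
                                            to = c("B", "C")))
  tp <- topology(path)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$average_path_length, 4 / 3)

  # two disjoint K5 cliques: Q of the 2-block partition = 2 x (0.5 - 0.25)
  k5a <- t(utils::combn(paste0("a", 1:5), 2))
  k5b <- t(utils::combn(paste0("b", 1:5), 2))
  net2 <- network_from_edges(tibble::tibble(
    from = c(k5a[, 1], k5b[, 1]), to = c(k5a[, 2], k5b[, 2])))
  membership <- ifelse(grepl("^a", igraph::V(net2$graph)$name), 1L, 2L)
  q_hand <- igraph::modularity(igraph::simplify(net2$graph), membership)
  expect_equal(q_hand, 0.5)
  expect_gte(topology(net2)$modularity, 0.5 - 1e-9)

  empty <- network_from_edges(
    tibble::tibble(from = character(), to = character()),
    nodes = tibble::tibble(name = c("x", "y"),
                           mean_rel_abundance = NA_real_))
  expect_warning(te <- topology(empty), "[Ee]mpty")
  expect_equal(te$n_edges, 0)
})

test_that("edge sets are invariant to sample order and read-depth scaling", {
  ct <- genus_fixture(n_samples = 14, seed = 35)
  sel <- select_taxa(ct)
  net1 <- correlation_network(sel, rho_min = 0.3, p_max = 0.2)
  # reorder samples and triple every count (relative abundances, and hence
  # Spearman ranks, unchanged)
  set.seed(1)
  perm <- sample(nrow(sel$counts))
  ct2 <- community_table(sel$counts[perm, ] * 3L,
                         sel$metadata[perm, ], sel$taxonomy)
  net2 <- correlation_network(ct2, rho_min = 0.3, p_max = 0.2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(net1$edges), key(net2$edges))
})

test_that("taxon-environment networks find constructed gradients", {
  set.seed(37)
  n <- 16
  soc <- sort(runif(n, 5, 30)) + seq_len(n) * 1e-3
  env <- tibble::tibble(
    sample_id = paste0("s", 1:n), SOC = soc,
    pH = runif(n, 7, 9), TN = runif(n, 0.5, 2),
    BD = rep(1.3, n)  # constant: must be excluded
  )
  cnt <- cbind(G1 = round(soc * 10), G2 = rpois(n, 200) + 1,
               G3 = rpois(n, 200) + 1)
  rownames(cnt) <- env$sample_id
  ct <- community_table(cnt, tibble::tibble(sample_id = env$sample_id))
  expect_warning(net <- taxon_env_network(ct, env, rho_min = 0.8,
                                          p_max = 0.01),
                 "constant")
  e <- net$edges
  g1soc <- e[e$from == "G1" & e$to == "SOC", ]
  expect_equal(nrow(g1soc), 1)
  expect_gt(g1soc$rho, 0.8)
  expect_equal(g1soc$sign, 1)
  expect_true(net$bipartite)
})

test_that("niche-tracking selection makes precipitation the best-connected variable", {
  cfg <- sim_config(n_taxa = 400, n_sites = 24, n_layers = 1,
                    reads_per_sample = 1500, regime = "variable_selection",
                    local_noise_sd = 0.2, seed = 39)
  sim <- simulate_dataset(cfg)
  genus <- select_taxa(sim$community, phylum_min = 0, top_n = 60)
  net <- taxon_env_network(genus, sim$env, rho_min = 0.6, p_max = 0.01)
  deg <- table(factor(net$edges$to,
                      levels = setdiff(unique(net$edges$to), NULL)))
  vars <- intersect(names(deg), c("SWC", "pH", "SOC", "TN", "TP", "TC",
                                  "AN", "AP", "AK", "BD", "EC", "MAT",
                                  "MAP"))
  expect_true(length(vars) > 0)
  expect_equal(deg[["MAP"]], max(deg[vars]))
})

test_that("positive edge fraction reflects edge signs", {
  pos <- network_from_edges(tibble::tibble(
    from = c("A", "B", "C"), to = c("B", "C", "A"), sign = c(1, 1, 1)))
  expect_equal(topology(pos)$positive_edge_fraction, 1)
  mixed <- network_from_edges(tibble::tibble(
    from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A"),
    sign = c(1, 1, -1, -1)))
  expect_equal(topology(mixed)$positive_edge_fraction, 0.5)
})
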