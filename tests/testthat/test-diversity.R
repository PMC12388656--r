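test_that("alpha diversity matches closed-form hand computations", {
  cnt <- matrix(c(5, 1, 1, 2), 1,
                dimnames = list("s1", c("A", "B", "C", "D")))
  ct <- community_table(cnt, tibble::tibble(sample_id = "s1"))
  a <- alpha_diversity(ct)
  expect_equal(a$sobs, 4L)
  expect_equal(a$chao1, 4 + 2 * 1 / (2 * 2))   # F1=2, F2=1
  expect_equal(a$goods_coverage, 1 - 2 / 9)
  p <- c(5, 1, 1, 2) / 9
  expect_equal(a$shannon, -sum(p * log(p)))

  # uniform counts: Shannon = ln k, Pielou = 1
  k <- 7
  u <- matrix(rep(10, k), 1, dimnames = list("s1", paste0("t", 1:k)))
  au <- alpha_diversity(community_table(u, tibble::tibble(sample_id = "s1")))
  expect_equal(au$shannon, log(k))
  expect_equal(au$pielou, 1)

  # single taxon: Shannon 0, Faith PD = root-to-tip path
  tr <- toy_tree3()
  s <- matrix(c(0, 0, 8), 1, dimnames = list("s1", c("A", "B", "C")))
  as1 <- alpha_diversity(community_table(s, tibble::tibble(sample_id = "s1")),
                         tree = tr)
  expect_equal(as1$shannon, 0)
  expect_equal(as1$faith_pd, 2)  # C sits on a length-2 pendant branch
})

test_that("alpha diversity cross-checks against vegan and picante", {
  ct <- random_table(6, 40, reads = 300, seed = 5)
  a <- alpha_diversity(ct)
  expect_equal(a$shannon, unname(vegan::diversity(ct$counts)),
               tolerance = 1e-12)
  ch <- vegan::estimateR(ct$counts)["S.chao1", ]
  expect_equal(a$chao1, unname(ch), tolerance = 1e-8)

  tr <- simulate_tree(40, seed = 6)
  tr$tip.label <- colnames(ct$counts)
  a2 <- alpha_diversity(ct, tr)
  pd <- picante::pd(ct$counts, tr, include.root = TRUE)
  expect_equal(a2$faith_pd, pd$PD, tolerance = 1e-9)
})

test_that("Chao1 equals observed richness when no singletons occur", {
  cnt <- matrix(c(4, 2, 6, 3), 1, dimnames = list("s", paste0("t", 1:4)))
  a <- alpha_diversity(community_table(cnt, tibble::tibble(sample_id = "s")))
  expect_equal(a$chao1, a$sobs)
})

test_that("beta metrics satisfy identity, disjointness, and range bounds", {
  cnt <- matrix(c(3, 1, 0, 0,
                  3, 1, 0, 0,
                  0, 0, 2, 5), 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("A", "B", "C", "D")))
  ct <- community_table(cnt, tibble::tibble(sample_id = paste0("s", 1:3)))
  bc <- beta_matrix(ct, "bray_curtis")
  expect_equal(bc["s1", "s2"], 0)
  expect_equal(bc["s1", "s3"], 1)  # disjoint supports
  expect_true(all(bc >= 0 & bc <= 1))

  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  wu <- beta_matrix(ct, "weighted_unifrac", tr)
  expect_equal(wu["s1", "s2"], 0)
  expect_true(all(wu >= 0 & wu <= 1))
})

test_that("weighted UniFrac equals exhaustive branch enumeration", {
  tr <- toy_tree3()
  cnt <- matrix(c(10, 0, 0,
                  0, 10, 0), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("A", "B", "C")))
  ct <- community_table(cnt, tibble::tibble(sample_id = c("a", "b")))
  wu <- beta_matrix(ct, "weighted_unifrac", tr)
  oracle <- brute_wunifrac(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0), tr)
  expect_equal(wu["a", "b"], oracle, tolerance = 1e-12)

  # random case on a larger tree
  tr2 <- simulate_tree(12, seed = 9)
  ct2 <- random_table(3, 12, reads = 100, seed = 10,
                      taxa = tr2$tip.label)
  wu2 <- beta_matrix(ct2, "weighted_unifrac", tr2)
  P <- relative_abundance(ct2)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    o <- brute_wunifrac(P[pair[1], ], P[pair[2], ], tr2)
    expect_equal(wu2[pair[1], pair[2]], o, tolerance = 1e-12)
  }
})

test_that("NMDS embeds Euclidean configurations with near-zero stress", {
  set.seed(4)
  pts <- matrix(rnorm(16), 8, 2,
                dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(dist(pts))
  dm <- as_dist_matrix(d)
  fit <- nmds(dm, k = 2, seed = 3)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(dm, k = 2, seed = 3)
  expect_equal(fit$points, fit2$points)
  expect_error(nmds(dm[1:2, 1:2], k = 2), "smaller")

  # unit square: recovered distance ranks are exact
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), NULL))
  dsq <- as_dist_matrix(as.matrix(dist(sq)))
  fsq <- nmds(dsq, k = 2, seed = 5)
  emb <- as.matrix(fsq$points[, -1])
  de <- as.matrix(dist(emb))
  sides <- c(de[1, 2], de[2, 3], de[3, 4], de[1, 4])
  diags <- c(de[1, 3], de[2, 4])
  # rank order preserved: every side shorter than every diagonal
  expect_lt(max(sides), min(diags))
})

test_that("ANOSIM equals vegan on a generic case and honors its guards", {
  ct <- random_table(12, 30, reads = 250, seed = 12)
  bc <- beta_matrix(ct, "bray_curtis")
  g <- rep(c("x", "y", "z"), each = 4)
  mine <- anosim(bc, g, n_perm = 199, seed = 1)
  ref <- vegan::anosim(stats::as.dist(bc), g, permutations = 199)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)

  # perfect separation: all between > all within -> R = 1
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  ps <- anosim(as_dist_matrix(d), rep(c("a", "b"), each = 3),
               n_perm = 199, seed = 2)
  expect_equal(ps$statistic, 1)

  # degenerate ties: identical groups of identical samples -> R = 0 + warning
  z <- matrix(0.5, 4, 4)
  diag(z) <- 0
  dimnames(z) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_warning(
    res <- anosim(as_dist_matrix(z), c("a", "a", "b", "b"), n_perm = 99,
                  seed = 3),
    "tied")
  expect_equal(res$statistic, 0)

  expect_warning(anosim(bc[1:5, 1:5], c("a", "a", "a", "a", "b"),
                        n_perm = 49, seed = 1), "single member")
})

test_that("PERMANOVA partitions squared distances exactly as the hand computation", {
  # 4 samples, 2 groups; within = 0.1, between = 0.9
  d <- matrix(0.9, 4, 4)
  d[1:2, 1:2] <- 0.1
  d[3:4, 3:4] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("a", "a", "b", "b")
  res <- permanova(as_dist_matrix(d), g, n_perm = 99, seed = 1)
  ss_total <- sum(d[lower.tri(d)]^2) / 4
  ss_within <- (0.1^2) / 2 + (0.1^2) / 2
  ss_between <- ss_total - ss_within
  f_hand <- (ss_between / 1) / (ss_within / 2)
  expect_equal(res$pseudo_f, f_hand, tolerance = 1e-12)
  expect_equal(res$r_squared, ss_between / ss_total, tolerance = 1e-12)

  # cross-check against vegan::adonis2 on a generic one-factor design
  ct <- random_table(10, 25, reads = 300, seed = 14)
  bc <- beta_matrix(ct, "bray_curtis")
  g2 <- rep(c("u", "v"), each = 5)
  mine <- permanova(bc, g2, n_perm = 99, seed = 5)
  ref <- vegan::adonis2(stats::as.dist(bc) ~ g2, permutations = 99)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)

  # duplicated points, within-distance 0 -> R2 = 1
  dd <- matrix(1, 4, 4)
  dd[1:2, 1:2] <- 0
  dd[3:4, 3:4] <- 0
  diag(dd) <- 0
  dimnames(dd) <- dimnames(d)
  r <- permanova(as_dist_matrix(dd), g, n_perm = 49, seed = 1)
  expect_equal(r$r_squared, 1)
})

test_that("group-test statistics are invariant to relabeling group names", {
  ct <- random_table(9, 20, reads = 200, seed = 16)
  bc <- beta_matrix(ct, "bray_curtis")
  g <- rep(c("T", "M", "S"), each = 3)
  g2 <- rep(c("group1", "group2", "group3"), each = 3)
  expect_equal(anosim(bc, g, n_perm = 99, seed = 4)$statistic,
               anosim(bc, g2, n_perm = 99, seed = 4)$statistic)
  expect_equal(permanova(bc, g, n_perm = 99, seed = 4)$p_value,
               permanova(bc, g2, n_perm = 99, seed = 4)$p_value)
})
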