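test_that("betaMNTD reproduces hand-computed patristic examples", {
  tr <- toy_tree3()
  # community 1 = {A}, community 2 = {C}: d(A,C) = 4 in both directions
  cnt <- matrix(c(5, 0, 0,
                  0, 0, 7), 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  ct <- community_table(cnt, tibble::tibble(sample_id = c("s1", "s2")))
  b <- beta_mntd(ct, tr)
  expect_equal(b["s1", "s2"], 4)

  # identical communities: every taxon's nearest neighbour is itself
  cnt2 <- matrix(c(3, 2, 1,
                   3, 2, 1), 2, byrow = TRUE,
                 dimnames = dimnames(cnt))
  ct2 <- community_table(cnt2, tibble::tibble(sample_id = c("s1", "s2")))
  expect_equal(beta_mntd(ct2, tr)["s1", "s2"], 0)
})

test_that("betaMNTD equals the brute-force double loop and picante on small instances", {
  for (k in 1:8) {
    set.seed(k)
    n_taxa <- sample(3:6, 1)
    tr <- simulate_tree(n_taxa, seed = 100 + k)
    cnt <- matrix(rpois(3 * n_taxa, 2), 3,
                  dimnames = list(paste0("s", 1:3), tr$tip.label))
    cnt[1, ] <- cnt[1, ] + 1  # no empty community
    cnt[2, 1] <- cnt[2, 1] + 1
    cnt[3, n_taxa] <- cnt[3, n_taxa] + 1
    if (any(rowSums(cnt) == 0)) next
    ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
    D <- ape::cophenetic.phylo(tr)[colnames(cnt), colnames(cnt)]
    mine <- beta_mntd(ct, tr)
    oracle <- brute_beta_mntd(cnt, D)
    expect_lt(max(abs(mine - oracle)), 1e-10)
    ref <- as.matrix(picante::comdistnt(cnt, D, abundance.weighted = TRUE))
    expect_lt(max(abs(mine - ref[rownames(mine), colnames(mine)])), 1e-10)

    unw <- beta_mntd(ct, tr, weighted = FALSE)
    oracle_u <- brute_beta_mntd(cnt, D, weighted = FALSE)
    expect_lt(max(abs(unw - oracle_u)), 1e-10)
  }
})

test_that("the compiled null kernel agrees with the reference R engine", {
  ct <- random_table(5, 25, reads = 150, seed = 19)
  tr <- simulate_tree(25, seed = 19)
  tr$tip.label <- colnames(ct$counts)
  D <- ape::cophenetic.phylo(tr)[colnames(ct$counts), colnames(ct$counts)]
  Fw <- relative_abundance(ct)
  pres <- ct$counts > 0
  set.seed(4)
  perms <- rbind(seq_len(25), sample.int(25), sample.int(25))
  acc <- assemblyscape:::.bmntd_null_cpp(Fw, pres, D, perms)
  ref <- lapply(seq_len(3), function(r) {
    p <- perms[r, ]
    assemblyscape:::beta_mntd_engine(Fw, pres, D[p, p])
  })
  expect_lt(max(abs(acc$sum - Reduce(`+`, ref))), 1e-10)
  expect_lt(max(abs(acc$sumsq - Reduce(`+`, lapply(ref, `^`, 2)))), 1e-10)
  # identity permutation reproduces the observed statistic
  expect_lt(max(abs(ref[[1]] - unclass(beta_mntd(ct, tr)))), 1e-12)
})

test_that("betaNTI is NaN with a warning when the null is degenerate", {
  # star tree: every shuffle leaves betaMNTD unchanged
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  cnt <- matrix(c(1, 1, 0, 0,
                  0, 0, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  ct <- community_table(cnt, tibble::tibble(sample_id = c("s1", "s2")))
  expect_warning(z <- beta_nti(ct, star, n_null = 99, seed = 1),
                 "undefined")
  expect_true(is.nan(z$betanti["s1", "s2"]))
})

test_that("betaNTI is calibrated under random assembly from the pool", {
  # random multinomial draws from a tip-exchangeable pool: |z| < 2 for
  # the vast majority of pairs (reduced replicate count of the full
  # calibration run in scripts/acceptance.R)
  frac_ok <- vapply(1:5, function(k) {
    set.seed(300 + k)
    tr <- simulate_tree(60, seed = 300 + k)
    pool <- rlnorm(60, 0, 1.5)
    cnt <- t(stats::rmultinom(10, 500, pool / sum(pool)))
    dimnames(cnt) <- list(paste0("s", 1:10), tr$tip.label)
    ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
    z <- beta_nti(ct, tr, n_null = 199, seed = k)$betanti
    v <- z[lower.tri(z)]
    mean(abs(v) < 2, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(frac_ok), 0.95)
})

test_that("betaNTI detects homogeneous selection on conserved niches", {
  cfg <- sim_config(n_taxa = 2000, n_sites = 6, n_layers = 1,
                    reads_per_sample = 600,
                    regime = "homogeneous_selection", seed = 7)
  sim <- simulate_dataset(cfg)
  z <- beta_nti(sim$community, sim$tree, n_null = 99, seed = 1)$betanti
  expect_lt(median(z[lower.tri(z)], na.rm = TRUE), -2)
})

test_that("RC-bray matches the exactly enumerated null on one-read toys", {
  # 4 samples, richness 1, 1 read each; pool = {A, B, C} with occupancy
  # (2, 1, 1)/4. For the pair (s1, s4), obs BC = 0 and the null BC is 0
  # when both draws coincide: P = sum(p_i^2) with p = (1/2, 1/4, 1/4).
  cnt <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  0, 0, 1,
                  1, 0, 0), 4, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
  p <- c(2, 1, 1) / 4
  p <- p / sum(p)
  p_tie <- sum(p^2)
  rc_exact <- 2 * (0.5 * p_tie) - 1
  rc <- rc_bray(ct, n_null = 9999, seed = 5)
  expect_lt(abs(rc["s1", "s4"] - rc_exact), 0.02)
  # for (s1, s2): obs BC = 1; null BC = 0 (less) with P = p_tie, else
  # ties the observed value at 1
  rc_exact_12 <- 2 * (p_tie + 0.5 * (1 - p_tie)) - 1
  expect_lt(abs(rc["s1", "s2"] - rc_exact_12), 0.02)
})

test_that("identical samples of regionally rare taxa sit at the null minimum", {
  set.seed(8)
  filler <- t(stats::rmultinom(8, 60, rep(1, 12)))
  cnt <- rbind(
    matrix(c(5, 5, rep(0, 12)), 2, 14, byrow = TRUE),
    cbind(matrix(0, 8, 2), filler)
  )
  dimnames(cnt) <- list(paste0("s", 1:10), paste0("t", 1:14))
  ct <- community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
  rc <- rc_bray(ct, n_null = 999, seed = 3)
  expect_lt(rc["s1", "s2"], -0.99)
})

test_that("process classification applies the exact threshold logic", {
  cases <- tibble::tribble(
    ~bnti, ~rc, ~process,
    -3,     0.99, "homogeneous_selection",
     3,    -0.99, "variable_selection",
     0,     0.96, "dispersal_limitation",
     0,    -0.96, "homogeneous_dispersal",
     0,     0,    "drift",
     1.99,  0.5,  "drift",
    -2,     0,    "drift",          # boundary falls to the stochastic side
     2,     0,    "drift",
     0,     0.95, "drift",          # |RC| = 0.95 is drift
     0,    -0.95, "drift"
  )
  labels <- c("x", "y")
  for (i in seq_len(nrow(cases))) {
    b <- matrix(c(0, cases$bnti[i], cases$bnti[i], 0), 2,
                dimnames = list(labels, labels))
    r <- matrix(c(0, cases$rc[i], cases$rc[i], 0), 2,
                dimnames = list(labels, labels))
    res <- classify_processes(as_dist_matrix(b, nonnegative = FALSE),
                              as_dist_matrix(r, nonnegative = FALSE))
    expect_equal(res$pairs$process, cases$process[i])
  }
})

test_that("classification is total and fractions sum to one", {
  set.seed(17)
  n <- 12
  labels <- paste0("s", 1:n)
  b <- matrix(0, n, n, dimnames = list(labels, labels))
  r <- matrix(0, n, n, dimnames = list(labels, labels))
  b[lower.tri(b)] <- runif(n * (n - 1) / 2, -4, 4)
  r[lower.tri(r)] <- runif(n * (n - 1) / 2, -1, 1)
  b <- b + t(b)
  r <- r + t(r)
  md <- tibble::tibble(sample_id = labels,
                       layer = rep(c("T", "M", "S"), each = 4),
                       type = rep(c("AM", "TG"), times = 6))
  res <- classify_processes(as_dist_matrix(b, nonnegative = FALSE),
                            as_dist_matrix(r, nonnegative = FALSE),
                            metadata = md)
  expect_false(any(is.na(res$pairs$process)))
  sums <- res$fractions |>
    dplyr::group_by(group) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # every finite pair maps to exactly one of the five processes
  expect_true(all(res$pairs$process %in%
                    c("homogeneous_selection", "variable_selection",
                      "homogeneous_dispersal", "dispersal_limitation",
                      "drift")))
})

test_that("undefined betaNTI pairs are excluded and counted", {
  labels <- paste0("s", 1:3)
  b <- matrix(c(0, NaN, -3, NaN, 0, 1, -3, 1, 0), 3,
              dimnames = list(labels, labels))
  r <- matrix(0, 3, 3, dimnames = list(labels, labels))
  res <- suppressMessages(
    classify_processes(as_dist_matrix(b, nonnegative = FALSE),
                       as_dist_matrix(r, nonnegative = FALSE)))
  expect_equal(res$n_undefined, 1L)
  expect_equal(sum(res$fractions$n), 2L)
})
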