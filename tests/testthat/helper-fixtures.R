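# Shared fixtures, all built in code.

# Small community with hand-checkable numbers.
toy_counts <- function() {
  m <- matrix(c(5, 1, 1, 2,
                0, 3, 3, 3,
                4, 0, 0, 6),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("A", "B", "C", "D")))
  m
}

toy_table <- function() {
  community_table(toy_counts(),
                  tibble::tibble(sample_id = paste0("s", 1:3),
                                 site = paste0("site", 1:3),
                                 layer = c("T", "M", "S"),
                                 type = c("AM", "AM", "TG")))
}

# The 3-tip tree used across hand-derived examples: ((A:1,B:1):1,C:2);
toy_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_table <- function(n_samples, n_taxa, reads = 200, seed = 1,
                         taxa = paste0("t", seq_len(n_taxa))) {
  set.seed(seed)
  cnt <- t(stats::rmultinom(n_samples, reads,
                            prob = rexp(n_taxa) + 0.05))
  dimnames(cnt) <- list(paste0("s", seq_len(n_samples)), taxa)
  community_table(cnt, tibble::tibble(sample_id = rownames(cnt)))
}

# Brute-force betaMNTD: literal double loop over present taxa.
brute_beta_mntd <- function(cnt, D, weighted = TRUE) {
  S <- nrow(cnt)
  out <- matrix(0, S, S, dimnames = list(rownames(cnt), rownames(cnt)))
  for (k in seq_len(S)) for (l in seq_len(S)) {
    if (k == l) next
    pk <- which(cnt[k, ] > 0)
    pl <- which(cnt[l, ] > 0)
    fk <- if (weighted) cnt[k, pk] / sum(cnt[k, pk]) else
      rep(1 / length(pk), length(pk))
    fl <- if (weighted) cnt[l, pl] / sum(cnt[l, pl]) else
      rep(1 / length(pl), length(pl))
    t1 <- sum(vapply(seq_along(pk), function(ii)
      fk[ii] * min(D[pk[ii], pl]), numeric(1)))
    t2 <- sum(vapply(seq_along(pl), function(jj)
      fl[jj] * min(D[pl[jj], pk]), numeric(1)))
    out[k, l] <- (t1 + t2) / 2
  }
  (out + t(out)) / 2
}

# Brute-force weighted UniFrac by explicit branch enumeration.
brute_wunifrac <- function(p_a, p_b, tree) {
  ntip <- length(tree$tip.label)
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    a <- sum(p_a[tips])
    b <- sum(p_b[tips])
    num <- num + tree$edge.length[e] * abs(a - b)
    den <- den + tree$edge.length[e] * (a + b)
  }
  num / den
}
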