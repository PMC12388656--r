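#' Multiple regression on distance matrices (MRM)
#'
#' Vectorizes the lower triangles of the response and predictor matrices,
#' fits ordinary least squares, and assesses significance by jointly
#' permuting the response matrix's row/column labels and refitting
#' (Legendre's MRM convention). Pairs with a non-finite response (e.g.
#' undefined betaNTI) are dropped.
#'
#' @param response_dm distance matrix for the response.
#' @param predictor_dms named list of predictor distance matrices sharing
#'   the response's labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return an `mrm_fit`: tibble of coefficients with permutation p-values,
#'   plus `r_squared`, `f_p_value`, `n_pairs`.
#' @export
mrm <- function(response_dm, predictor_dms, n_perm = 999, seed = 1) {
  if (is.null(names(predictor_dms)) || any(names(predictor_dms) == ""))
    names(predictor_dms) <- paste0("predictor_",
                                   seq_along(predictor_dms))
  for (p in predictor_dms)
    check_matching_labels(response_dm, p, "response and predictor")
  X <- do.call(cbind, lapply(predictor_dms, lower_vec))
  x_ok <- apply(is.finite(X), 1, all)
  keep_pairs <- is.finite(lower_vec(response_dm)) & x_ok
  Xk <- X[keep_pairs, , drop = FALSE]
  if (ncol(Xk) > 1) {
    sv <- svd(scale(Xk))$d
    if (max(sv) / max(min(sv), 1e-300) > 1e8) {
      r2x <- vapply(seq_len(ncol(Xk)), function(j)
        summary(stats::lm(Xk[, j] ~ Xk[, -j]))$r.squared, numeric(1))
      warn(paste0("Near-collinear predictors; VIFs: ",
                  paste(sprintf("%s=%.1f", colnames(X), 1 / (1 - r2x)),
                        collapse = ", ")))
    }
  }
  # pairs with a defined response move under label permutation, so each
  # fit selects its own usable pairs
  fit_stats <- function(y) {
    ok <- x_ok & is.finite(y)
    f <- stats::lm.fit(cbind(`(Intercept)` = 1, X[ok, , drop = FALSE]),
                       y[ok])
    yk <- y[ok]
    c(f$coefficients, 1 - sum(f$residuals^2) / sum((yk - mean(yk))^2))
  }
  y_obs <- lower_vec(response_dm)
  obs <- fit_stats(y_obs)
  coefs <- obs[-length(obs)]
  r2 <- unname(obs[length(obs)])
  n <- nrow(response_dm)
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    fit_stats(lower_vec(response_dm[p, p]))
  }, numeric(length(coefs) + 1)))
  p_coef <- vapply(seq_along(coefs), function(j)
    (1 + sum(abs(perm_stats[j, ]) >= abs(coefs[j]))) / (n_perm + 1),
    numeric(1))
  p_model <- (1 + sum(perm_stats[length(coefs) + 1, ] >= r2)) / (n_perm + 1)
  structure(list(
    coefficients = tibble(term = names(coefs), estimate = unname(coefs),
                          p_value = p_coef),
    r_squared = r2, f_p_value = p_model, n_pairs = sum(keep_pairs),
    n_perm = n_perm
  ), class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("<mrm_fit> R2 = %.3f (model p = %.3g, %d pairs)\n",
              x$r_squared, x$f_p_value, x$n_pairs))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.mrm_fit <- function(x, ...) x$coefficients

#' @export
glance.mrm_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_value = x$f_p_value,
         n_pairs = x$n_pairs, n_perm = x$n_perm)
}

#' Biotic "taxa association" distance between samples
#'
#' Each sample's association profile weights its genus relative abundances
#' by the genus-genus Spearman correlation structure (`S = P A` with `P`
#' the relative-abundance matrix and `A` the correlation matrix); the
#' distance is Euclidean between profile rows.
#'
#' @param ct genus-level [community_table()].
#' @return a [as_dist_matrix()] over samples.
#' @export
biotic_distance <- function(ct) {
  rel <- relative_abundance(ct)
  keep <- apply(rel, 2, function(z) stats::sd(z) > 0)
  rel <- rel[, keep, drop = FALSE]
  A <- spearman_matrix(rel)$rho
  S <- rel %*% A
  d <- as.matrix(stats::dist(S))
  dimnames(d) <- list(rownames(rel), rownames(rel))
  as_dist_matrix(d)
}

# Topological order of an acyclic inner matrix (inner[i, j] = 1 means
# latent i -> latent j); errors on cycles.
topo_order <- function(inner) {
  k <- nrow(inner)
  remaining <- seq_len(k)
  ord <- integer(0)
  inn <- inner
  while (length(remaining)) {
    src <- remaining[colSums(inn[remaining, remaining, drop = FALSE]) == 0]
    if (!length(src)) abort("Inner path matrix is cyclic.")
    ord <- c(ord, src[1])
    remaining <- setdiff(remaining, src[1])
  }
  ord
}

#' Partial least squares path modeling (mode A, centroid scheme)
#'
#' Latent variables are measured by indicator blocks (mode A outer
#' estimation: weights proportional to indicator-score correlations) and
#' connected by a directed acyclic inner path matrix. Iterative estimation
#' alternates inner (centroid scheme: sign-of-correlation weights over
#' adjacent latents) and outer updates until the largest weight change
#' falls below 1e-6 (error after 300 iterations). Path coefficients come
#' from OLS of each endogenous latent on its predecessors; indirect effects
#' are products along directed paths; the goodness of fit is
#' `GOF = sqrt(mean communality x mean R^2)`. Bootstrap percentile
#' intervals are provided for the path coefficients. Latent orientation is
#' fixed by positive correlation with each block's first indicator.
#'
#' @param data data frame of indicators (rows are observations, e.g.
#'   sample pairs); indicators are z-scored internally.
#' @param blocks named list mapping each latent to its indicator columns.
#' @param inner square 0/1 matrix over the latents, `inner[i, j] = 1`
#'   meaning latent i predicts latent j; must be acyclic.
#' @param n_boot bootstrap resamples for path intervals (default 999; 0
#'   skips the bootstrap).
#' @param seed integer seed.
#' @return a `plspm_fit`: `paths` tibble (direct effects with bootstrap
#'   percentile intervals), `effects` (direct/indirect/total), `scores`,
#'   `outer` (weights and loadings), `r_squared`, `gof`.
#' @export
pls_pm <- function(data, blocks, inner, n_boot = 999, seed = 1) {
  stopifnot(is.matrix(inner), nrow(inner) == ncol(inner),
            length(blocks) == nrow(inner))
  latents <- names(blocks)
  dimnames(inner) <- list(latents, latents)
  topo <- topo_order(inner)
  X <- lapply(blocks, function(cols) {
    m <- scale(as.matrix(data[, cols, drop = FALSE]))
    if (anyNA(m)) abort("Indicators contain missing or constant values.")
    m
  })
  core <- function(X) {
    k <- length(X)
    w <- lapply(X, function(x) rep(1, ncol(x)))
    scores <- matrix(0, nrow(X[[1]]), k)
    normalize <- function(y) y / stats::sd(y)
    for (j in seq_len(k)) scores[, j] <- normalize(X[[j]] %*% w[[j]])
    adj <- (inner + t(inner)) > 0
    for (it in seq_len(300)) {
      delta <- 0
      inner_scores <- scores
      for (j in seq_len(k)) {
        nb <- which(adj[j, ])
        e <- sign(stats::cor(scores[, j], scores[, nb, drop = FALSE]))
        e[e == 0] <- 1
        inner_scores[, j] <- scores[, nb, drop = FALSE] %*% as.numeric(e)
      }
      for (j in seq_len(k)) {
        w_new <- as.numeric(stats::cor(X[[j]], inner_scores[, j]))
        w_new <- w_new / sqrt(sum(w_new^2))
        w_old <- w[[j]] / sqrt(sum(w[[j]]^2))
        delta <- max(delta, max(abs(w_new - w_old)))
        w[[j]] <- w_new
        scores[, j] <- normalize(X[[j]] %*% w[[j]])
      }
      if (delta < 1e-6) break
      if (it == 300) abort("PLS-PM did not converge in 300 iterations.")
    }
    for (j in seq_len(k)) {
      s <- stats::cor(scores[, j], X[[j]][, 1])
      if (is.finite(s) && s < 0) {
        scores[, j] <- -scores[, j]
        w[[j]] <- -w[[j]]
      }
    }
    colnames(scores) <- latents
    B <- matrix(0, k, k, dimnames = list(latents, latents))
    r2 <- stats::setNames(rep(NA_real_, k), latents)
    for (j in seq_len(k)) {
      pred <- which(inner[, j] == 1)
      if (!length(pred)) next
      f <- stats::lm.fit(cbind(1, scores[, pred, drop = FALSE]), scores[, j])
      B[pred, j] <- f$coefficients[-1]
      r2[j] <- 1 - sum(f$residuals^2) /
        sum((scores[, j] - mean(scores[, j]))^2)
    }
    loadings <- lapply(seq_len(k), function(j)
      as.numeric(stats::cor(X[[j]], scores[, j])))
    communality <- unlist(lapply(loadings, function(l) l^2))
    gof <- sqrt(mean(communality) * mean(r2, na.rm = TRUE))
    list(B = B, r2 = r2, scores = scores, w = w, loadings = loadings,
         gof = gof)
  }
  fit <- core(X)
  # Total effects: sum of products along all directed paths.
  k <- length(latents)
  total <- fit$B
  Bp <- fit$B
  for (step in seq_len(k)) {
    Bp <- Bp %*% fit$B
    total <- total + Bp
  }
  indirect <- total - fit$B
  eff <- tibble(
    from = rep(latents, k), to = rep(latents, each = k),
    direct = as.numeric(fit$B), indirect = as.numeric(indirect),
    total = as.numeric(total)
  ) |> dplyr::filter(.data$direct != 0 | .data$indirect != 0)
  path_idx <- which(inner == 1, arr.ind = TRUE)
  paths <- tibble(
    from = latents[path_idx[, 1]], to = latents[path_idx[, 2]],
    estimate = fit$B[path_idx]
  )
  if (n_boot > 0) {
    nobs <- nrow(X[[1]])
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nobs, replace = TRUE)
      Xb <- lapply(X, function(x) {
        xb <- scale(x[idx, , drop = FALSE])
        if (anyNA(xb)) return(NULL)
        xb
      })
      if (any(vapply(Xb, is.null, logical(1))))
        return(rep(NA_real_, nrow(path_idx)))
      tryCatch(core(Xb)$B[path_idx], error = function(e)
        rep(NA_real_, nrow(path_idx)))
    }, numeric(nrow(path_idx))))
    boot <- matrix(boot, nrow = nrow(path_idx))
    paths$conf_low <- apply(boot, 1, stats::quantile, probs = 0.025,
                            na.rm = TRUE)
    paths$conf_high <- apply(boot, 1, stats::quantile, probs = 0.975,
                             na.rm = TRUE)
  }
  outer_tbl <- dplyr::bind_rows(lapply(seq_len(k), function(j)
    tibble(latent = latents[j], indicator = colnames(X[[j]]) %||%
             blocks[[j]],
           weight = fit$w[[j]], loading = fit$loadings[[j]])))
  structure(list(paths = paths, effects = eff,
                 scores = as_tibble(fit$scores), outer = outer_tbl,
                 r_squared = fit$r2[!is.na(fit$r2)], gof = fit$gof,
                 inner = inner, n_boot = n_boot),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("<plspm_fit> GOF = %.3f\n", x$gof))
  print(x$paths)
  cat("R2: ", paste(sprintf("%s=%.3f", names(x$r_squared), x$r_squared),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.plspm_fit <- function(x, ...) x$paths

#' @export
glance.plspm_fit <- function(x, ...) {
  tibble(gof = x$gof, mean_r_squared = mean(x$r_squared),
         n_paths = nrow(x$paths), n_boot = x$n_boot)
}
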