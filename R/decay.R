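# Haversine great-circle distance (km) on a sphere of radius 6371.0088 km.
geographic_distance_km <- function(lat, lon) {
  if (any(abs(lat) > 90)) abort("Latitude outside [-90, 90].")
  if (any(abs(lon) > 180)) abort("Longitude outside [-180, 180].")
  m <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) /
    1000 * (6371.0088 / 6378.137)
  m
}

#' Pairwise geographic distances between samples (km)
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km.
#'
#' @param env environment tibble with `sample_id`, `latitude`, `longitude`.
#' @return a [as_dist_matrix()] labelled by sample id, in km.
#' @export
geographic_distance <- function(env) {
  d <- geographic_distance_km(env$latitude, env$longitude)
  dimnames(d) <- list(env$sample_id, env$sample_id)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  as_dist_matrix(d)
}

#' Pairwise environmental (Euclidean) distances between samples
#'
#' Euclidean distance on z-scored environmental variables.
#'
#' @param env environment tibble with `sample_id` and the variables.
#' @param variables columns to use (defaults to the standard set present).
#' @return a [as_dist_matrix()] labelled by sample id.
#' @export
environmental_distance <- function(env,
                                   variables = intersect(env_variables,
                                                         names(env))) {
  x <- scale(as.matrix(env[, variables]))
  x <- x[, !apply(x, 2, anyNA), drop = FALSE]
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(env$sample_id, env$sample_id)
  as_dist_matrix(d)
}

#' Distance-decay regression of community dissimilarity
#'
#' Fits `ln C = alpha + beta ln(E/G)` by ordinary least squares over sample
#' pairs, where `C` is community dissimilarity and `E/G` environmental or
#' geographic distance. Pairs with a zero on either side are excluded from
#' the log fit (no pseudo-count) and counted. Significance of the slope is
#' assessed by a Mantel-style permutation of one matrix's sample labels,
#' never by shuffling pairs independently. Set `similarity = TRUE` to fit
#' on `1 - C`.
#'
#' @param community_dm dissimilarity matrix (values in `(0, 1]` used).
#' @param predictor_dm geographic (km) or environmental distance matrix.
#' @param n_perm label permutations for the p-value (default 999; 0 skips
#'   the permutation test and reports `p_value = NA`).
#' @param seed integer seed.
#' @param similarity regress `ln(1 - C)` instead of `ln C`.
#' @return a `decay_fit`: list with `alpha`, `beta`, `r_squared`,
#'   `p_value`, `n_pairs`, `n_excluded`, and the pair tibble `pairs`.
#' @export
fit_decay <- function(community_dm, predictor_dm, n_perm = 999, seed = 1,
                      similarity = FALSE) {
  check_matching_labels(community_dm, predictor_dm, "community and predictor")
  cv <- lower_vec(community_dm)
  if (similarity) cv <- 1 - cv
  pv <- lower_vec(predictor_dm)
  usable <- cv > 0 & pv > 0
  n_excluded <- sum(!usable)
  if (sum(usable) < 3) abort("Fewer than 3 usable pairs.")
  fit_once <- function(cm) {
    y <- log(lower_vec(cm))
    ok <- is.finite(y) & pv > 0
    stats::lm.fit(cbind(1, log(pv[ok])), y[ok])$coefficients
  }
  y <- log(cv[usable])
  x <- log(pv[usable])
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  beta_obs <- unname(stats::coef(fit)[2])
  alpha <- unname(stats::coef(fit)[1])
  beta_se <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 2] else
    NA_real_
  tcrit <- stats::qt(0.975, fit$df.residual)
  r2 <- sm$r.squared
  if (n_perm > 0) {
    cm0 <- community_dm
    if (similarity) cm0 <- 1 - cm0
    diag(cm0) <- 0
    beta_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(nrow(cm0))
      fit_once(cm0[p, p])[2]
    }, numeric(1)))
    p <- (1 + sum(abs(beta_null) >= abs(beta_obs), na.rm = TRUE)) /
      (n_perm + 1)
  } else {
    p <- NA_real_
  }
  pairs <- dm_pairs(community_dm, "dissimilarity")
  pairs$predictor <- lower_vec(predictor_dm)
  pairs$used <- usable
  structure(list(alpha = alpha, beta = beta_obs, beta_se = beta_se,
                 conf_low = beta_obs - tcrit * beta_se,
                 conf_high = beta_obs + tcrit * beta_se,
                 r_squared = r2,
                 p_value = p, n_pairs = sum(usable),
                 n_excluded = n_excluded, n_perm = n_perm,
                 similarity = similarity, pairs = pairs),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> ln C = %.4f %+.4f ln(E/G)  r2 = %.3f  p = %.3g  (%d pairs, %d excluded)\n",
    x$alpha, x$beta, x$r_squared, x$p_value, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, beta_se = x$beta_se,
         conf_low = x$conf_low, conf_high = x$conf_high,
         r_squared = x$r_squared,
         p_value = x$p_value, n_pairs = x$n_pairs,
         n_excluded = x$n_excluded)
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- dplyr::filter(object$pairs, .data$used)
  yl <- if (object$similarity) "ln(1 - dissimilarity)" else
    "ln(dissimilarity)"
  y <- if (object$similarity) log(1 - df$dissimilarity) else
    log(df$dissimilarity)
  ggplot2::ggplot(tibble(x = log(df$predictor), y = y),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = object$alpha, slope = object$beta,
                         colour = "blue") +
    ggplot2::labs(x = "ln(distance)", y = yl,
                  subtitle = sprintf("beta = %.4f, r2 = %.2f, p = %.3g",
                                     object$beta, object$r_squared,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
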