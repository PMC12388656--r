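#' Fit Sloan's neutral community model
#'
#' Relates each taxon's occurrence frequency across samples to its mean
#' relative abundance under neutral birth-death with immigration. With
#' `N` the (mean) reads per sample, detection limit `d = 1/N`, and
#' migration rate `m`, the predicted occurrence frequency of a taxon with
#' mean relative abundance `p` is
#' `f_pred(p) = 1 - BetaCDF(d; N m p, N m (1 - p))`.
#' `m` is estimated by least squares over taxa; a coarse log-spaced scan of
#' the SSE profile brackets the optimum before a golden-section refinement,
#' which dodges the flat regions near the boundary. The 95% band is a
#' Wilson binomial interval on `f_pred` at the number of samples, and taxa
#' are classed as `above` / `within` / `below` it.
#'
#' @param ct a [community_table()] of integer counts (>= 10 non-empty taxa).
#' @param N reads per sample for the model; defaults to the mean sample
#'   total (the table is expected to be rarefied, making this exact).
#' @return an `ncm_fit`: list with `m`, `Nm`, `r_squared`, `N`,
#'   `n_samples`, and a per-taxon tibble `taxa` (`taxon_id`, `p`, `f_obs`,
#'   `f_pred`, `lower`, `upper`, `class`).
#' @export
fit_ncm <- function(ct, N = NULL) {
  ct <- drop_zero_taxa(ct)
  cnt <- ct$counts
  if (ncol(cnt) < 10) abort("Need at least 10 taxa occurring in >= 1 sample.")
  S <- nrow(cnt)
  N <- N %||% mean(rowSums(cnt))
  p <- colMeans(relative_abundance(ct))
  f_obs <- colSums(cnt > 0) / S
  if (all(f_obs %in% c(0, 1)))
    warn("All occurrence frequencies are 0 or 1; the fit is uninformative.")
  d <- 1 / N
  pred <- function(m) 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
  sse <- function(m) sum((f_obs - pred(m))^2)
  grid <- exp(seq(log(1e-6), log(1), length.out = 80))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  m_hat <- opt$minimum
  f_pred <- pred(m_hat)
  sst <- sum((f_obs - mean(f_obs))^2)
  r2 <- 1 - opt$objective / sst
  band <- wilson_band(f_pred, S)
  taxa <- tibble(
    taxon_id = colnames(cnt), p = unname(p), f_obs = unname(f_obs),
    f_pred = unname(f_pred), lower = band$lower, upper = band$upper,
    class = dplyr::case_when(
      f_obs > band$upper ~ "above",
      f_obs < band$lower ~ "below",
      TRUE ~ "within"
    )
  )
  structure(list(m = m_hat, Nm = N * m_hat, r_squared = r2, N = N,
                 n_samples = S, taxa = taxa),
            class = "ncm_fit")
}

wilson_band <- function(phat, n, z = stats::qnorm(0.975)) {
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> m = %.4f  Nm = %.1f  R2 = %.3f  (%d samples, %d taxa)\n",
              x$m, x$Nm, x$r_squared, x$n_samples, nrow(x$taxa)))
  print(table(x$taxa$class))
  invisible(x)
}

#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @export
glance.ncm_fit <- function(x, ...) {
  tibble(m = x$m, Nm = x$Nm, r_squared = x$r_squared, N = x$N,
         n_samples = x$n_samples, n_taxa = nrow(x$taxa))
}

#' @export
autoplot.ncm_fit <- function(object, ...) {
  curve_df <- tibble(p = exp(seq(log(max(min(object$taxa$p), 1e-7)),
                                 log(max(object$taxa$p)), length.out = 200)))
  d <- 1 / object$N
  curve_df$f_pred <- 1 - stats::pbeta(d, object$N * object$m * curve_df$p,
                                      object$N * object$m * (1 - curve_df$p))
  band <- wilson_band(curve_df$f_pred, object$n_samples)
  curve_df$lower <- band$lower
  curve_df$upper <- band$upper
  ggplot2::ggplot(object$taxa, ggplot2::aes(x = .data$p, y = .data$f_obs)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.6,
                        size = 1) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(y = .data$f_pred), colour = "blue") +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$lower),
                       colour = "blue", linetype = 2) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$upper),
                       colour = "blue", linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(above = "#2e7d32",
                                            within = "grey40",
                                            below = "#c62828")) +
    ggplot2::labs(x = "Mean relative abundance (log scale)",
                  y = "Occurrence frequency",
                  subtitle = sprintf("m = %.3f, R2 = %.2f",
                                     object$m, object$r_squared)) +
    ggplot2::theme_minimal()
}
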