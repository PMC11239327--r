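#' Deviance information criterion of a fit
#'
#' MCMC estimator of the DIC built from the observed-data log-likelihood
#' `log p(y | theta, z, rho)` evaluated at each retained draw and at the
#' joint MAP draw:
#' `DIC = -(4/S) * sum_s log p(y | draw_s) + 2 * log p(y | MAP)`.
#' Smaller is better; the criterion is used to choose the number of sample
#' clusters K. If any retained draw has a `-Inf` log-likelihood the DIC is
#' `+Inf` with a warning.
#'
#' @param fit an [hmm_biclust()] object.
#' @return an object of class `"hb_dic"`: a list with `K`, `dic`,
#'   `mean_deviance_term`, `map_term` (the two summands, so that
#'   `dic = mean_deviance_term + map_term`) and `n_empty_cluster_draws`,
#'   the number of retained draws containing an empty cluster.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hmm_biclust"))
  ll <- fit$obs_loglik
  if (any(!is.finite(ll))) {
    warning("non-finite log-likelihood among retained draws; DIC is +Inf")
    mean_dev <- Inf
  } else {
    mean_dev <- -4 * mean(ll)
  }
  map_term <- 2 * ll[fit$map$index]
  structure(list(K = fit$K, dic = mean_dev + map_term,
                 mean_deviance_term = mean_dev, map_term = map_term,
                 n_empty_cluster_draws = fit$n_empty_cluster_draws),
            class = "hb_dic")
}

#' @export
print.hb_dic <- function(x, ...) {
  cat(sprintf("DIC (K = %d): %.2f  [mean-deviance %.2f + MAP term %.2f]\n",
              x$K, x$dic, x$mean_deviance_term, x$map_term))
  if (x$n_empty_cluster_draws > 0)
    cat(sprintf("  %d retained draw(s) had an empty cluster\n",
                x$n_empty_cluster_draws))
  invisible(x)
}

#' DIC scan over a grid of cluster numbers
#'
#' Fits the model once per candidate K and reports the DIC curve. The curve
#' typically declines until the true number of clusters and then flattens;
#' pick the K near the elbow, avoiding values flagged for clusters smaller
#' than `min_size` at the MAP (such clusterings should not be selected).
#' Selection is deliberately not automated. Seeds are derived from the base
#' seed and K (not grid position), so permuting `K_grid` permutes the rows.
#'
#' @inheritParams hmm_biclust
#' @param K_grid integer vector of candidate cluster numbers.
#' @param min_size MAP cluster-size threshold used for the
#'   `small_cluster` flag.
#' @param keep_fits if `TRUE`, attach the individual fits as
#'   `attr(, "fits")`.
#' @param ... further arguments passed to [hmm_biclust()].
#' @return a data frame of class `"hb_dic_scan"` with one row per K:
#'   `K`, `dic`, `mean_deviance_term`, `map_term`, `n_empty_cluster_draws`,
#'   `min_map_cluster_size`, `small_cluster`. Plot it with `plot()`.
#' @export
dic_scan <- function(Y, K_grid, n_iter = 2000, burn_in = floor(n_iter / 2),
                     seed = 1, min_size = 3, keep_fits = FALSE, ...) {
  if (!length(K_grid)) stop("'K_grid' must be nonempty")
  rows <- vector("list", length(K_grid))
  fits <- if (keep_fits) vector("list", length(K_grid)) else NULL
  for (i in seq_along(K_grid)) {
    K <- as.integer(K_grid[i])
    fit <- hmm_biclust(Y, K, n_iter = n_iter, burn_in = burn_in,
                       seed = seed + K, ...)
    d <- dic(fit)
    sizes <- tabulate(fit$map$z, nbins = K)
    rows[[i]] <- data.frame(K = K, dic = d$dic,
                            mean_deviance_term = d$mean_deviance_term,
                            map_term = d$map_term,
                            n_empty_cluster_draws = d$n_empty_cluster_draws,
                            min_map_cluster_size = min(sizes),
                            small_cluster = min(sizes) < min_size)
    if (keep_fits) fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hb_dic_scan", "data.frame")
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' @export
plot.hb_dic_scan <- function(x, ...) {
  graphics::plot(x$K, x$dic, type = "b", pch = 19,
                 xlab = "number of clusters K", ylab = "DIC", ...)
  if (any(x$small_cluster))
    graphics::points(x$K[x$small_cluster], x$dic[x$small_cluster],
                     pch = 4, cex = 2, col = 2)
  invisible(x)
}
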