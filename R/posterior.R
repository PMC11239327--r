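#' Joint maximum a posteriori draw of a fit
#'
#' The point estimate is a single retained draw, guaranteeing that labels,
#' feature states and parameters are internally consistent. By default the
#' draw maximizing the complete-data log-likelihood plus the log prior
#' density of the continuous parameters is returned; `type = "loglik"`
#' scores by the complete-data log-likelihood alone. Ties are broken by the
#' earliest draw.
#'
#' @param fit an [hmm_biclust()] object.
#' @param type `"posterior"` (default) or `"loglik"`.
#' @return a list with `index` (retained-draw index), `score`, `z`
#'   (labels), `rho` (p x K states) and `params` (full parameter list of
#'   that draw). For unconstrained fits the states have been relabelled so
#'   state 1 carries the larger cluster mean.
#' @export
map_estimate <- function(fit, type = c("posterior", "loglik")) {
  stopifnot(inherits(fit, "hmm_biclust"))
  if (fit$S < 1) stop("empty trace")
  type <- match.arg(type)
  if (type == "posterior") fit$map else fit$map_lik
}

#' Relabel feature states of an unconstrained point estimate
#'
#' Without the sign constraint on the cluster means the two relevant
#' feature states are exchangeable within each cluster. This relabels
#' states 1 and 2 (and the associated means and variances) per cluster so
#' that state 1 carries the larger cluster mean, restoring the
#' overexpressed/underexpressed interpretation. Estimates already ordered
#' pass through unchanged.
#'
#' @param est a point estimate as returned by [map_estimate()].
#' @return the relabelled point estimate.
#' @export
align_feature_labels <- function(est) {
  pr <- est$params
  K <- length(pr$omega)
  for (k in seq_len(K)) {
    if (pr$mu_cluster[k, 1] < pr$mu_cluster[k, 2]) {
      st <- est$rho[, k]
      col <- st
      col[st == 1] <- 2L
      col[st == 2] <- 1L
      est$rho[, k] <- col
      pr$mu_cluster[k, ] <- pr$mu_cluster[k, 2:1]
      pr$sigma2_cluster[k, ] <- pr$sigma2_cluster[k, 2:1]
      pr$mu_feature[, k, ] <- pr$mu_feature[, k, 2:1]
      pr$sigma2_feature[, k, ] <- pr$sigma2_feature[, k, 2:1]
    }
  }
  est$params <- pr
  est
}

#' Extract the estimated biclusters of a fit
#'
#' Returns the `3 x K` rectangles of the MAP estimate: for every retained
#' sample cluster, its samples crossed with its overexpressed,
#' underexpressed and irrelevant feature sets (which partition the
#' features). Clusters with fewer than `min_size` samples are discarded
#' (default 3, the rule used in the kidney-cancer application); set
#' `min_size = 0` to always obtain all `3 * K` rectangles.
#'
#' @param fit an [hmm_biclust()] object (or a point estimate from
#'   [map_estimate()]).
#' @param min_size minimum cluster size retained.
#' @param type MAP score passed to [map_estimate()].
#' @return a [bicluster_set()].
#' @export
biclusters <- function(fit, min_size = 3, type = "posterior") {
  est <- if (inherits(fit, "hmm_biclust")) map_estimate(fit, type) else fit
  K <- ncol(est$rho)
  out <- list()
  for (k in seq_len(K)) {
    samples <- which(est$z == k)
    if (length(samples) < min_size) next
    for (l in 1:3) {
      out[[length(out) + 1L]] <-
        bicluster(samples = samples,
                  features = which(est$rho[, k] == l),
                  cluster = k, state = l)
    }
  }
  bicluster_set(out)
}
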