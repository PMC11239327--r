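#' Simulate expression data with known ground-truth biclusters
#'
#' Generates the two simulation designs of the accompanying study. In both,
#' every sample cluster k has overexpressed features with mean
#' `mu_k1 = (k + 1)/2`, underexpressed features with mean
#' `mu_k2 = -(k + 1)/2` and irrelevant features with mean 0, plus
#' homoscedastic Gaussian noise. In setting 1 the relevant features form two
#' contiguous blocks at the start of the feature ordering (`n_over` features
#' in state 1 followed by `n_under` in state 2, defaults 100 each, identical
#' for every cluster), mimicking features pre-sorted by biological
#' similarity. In setting 2 the same numbers of relevant features are placed
#' uniformly at random among the p positions, so the ordering carries no
#' information.
#'
#' @param n number of samples.
#' @param K number of sample clusters; samples are assigned in balanced
#'   deterministic blocks (first `ceiling(n/K)` samples to cluster 1, and so
#'   on) unless `assignment = "multinomial"`.
#' @param p number of features (default 1000).
#' @param sigma2 noise variance (1 and 2 in the study).
#' @param setting 1 (ordered relevant blocks) or 2 (random positions).
#' @param seed integer seed; the generator is bit-reproducible given a seed.
#' @param n_over,n_under number of overexpressed / underexpressed features.
#' @param assignment `"balanced"` (default) or `"multinomial"` sample-to-
#'   cluster assignment.
#' @return a list with components `Y` (an n x p matrix with sample and
#'   feature identifiers) and `truth`, an object of class `"hb_truth"`
#'   holding `z` (true labels), `rho` (p x K true states), `mu` (K x 3 true
#'   means), `sigma2`, `setting` and `seed`.
#' @examples
#' sim <- simulate_expression(n = 20, K = 2, p = 50, sigma2 = 1,
#'                            n_over = 5, n_under = 5, seed = 1)
#' truth_biclusters(sim$truth)
#' @export
simulate_expression <- function(n, K, p = 1000, sigma2 = 1, setting = 1,
                                seed = NULL, n_over = 100, n_under = 100,
                                assignment = c("balanced", "multinomial")) {
  assignment <- match.arg(assignment)
  if (n < K) stop("'n' must be at least 'K'")
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  if (!setting %in% c(1, 2)) stop("'setting' must be 1 or 2")
  if (p < n_over + n_under)
    stop(sprintf("'p' must be at least n_over + n_under = %d",
                 n_over + n_under))
  if (!is.null(seed)) set.seed(seed)
  z <- switch(assignment,
              balanced = rep(seq_len(K), each = ceiling(n / K))[seq_len(n)],
              multinomial = sample.int(K, n, replace = TRUE))
  rho <- matrix(3L, p, K)
  if (setting == 1) {
    over <- seq_len(n_over)
    under <- n_over + seq_len(n_under)
  } else {
    pos <- sample.int(p, n_over + n_under)
    over <- pos[seq_len(n_over)]
    under <- pos[n_over + seq_len(n_under)]
  }
  rho[over, ] <- 1L
  rho[under, ] <- 2L
  mu <- cbind((seq_len(K) + 1) / 2, -(seq_len(K) + 1) / 2, 0)
  colnames(mu) <- c("over", "under", "irrelevant")
  ## mean surface: mean of sample i, feature j is mu[z_i, rho_{j, z_i}]
  mumat <- matrix(mu[cbind(rep(seq_len(K), each = p), as.vector(rho))], p, K)
  M <- t(mumat[, z, drop = FALSE])
  Y <- M + matrix(rnorm(n * p, sd = sqrt(sigma2)), n, p)
  dimnames(Y) <- list(paste0("S", seq_len(n)), paste0("F", seq_len(p)))
  truth <- structure(list(z = z, rho = rho, mu = mu, sigma2 = sigma2,
                          setting = setting, seed = seed,
                          n_over = n_over, n_under = n_under),
                     class = "hb_truth")
  list(Y = Y, truth = truth)
}

#' @export
print.hb_truth <- function(x, ...) {
  cat("Ground truth: setting ", x$setting, ", K = ", ncol(x$rho),
      ", n = ", length(x$z), ", p = ", nrow(x$rho),
      ", sigma2 = ", x$sigma2, "\n", sep = "")
  invisible(x)
}

#' True biclusters of a simulated data set
#'
#' Each sample cluster contributes three rectangles (overexpressed,
#' underexpressed, irrelevant feature sets crossed with its samples), giving
#' exactly `3 * K` biclusters; the three feature sets partition the features
#' within each cluster.
#'
#' @param truth an `"hb_truth"` object from [simulate_expression()].
#' @return a [bicluster_set()] of `3 * K` rectangles.
#' @export
truth_biclusters <- function(truth) {
  stopifnot(inherits(truth, "hb_truth"))
  K <- ncol(truth$rho)
  out <- list()
  for (k in seq_len(K)) for (l in 1:3) {
    out[[length(out) + 1L]] <-
      bicluster(samples = which(truth$z == k),
                features = which(truth$rho[, k] == l),
                cluster = k, state = l)
  }
  bicluster_set(out)
}
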