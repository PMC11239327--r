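#' Hyperparameters and model variant for the HMM biclustering model
#'
#' Collects all fixed hyperparameters of the hierarchical model together with
#' the two variant switches: whether feature states follow a first-order
#' Markov chain along the feature ordering (`hmm`) and whether the cluster
#' mean parameters are sign-constrained away from zero (`constraint`).
#' Defaults are the settings used throughout the simulation study and the
#' kidney-cancer application: truncation point `t = 0.2`, diffuse mean prior
#' `Normal(0, 1000)`, inverse-gamma `IG(1, 1)` variance priors, and uniform
#' Dirichlet priors on the cluster probabilities and the transition matrix.
#'
#' @param K number of sample clusters (fixed during one fit).
#' @param alpha Dirichlet prior parameters for the cluster probabilities
#'   `omega`; a scalar is recycled to length `K`.
#' @param delta Dirichlet prior parameters for each row of the 3x3 feature
#'   state transition matrix `xi`; a scalar is recycled to length 3.
#' @param t truncation point: under the constraint variant the overexpressed
#'   cluster mean satisfies `mu_k1 > t` and the underexpressed one
#'   `mu_k2 < -t`.
#' @param mu0,sigma2_mu0 mean and variance of the (truncated) normal prior on
#'   the magnitude of the cluster means `mu_kl`.
#' @param a0,b0 shape and scale of the inverse-gamma priors on all variance
#'   parameters.
#' @param v initial state distribution of each feature chain; must be a
#'   length-3 probability vector (uniform in the model as published).
#' @param hmm logical; `FALSE` replaces the Markov prior on feature states by
#'   i.i.d. uniform categorical states (the "NoHMM" variants).
#' @param constraint logical; `FALSE` drops the sign/truncation constraint on
#'   `mu_kl` (the "NoC" variants), in which case states 1 and 2 are only
#'   identified up to relabelling (see [align_feature_labels()]).
#' @return an object of class `"hb_hyper"`.
#' @seealso [hmm_biclust()]
#' @export
hb_hyper <- function(K, alpha = 1, delta = 1, t = 0.2, mu0 = 0,
                     sigma2_mu0 = 1000, a0 = 1, b0 = 1,
                     v = rep(1 / 3, 3), hmm = TRUE, constraint = TRUE) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("'K' must be a positive integer")
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(delta) == 1L) delta <- rep(delta, 3L)
  if (length(alpha) != K || any(alpha <= 0))
    stop("'alpha' must be positive and of length K")
  if (length(delta) != 3L || any(delta <= 0))
    stop("'delta' must be positive and of length 3")
  if (t <= 0) stop("truncation point 't' must be positive")
  if (sigma2_mu0 <= 0 || a0 <= 0 || b0 <= 0)
    stop("'sigma2_mu0', 'a0' and 'b0' must be positive")
  if (length(v) != 3L || any(v < 0) || abs(sum(v) - 1) > 1e-8)
    stop("'v' must be a length-3 probability vector")
  structure(list(K = K, alpha = as.numeric(alpha), delta = as.numeric(delta),
                 t = t, mu0 = mu0, sigma2_mu0 = sigma2_mu0,
                 a0 = a0, b0 = b0, v = as.numeric(v),
                 hmm = isTRUE(hmm), constraint = isTRUE(constraint)),
            class = "hb_hyper")
}

#' @export
print.hb_hyper <- function(x, ...) {
  variant <- paste0(if (x$hmm) "HMM" else "NoHMM", "Bi-",
                    if (x$constraint) "C" else "NoC")
  cat("Hyperparameters (", variant, "): K = ", x$K,
      ", t = ", x$t, ", mu0 = ", x$mu0, ", sigma2_mu0 = ", x$sigma2_mu0,
      ", a0 = ", x$a0, ", b0 = ", x$b0, "\n", sep = "")
  invisible(x)
}

## Random starting state for the continuous parameters: draws from the
## priors, except that the scale of the cluster-mean prior is capped at 1
## for initialization so that starting means live on the scale of
## standardized expression data (the diffuse prior scale, sd ~ 32, would
## start the chains absurdly far from any data).
hb_init_params <- function(p, K, hyper) {
  sdmu <- sqrt(min(hyper$sigma2_mu0, 1))
  rig <- function(n) rinvgamma(n, hyper$a0, hyper$b0)
  m1 <- rtnorm_lower(K, hyper$t, hyper$mu0, sdmu)
  m2 <- -rtnorm_lower(K, hyper$t, hyper$mu0, sdmu)
  mu_cluster <- cbind(m1, m2, deparse.level = 0)
  sigma2_cluster <- matrix(rig(2 * K), K, 2)
  mu_feature <- array(0, dim = c(p, K, 2))
  for (k in seq_len(K)) for (l in 1:2)
    mu_feature[, k, l] <- rnorm(p, mu_cluster[k, l],
                                sqrt(sigma2_cluster[k, l]))
  list(omega = drop(rdirichlet(1, hyper$alpha)),
       xi = if (hyper$hmm) rdirichlet(3, hyper$delta) else
         matrix(drop(rdirichlet(1, hyper$delta)), 3, 3, byrow = TRUE),
       mu_cluster = mu_cluster,
       sigma2_cluster = sigma2_cluster,
       mu_feature = mu_feature,
       sigma2_feature = array(rig(2 * p * K), dim = c(p, K, 2)),
       sigma2_irrelevant = rig(p))
}

## Fixed neutral starting state (unit variances, cluster means +/-1,
## uniform probabilities).
hb_params <- function(p, K, hyper) {
  mu_feature <- array(0, dim = c(p, K, 2))
  mu_feature[, , 1] <- 1
  mu_feature[, , 2] <- -1
  list(omega = rep(1 / K, K),
       xi = matrix(1 / 3, 3, 3),
       mu_cluster = cbind(rep(1, K), rep(-1, K)),
       sigma2_cluster = matrix(1, K, 2),
       mu_feature = mu_feature,
       sigma2_feature = array(1, dim = c(p, K, 2)),
       sigma2_irrelevant = rep(1, p))
}

check_params <- function(params, p, K) {
  stopifnot(length(params$omega) == K,
            all(dim(params$xi) == c(3, 3)),
            all(dim(params$mu_cluster) == c(K, 2)),
            all(dim(params$sigma2_cluster) == c(K, 2)),
            all(dim(params$mu_feature) == c(p, K, 2)),
            all(dim(params$sigma2_feature) == c(p, K, 2)),
            length(params$sigma2_irrelevant) == p,
            all(params$sigma2_cluster > 0),
            all(params$sigma2_feature > 0),
            all(params$sigma2_irrelevant > 0))
  invisible(params)
}

## log with hard underflow clamp: probabilities below 1e-300 count as zero
log_clamp <- function(x) {
  out <- suppressWarnings(log(x))
  out[x < 1e-300] <- -Inf
  out
}
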