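## Independent oracles used across the tests. Everything here is written
## directly from the model's definition (explicit products of densities),
## on purpose not reusing the package's likelihood code.

## A small fixed parameter set for an n x p, K-cluster toy problem.
toy_params <- function(p, K, mu1 = 0.9, mu2 = -0.8,
                       xi = matrix(c(0.6, 0.2, 0.2,
                                     0.25, 0.5, 0.25,
                                     0.15, 0.15, 0.7), 3, 3, byrow = TRUE)) {
  mu_feature <- array(0, dim = c(p, K, 2))
  mu_feature[, , 1] <- mu1 + 0.05 * seq_len(p)
  mu_feature[, , 2] <- mu2 - 0.05 * seq_len(p)
  list(omega = rep(1 / K, K),
       xi = xi,
       mu_cluster = cbind(rep(1, K), rep(-1, K)),
       sigma2_cluster = matrix(0.5, K, 2),
       mu_feature = mu_feature,
       sigma2_feature = array(1.2, dim = c(p, K, 2)),
       sigma2_irrelevant = rep(0.9, p))
}

toy_Y <- function(n, p, seed = 42) {
  set.seed(seed)
  matrix(round(rnorm(n * p, sd = 0.8), 3), n, p)
}

## Explicit log-weight of one latent configuration (z, rho) under the
## joint: chain prior once per cluster, omega per sample, Gaussian
## observation terms.
oracle_logw <- function(Y, z, rho, params, hyper) {
  p <- nrow(rho); K <- ncol(rho)
  lw <- 0
  for (k in seq_len(K)) {
    if (hyper$hmm) {
      lw <- lw + log(hyper$v[rho[1, k]])
      if (p > 1)
        for (j in 2:p) lw <- lw + log(params$xi[rho[j - 1, k], rho[j, k]])
    } else {
      for (j in seq_len(p)) lw <- lw + log(params$xi[1, rho[j, k]])
    }
  }
  for (i in seq_len(nrow(Y))) {
    k <- z[i]
    lw <- lw + log(params$omega[k])
    for (j in seq_len(p)) {
      l <- rho[j, k]
      mu <- if (l == 3) 0 else params$mu_feature[j, k, l]
      v <- if (l == 3) params$sigma2_irrelevant[j] else
        params$sigma2_feature[j, k, l]
      lw <- lw + dnorm(Y[i, j], mu, sqrt(v), log = TRUE)
    }
  }
  lw
}

## All 3^p feature-state configurations for a single cluster.
rho_configs <- function(p) {
  as.matrix(expand.grid(rep(list(1:3), p)))
}

## Exact distribution over the 3^p chain configurations for K = 1
## (z is degenerate), as normalized probabilities aligned with
## rho_configs(p) rows.
oracle_chain_dist <- function(Y, params, hyper) {
  p <- ncol(Y)
  cfg <- rho_configs(p)
  lw <- apply(cfg, 1, function(r)
    oracle_logw(Y, rep(1, nrow(Y)), matrix(r, ncol = 1), params, hyper))
  w <- exp(lw - max(lw))
  w / sum(w)
}

## Exact full conditional of site j given the other sites, from the
## enumerated joint.
oracle_site_conditional <- function(j, rho_vec, dist, cfg) {
  sel <- rep(TRUE, nrow(cfg))
  for (jj in seq_along(rho_vec))
    if (jj != j) sel <- sel & cfg[, jj] == rho_vec[jj]
  pr <- numeric(3)
  for (l in 1:3) pr[l] <- sum(dist[sel & cfg[, j] == l])
  pr / sum(pr)
}

## Mean and sd of a Normal(mean, sd) truncated to (lower, Inf), by
## numerical quadrature.
tnorm_moments <- function(lower, mean, sd) {
  zc <- integrate(function(x) dnorm(x, mean, sd), lower, Inf)$value
  m1 <- integrate(function(x) x * dnorm(x, mean, sd), lower, Inf)$value / zc
  m2 <- integrate(function(x) x^2 * dnorm(x, mean, sd), lower, Inf)$value / zc
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

## Normalize unnormalized log-probabilities.
softmax_log <- function(lp) {
  w <- exp(lp - max(lp))
  w / sum(w)
}

## Relabel estimated clusters to best match true labels (maximum overlap,
## greedy) and return the permuted estimate.
match_clusters <- function(z_hat, z_true, K) {
  perm <- integer(K)
  tab <- table(factor(z_hat, 1:K), factor(z_true, 1:K))
  for (i in seq_len(K)) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    tab[idx[1], ] <- -1
    tab[, idx[2]] <- -1
  }
  perm
}
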