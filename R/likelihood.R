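#' Gaussian observation log-density
#'
#' Log-density of a single expression value given its feature/cluster/state
#' mean and variance. This is the elementary observation term of the model:
#' `y_ij = mu_jkl + e_ijkl`, `e_ijkl ~ Normal(0, sigma2_jkl)`.
#'
#' @param y observed value(s).
#' @param mu mean(s).
#' @param sigma2 variance(s); must be strictly positive.
#' @return log normal density, vectorized over the inputs.
#' @export
obs_loglik <- function(y, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("'sigma2' must be strictly positive")
  dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE)
}

## Per-cluster observation means/variances implied by a rho column:
## mu[j] and var[j] for samples in cluster k (state-3 mean is 0, variance
## the shared per-feature sigma2_j3).
state_moments <- function(rho_k, params, k) {
  p <- length(rho_k)
  mu <- numeric(p)
  v <- numeric(p)
  for (l in 1:2) {
    sel <- which(rho_k == l)
    if (length(sel)) {
      mu[sel] <- params$mu_feature[cbind(sel, k, l)]
      v[sel] <- params$sigma2_feature[cbind(sel, k, l)]
    }
  }
  sel3 <- which(rho_k == 3)
  if (length(sel3)) v[sel3] <- params$sigma2_irrelevant[sel3]
  list(mu = mu, var = v)
}

#' Complete-data log-likelihood of the HMM biclustering model
#'
#' Joint log-density of the data, the feature-state chains and the cluster
#' labels given all continuous parameters:
#' each of the K feature chains contributes its initial-state probability and
#' its transition factors once, each sample contributes its cluster
#' probability `omega_{z_i}` and the product of Gaussian observation
#' densities for its row. Under the non-HMM variant the chain factors are
#' replaced by independent uniform state probabilities. Zero-probability
#' factors met with positive count yield `-Inf` (never an error).
#'
#' @param Y numeric matrix, samples x features.
#' @param z integer cluster labels, length `nrow(Y)`.
#' @param rho integer feature-state matrix, `ncol(Y)` x K.
#' @param params parameter list (see package conventions).
#' @param hyper an [hb_hyper()] object.
#' @return scalar log-likelihood (finite or `-Inf`).
#' @export
complete_loglik <- function(Y, z, rho, params, hyper) {
  n <- nrow(Y); p <- ncol(Y); K <- hyper$K
  stopifnot(length(z) == n, nrow(rho) == p, ncol(rho) == K)
  ll <- sum(log_clamp(params$omega)[z])
  if (hyper$hmm) {
    lxi <- log_clamp(params$xi)
    lv <- log_clamp(hyper$v)
    for (k in seq_len(K)) {
      ll <- ll + lv[rho[1, k]]
      if (p > 1) ll <- ll + sum(lxi[cbind(rho[-p, k], rho[-1, k])])
    }
  } else {
    ## non-HMM variant: i.i.d. categorical states with the shared state
    ## distribution held in the (identical) rows of xi
    ll <- ll + sum(log_clamp(params$xi[1, ])[as.vector(rho)])
  }
  for (k in seq_len(K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    sm <- state_moments(rho[, k], params, k)
    ll <- ll + sum(dnorm(t(Y[idx, , drop = FALSE]), sm$mu, sqrt(sm$var),
                         log = TRUE))
  }
  if (is.nan(ll)) ll <- -Inf
  ll
}

#' Sufficient statistics of the full conditional distributions
#'
#' Computes every count and sum entering the conjugate Gibbs updates:
#' per-(cluster, state) counts `N_kl`, feature-mean sums `M_kl` and squared
#' deviations `S2_kl`; pooled transition counts `n_rl` over the K feature
#' chains (consecutive pairs along the feature ordering); per-feature cluster
#' sums `Mprime` and cluster sizes `Nprime`; and the residual counts/sums of
#' the variance updates, both in the per-feature scoping used by the sampler
#' and in the printed all-feature form (`Ndprime_kl`, `S2dprime_kl`,
#' `Nrho_prime`, `S2rho_prime`).
#'
#' @inheritParams complete_loglik
#' @return a list of statistics; see Details.
#' @export
sufficient_stats <- function(Y, z, rho, params) {
  K <- ncol(rho); p <- nrow(rho); n <- nrow(Y)
  stopifnot(ncol(Y) == p, length(z) == n)
  N_kl <- M_kl <- S2_kl <- matrix(0, K, 2)
  for (k in seq_len(K)) for (l in 1:2) {
    sel <- which(rho[, k] == l)
    N_kl[k, l] <- length(sel)
    if (length(sel)) {
      muf <- params$mu_feature[cbind(sel, k, l)]
      M_kl[k, l] <- sum(muf)
      S2_kl[k, l] <- sum((muf - params$mu_cluster[k, l])^2)
    }
  }
  nk <- tabulate(z, nbins = K)
  Mprime <- vapply(seq_len(K), function(k)
    colSums(Y[z == k, , drop = FALSE]), numeric(p))
  Ndprime <- N_kl * nk                     # Eq-7 statistic as printed (all j)
  S2dprime <- matrix(0, K, 2)
  for (k in seq_len(K)) for (l in 1:2) {
    sel <- which(rho[, k] == l)
    idx <- which(z == k)
    if (length(sel) && length(idx)) {
      res <- Y[idx, sel, drop = FALSE] -
        matrix(params$mu_feature[cbind(sel, k, l)],
               length(idx), length(sel), byrow = TRUE)
      S2dprime[k, l] <- sum(res^2)
    }
  }
  irr <- rho == 3                          # p x K
  Nrho_prime <- sum(nk * colSums(irr))
  S2rho_prime <- 0
  for (k in seq_len(K)) {
    idx <- which(z == k)
    sel <- which(irr[, k])
    if (length(idx) && length(sel))
      S2rho_prime <- S2rho_prime + sum(Y[idx, sel, drop = FALSE]^2)
  }
  list(M_kl = M_kl, N_kl = N_kl, S2_kl = S2_kl,
       n_rl = transition_counts(rho),
       Mprime = Mprime, Nprime = nk,
       Ndprime_kl = Ndprime, S2dprime_kl = S2dprime,
       Nrho_prime = Nrho_prime, S2rho_prime = S2rho_prime)
}

#' Pooled feature-state transition counts
#'
#' `n_rl` counts transitions from state r to state l over consecutive
#' (in feature order) pairs, pooled across the K chains, so that
#' `sum(n_rl) == K * (p - 1)`.
#'
#' @param rho integer p x K feature-state matrix with values in 1..3.
#' @return 3 x 3 integer matrix of counts.
#' @export
transition_counts <- function(rho) {
  rho <- as.matrix(rho)
  p <- nrow(rho)
  cnt <- matrix(0L, 3, 3)
  if (p < 2) return(cnt)
  from <- rho[-p, , drop = FALSE]
  to <- rho[-1, , drop = FALSE]
  for (r in 1:3) for (l in 1:3)
    cnt[r, l] <- sum(from == r & to == l)
  cnt
}
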