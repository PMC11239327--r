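## Distribution helpers -------------------------------------------------

## n draws from Dirichlet(alpha) (rows of the returned matrix)
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

## inverse-gamma(shape, scale): density ~ x^-(shape+1) exp(-scale/x)
rinvgamma <- function(n, shape, scale) {
  1 / rgamma(n, shape = shape, rate = scale)
}

## Normal(mean, sd) truncated to (lower, Inf). Inverse-CDF on the upper
## tail (numerically stable for moderate truncation); Robert's exponential
## rejection sampler for extreme truncation.
rtnorm_lower <- function(n, lower, mean = 0, sd = 1) {
  alpha <- (lower - mean) / sd
  alpha <- rep_len(alpha, n)
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  easy <- alpha < 6
  if (any(easy)) {
    pa <- pnorm(alpha[easy], lower.tail = FALSE)
    out[easy] <- mean[easy] +
      sd[easy] * qnorm(runif(sum(easy)) * pa, lower.tail = FALSE)
  }
  for (i in which(!easy)) {
    a <- alpha[i]
    lam <- 0.5 * (a + sqrt(a^2 + 4))
    repeat {
      x <- a + stats::rexp(1) / lam
      if (runif(1) <= exp(-0.5 * (x - lam)^2)) break
    }
    out[i] <- mean[i] + sd[i] * x
  }
  out
}

## one draw from a categorical given unnormalized log-probabilities
sample_categorical_log <- function(lp) {
  m <- max(lp)
  if (!is.finite(m))
    stop("all states have zero conditional probability")
  pr <- exp(lp - m)
  sample.int(length(lp), 1L, prob = pr)
}

## Conjugate full-conditional kernels ------------------------------------
## These are the reference (pure R) implementations of the Gibbs updates,
## one draw per call; the compiled engine used by hmm_biclust() repeats the
## same conditionals. All are exported so that individual conditionals can
## be inspected or validated directly.

#' Gibbs update of the cluster probabilities
#'
#' Draws `omega` from its Dirichlet full conditional with parameters
#' `alpha_k + sum_i I(z_i = k)`.
#'
#' @param z integer cluster labels.
#' @param hyper an [hb_hyper()] object.
#' @return a length-K probability vector.
#' @family gibbs kernels
#' @export
gibbs_update_omega <- function(z, hyper) {
  drop(rdirichlet(1, hyper$alpha + tabulate(z, nbins = hyper$K)))
}

#' Gibbs update of the feature-state transition matrix
#'
#' Under the HMM variant each row r of `xi` is drawn independently from
#' `Dirichlet(delta + n_r.)`, with transition counts pooled across the K
#' feature chains. Under the non-HMM variant feature states are i.i.d.
#' categorical with a shared state distribution, drawn from
#' `Dirichlet(delta + pooled state counts)` and returned as three identical
#' rows.
#'
#' @param rho p x K feature-state matrix.
#' @inheritParams gibbs_update_omega
#' @return a 3 x 3 row-stochastic matrix.
#' @family gibbs kernels
#' @export
gibbs_update_xi <- function(rho, hyper) {
  if (hyper$hmm) {
    cnt <- transition_counts(rho)
    t(vapply(1:3, function(r) drop(rdirichlet(1, hyper$delta + cnt[r, ])),
             numeric(3)))
  } else {
    pi <- drop(rdirichlet(1, hyper$delta + tabulate(rho, nbins = 3)))
    matrix(pi, 3, 3, byrow = TRUE)
  }
}

#' Gibbs update of a cluster mean parameter
#'
#' Under the constraint variant, the magnitude `sign(mu_kl) * mu_kl` is
#' drawn from a normal left-truncated at `t` with precision-weighted
#' posterior mean and variance; the sign is positive for the overexpressed
#' state (l = 1) and negative for the underexpressed state (l = 2). Under
#' the no-constraint variant the untruncated normal with the same mean and
#' variance is used.
#'
#' @param k,l cluster and state (l in 1:2) indices.
#' @param stats output of [sufficient_stats()].
#' @param params current parameter list.
#' @inheritParams gibbs_update_omega
#' @return a scalar draw of `mu_kl`.
#' @family gibbs kernels
#' @export
gibbs_update_mu_cluster <- function(k, l, stats, params, hyper) {
  N <- stats$N_kl[k, l]
  M <- stats$M_kl[k, l]
  v2 <- params$sigma2_cluster[k, l]
  if (v2 <= 0) stop("'sigma2_cluster' must be strictly positive")
  sgn <- if (l == 1) 1 else -1
  sd_post <- sqrt(1 / (1 / hyper$sigma2_mu0 + N / v2))
  if (hyper$constraint) {
    m <- (hyper$mu0 * v2 / hyper$sigma2_mu0 + sgn * M) /
      (v2 / hyper$sigma2_mu0 + N)
    sgn * rtnorm_lower(1, hyper$t, m, sd_post)
  } else {
    m <- (hyper$mu0 * v2 / hyper$sigma2_mu0 + M) /
      (v2 / hyper$sigma2_mu0 + N)
    rnorm(1, m, sd_post)
  }
}

#' Gibbs update of a cluster-level variance
#'
#' Inverse-gamma draw with shape `a0 + N_kl/2` and scale `b0 + S2_kl/2`,
#' where `S2_kl` sums squared deviations of the feature means currently in
#' state l from the cluster mean.
#'
#' @inheritParams gibbs_update_mu_cluster
#' @return a positive scalar draw of `sigma2_kl`.
#' @family gibbs kernels
#' @export
gibbs_update_sigma2_cluster <- function(k, l, stats, hyper) {
  rinvgamma(1, hyper$a0 + stats$N_kl[k, l] / 2,
            hyper$b0 + stats$S2_kl[k, l] / 2)
}

#' Gibbs update of the error variance of an irrelevant feature
#'
#' For feature j, residuals are the observations `y_ij` of all samples whose
#' own cluster currently has feature j in state 3 (the state-3 mean is 0).
#'
#' @param j feature index.
#' @param Y data matrix.
#' @param z cluster labels.
#' @param rho feature-state matrix.
#' @inheritParams gibbs_update_omega
#' @return a positive scalar draw of `sigma2_j3`.
#' @family gibbs kernels
#' @export
gibbs_update_sigma2_irrelevant <- function(j, Y, z, rho, hyper) {
  in3 <- rho[j, z] == 3
  rinvgamma(1, hyper$a0 + sum(in3) / 2,
            hyper$b0 + sum(Y[in3, j]^2) / 2)
}

#' Gibbs update of the error variance of a relevant feature
#'
#' For feature j in cluster k and state l (1 or 2), residuals are
#' `y_ij - mu_jkl` over the samples of cluster k, provided feature j is
#' currently in state l there; otherwise the draw reduces to the prior
#' `IG(a0, b0)`.
#'
#' @inheritParams gibbs_update_sigma2_irrelevant
#' @param k,l cluster and state (l in 1:2) indices.
#' @param params current parameter list.
#' @return a positive scalar draw of `sigma2_jkl`.
#' @family gibbs kernels
#' @export
gibbs_update_sigma2_feature <- function(j, k, l, Y, z, rho, params, hyper) {
  if (rho[j, k] == l) {
    r <- Y[z == k, j] - params$mu_feature[j, k, l]
    rinvgamma(1, hyper$a0 + length(r) / 2, hyper$b0 + sum(r^2) / 2)
  } else {
    rinvgamma(1, hyper$a0, hyper$b0)
  }
}

#' Gibbs update of a feature-level mean
#'
#' Conjugate normal draw shrinking the cluster-k sample mean of feature j
#' towards the cluster mean `mu_kl`; when feature j is not currently in
#' state l for cluster k (or the cluster is empty) the draw reduces to the
#' prior `Normal(mu_kl, sigma2_kl)`.
#'
#' @inheritParams gibbs_update_sigma2_feature
#' @return a scalar draw of `mu_jkl`.
#' @family gibbs kernels
#' @export
gibbs_update_mu_feature <- function(j, k, l, Y, z, rho, params, hyper) {
  mc <- params$mu_cluster[k, l]
  vc <- params$sigma2_cluster[k, l]
  vf <- params$sigma2_feature[j, k, l]
  if (vc <= 0 || vf <= 0) stop("variances must be strictly positive")
  if (rho[j, k] == l) {
    idx <- z == k
    Np <- sum(idx)
    Mp <- sum(Y[idx, j])
  } else {
    Np <- 0; Mp <- 0
  }
  m <- (mc * vf / vc + Mp) / (vf / vc + Np)
  v <- 1 / (1 / vc + Np / vf)
  rnorm(1, m, sqrt(v))
}

## Latent-state kernels ---------------------------------------------------

#' Unnormalized log conditional probabilities of a feature state
#'
#' Full conditional of `rho_jk` over the three states: Gaussian likelihood
#' of column j restricted to the samples of cluster k, plus the Markov
#' neighbour factors `xi[rho_{j-1,k}, l]` (absent at j = 1, where the
#' uniform initial distribution cancels) and `xi[l, rho_{j+1,k}]` (absent at
#' j = p). Under the non-HMM variant the neighbour factors are dropped.
#'
#' @inheritParams gibbs_update_sigma2_feature
#' @return length-3 vector of unnormalized log-probabilities.
#' @family gibbs kernels
#' @export
gibbs_rho_logprobs <- function(j, k, Y, z, rho, params, hyper) {
  p <- nrow(rho)
  yj <- Y[z == k, j]
  lp <- numeric(3)
  for (l in 1:3) {
    if (l == 3) {
      mu <- 0; v <- params$sigma2_irrelevant[j]
    } else {
      mu <- params$mu_feature[j, k, l]; v <- params$sigma2_feature[j, k, l]
    }
    lp[l] <- sum(dnorm(yj, mu, sqrt(v), log = TRUE))
  }
  if (hyper$hmm) {
    lxi <- log_clamp(params$xi)
    if (j > 1) lp <- lp + lxi[rho[j - 1, k], ]
    if (j < p) lp <- lp + lxi[, rho[j + 1, k]]
  } else {
    lp <- lp + log_clamp(params$xi[1, ])
  }
  lp
}

#' Gibbs update of one feature-state chain
#'
#' Single-site systematic scan j = 1..p of the full conditionals of
#' `rho_{jk}`, each site drawn given the current states of its neighbours.
#'
#' @inheritParams gibbs_rho_logprobs
#' @return the updated length-p state vector for cluster k.
#' @family gibbs kernels
#' @export
gibbs_update_rho_column <- function(k, Y, z, rho, params, hyper) {
  p <- nrow(rho)
  for (j in seq_len(p)) {
    lp <- gibbs_rho_logprobs(j, k, Y, z, rho, params, hyper)
    if (all(!is.finite(lp)))
      stop(sprintf("zero conditional probability for all states at feature %d, cluster %d",
                   j, k))
    rho[j, k] <- sample_categorical_log(lp)
  }
  rho[, k]
}

#' Unnormalized log conditional probabilities of the cluster labels
#'
#' Row i of the returned matrix holds `log omega_k` plus the Gaussian
#' log-likelihood of sample i under the feature states of cluster k, for
#' each k.
#'
#' @inheritParams complete_loglik
#' @return an n x K matrix of unnormalized log-probabilities.
#' @family gibbs kernels
#' @export
gibbs_z_logprobs <- function(Y, rho, params, hyper) {
  n <- nrow(Y); K <- hyper$K
  L <- matrix(0, n, K)
  lo <- log_clamp(params$omega)
  for (k in seq_len(K)) {
    sm <- state_moments(rho[, k], params, k)
    L[, k] <- colSums(dnorm(t(Y), sm$mu, sqrt(sm$var), log = TRUE)) + lo[k]
  }
  L
}

#' Gibbs update of the cluster labels
#'
#' Each `z_i` is drawn independently from its normalized K-state
#' conditional, computed in log space.
#'
#' @inheritParams complete_loglik
#' @return integer vector of new cluster labels.
#' @family gibbs kernels
#' @export
gibbs_update_z <- function(Y, rho, params, hyper) {
  L <- gibbs_z_logprobs(Y, rho, params, hyper)
  vapply(seq_len(nrow(L)), function(i) sample_categorical_log(L[i, ]),
         integer(1))
}
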