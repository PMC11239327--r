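## Unit-level checks of the conjugate kernels: structural properties plus
## moderate-size moment checks (large-sample moment comparisons at the
## scale of the acceptance criteria live in test-acceptance.R).

ndraw <- 2e4

test_that("omega update draws from the Dirichlet full conditional", {
  hy <- hb_hyper(2)
  set.seed(1)
  ## Dir(3, 2) posterior from z = (1,1,2), alpha = (1,1)
  d <- replicate(ndraw, gibbs_update_omega(c(1L, 1L, 2L), hy))
  expect_equal(rowMeans(d), c(0.6, 0.4), tolerance = 0.01)
  expect_true(all(abs(colSums(d) - 1) < 1e-12))
  ## no data: prior Dir(1, 1), mean 1/2
  d0 <- replicate(ndraw, gibbs_update_omega(integer(0), hy))
  expect_equal(mean(d0[1, ]), 0.5, tolerance = 0.015)
})

test_that("xi update uses pooled transition counts (HMM) or pooled state counts (non-HMM)", {
  hy <- hb_hyper(1)
  rho <- matrix(c(1L, 1L, 2L, 3L), ncol = 1)
  set.seed(2)
  d <- replicate(ndraw, gibbs_update_xi(rho, hy)[1, ])
  ## row 1 ~ Dir(2, 2, 1)
  expect_equal(rowMeans(d), c(0.4, 0.4, 0.2), tolerance = 0.012)
  ## constant state-3 chain: row 3 ~ Dir(1, 1, 1 + K(p-1)), rows 1-2 prior
  rho3 <- matrix(3L, 5, 2)
  set.seed(3)
  d3 <- replicate(ndraw, gibbs_update_xi(rho3, hy))
  expect_equal(mean(d3[3, 3, ]), 9 / 11, tolerance = 0.01)  # Dir(1,1,9)
  expect_equal(mean(d3[1, 1, ]), 1 / 3, tolerance = 0.015)
  ## non-HMM: identical rows, Dirichlet over pooled state counts
  hyn <- hb_hyper(1, hmm = FALSE)
  set.seed(4)
  dn <- gibbs_update_xi(rho, hyn)
  expect_equal(dn[1, ], dn[2, ])
  expect_equal(dn[2, ], dn[3, ])
  dnm <- replicate(ndraw, gibbs_update_xi(rho, hyn)[1, ])
  ## Dir(1+2, 1+1, 1+1): mean (3/7, 2/7, 2/7)
  expect_equal(rowMeans(dnm), c(3, 2, 2) / 7, tolerance = 0.012)
})

test_that("cluster-mean update respects the sign constraint and its posterior", {
  hy <- hb_hyper(1)
  pr <- toy_params(4, 1)
  st <- list(M_kl = matrix(c(3.5, -3.2), 1, 2),
             N_kl = matrix(c(4, 4), 1, 2))
  set.seed(5)
  d1 <- replicate(ndraw, gibbs_update_mu_cluster(1, 1, st, pr, hy))
  d2 <- replicate(ndraw, gibbs_update_mu_cluster(1, 2, st, pr, hy))
  expect_true(all(d1 > hy$t))
  expect_true(all(d2 < -hy$t))
  ## quadrature oracle for the truncated posterior of |mu|
  v2 <- pr$sigma2_cluster[1, 1]
  m <- (hy$mu0 * v2 / hy$sigma2_mu0 + st$M_kl[1, 1]) /
    (v2 / hy$sigma2_mu0 + st$N_kl[1, 1])
  s <- sqrt(1 / (1 / hy$sigma2_mu0 + st$N_kl[1, 1] / v2))
  mom <- tnorm_moments(hy$t, m, s)
  expect_equal(mean(d1), mom["mean"], tolerance = 5 * mom["sd"] / sqrt(ndraw),
               ignore_attr = TRUE)
  ## mirrored for the underexpressed state
  m2 <- (hy$mu0 * v2 / hy$sigma2_mu0 - st$M_kl[1, 2]) /
    (v2 / hy$sigma2_mu0 + st$N_kl[1, 2])
  mom2 <- tnorm_moments(hy$t, m2, s)
  expect_equal(mean(-d2), mom2["mean"], tolerance = 5 * mom2["sd"] / sqrt(ndraw),
               ignore_attr = TRUE)
})

test_that("unconstrained cluster-mean update is the plain conjugate normal", {
  hy <- hb_hyper(1, constraint = FALSE)
  pr <- toy_params(4, 1)
  st <- list(M_kl = matrix(c(3.5, -3.2), 1, 2),
             N_kl = matrix(c(4, 4), 1, 2))
  v2 <- pr$sigma2_cluster[1, 1]
  m <- (hy$mu0 * v2 / hy$sigma2_mu0 + st$M_kl[1, 1]) /
    (v2 / hy$sigma2_mu0 + st$N_kl[1, 1])
  s <- sqrt(1 / (1 / hy$sigma2_mu0 + st$N_kl[1, 1] / v2))
  set.seed(6)
  d <- replicate(ndraw, gibbs_update_mu_cluster(1, 1, st, pr, hy))
  expect_equal(mean(d), m, tolerance = 5 * s / sqrt(ndraw))
  expect_equal(sd(d), s, tolerance = 0.02)
})

test_that("cluster-variance update is inverse-gamma with the stated parameters", {
  hy <- hb_hyper(1)
  ## empty state: prior IG(1, 1), median 1/qgamma(0.5, 1) = 1/log(2)
  st0 <- list(N_kl = matrix(0, 1, 2), S2_kl = matrix(0, 1, 2))
  set.seed(7)
  d0 <- replicate(ndraw, gibbs_update_sigma2_cluster(1, 1, st0, hy))
  expect_equal(median(d0), 1 / log(2), tolerance = 0.05)
  ## posterior IG(1 + 5, 1 + 4): mean 5/5 = 1
  st <- list(N_kl = matrix(10, 1, 2), S2_kl = matrix(8, 1, 2))
  set.seed(8)
  d <- replicate(ndraw, gibbs_update_sigma2_cluster(1, 1, st, hy))
  expect_equal(mean(d), 1, tolerance = 0.02)
  ## large N concentrates near S2/N
  stb <- list(N_kl = matrix(2000, 1, 2), S2_kl = matrix(2000 * 0.7, 1, 2))
  set.seed(9)
  db <- replicate(2000, gibbs_update_sigma2_cluster(1, 1, stb, hy))
  expect_equal(mean(db), 0.7, tolerance = 0.01)
})

test_that("error-variance updates match nested-loop statistics on a toy", {
  set.seed(10)
  n <- 6; p <- 5; K <- 2
  hy <- hb_hyper(K)
  Y <- toy_Y(n, p, seed = 10)
  z <- c(1L, 1L, 2L, 2L, 2L, 1L)
  rho <- matrix(sample(1:3, p * K, replace = TRUE), p, K)
  rho[2, 1] <- 3L; rho[2, 2] <- 3L; rho[4, 1] <- 1L
  pr <- toy_params(p, K)
  ## irrelevant variance for feature 2: loop oracle for N', S'^2
  Np <- 0; Sp <- 0
  for (i in 1:n) if (rho[2, z[i]] == 3) {
    Np <- Np + 1; Sp <- Sp + Y[i, 2]^2
  }
  d <- replicate(ndraw, gibbs_update_sigma2_irrelevant(2, Y, z, rho, hy))
  a <- hy$a0 + Np / 2; b <- hy$b0 + Sp / 2
  expect_equal(mean(d), b / (a - 1), tolerance = 4 * (b / (a - 1)) / sqrt(ndraw) *
                 sqrt(1 / (a - 2)))
  ## relevant variance for (j=4, k=1, l=1): loop oracle for N'', S''^2
  Nd <- 0; Sd <- 0
  for (i in 1:n) if (z[i] == 1 && rho[4, 1] == 1) {
    Nd <- Nd + 1; Sd <- Sd + (Y[i, 4] - pr$mu_feature[4, 1, 1])^2
  }
  d2 <- replicate(ndraw, gibbs_update_sigma2_feature(4, 1, 1, Y, z, rho, pr, hy))
  a2 <- hy$a0 + Nd / 2; b2 <- hy$b0 + Sd / 2
  expect_equal(mean(d2), b2 / (a2 - 1), tolerance = 0.06)
  ## state mismatch falls back to the prior
  d3 <- replicate(ndraw, gibbs_update_sigma2_feature(2, 1, 1, Y, z, rho, pr, hy))
  expect_equal(median(d3), 1 / log(2), tolerance = 0.05)
})

test_that("feature-mean update shrinks between prior and sample mean", {
  set.seed(12)
  n <- 8; p <- 3; K <- 1
  hy <- hb_hyper(K)
  Y <- toy_Y(n, p, seed = 12) + 1
  z <- rep(1L, n)
  rho <- matrix(c(1L, 2L, 3L), ncol = 1)
  pr <- toy_params(p, K)
  ## closed-form posterior for (j=1, l=1)
  vf <- pr$sigma2_feature[1, 1, 1]; vc <- pr$sigma2_cluster[1, 1]
  mc <- pr$mu_cluster[1, 1]
  Mp <- sum(Y[, 1]); Np <- n
  m <- (mc * vf / vc + Mp) / (vf / vc + Np)
  s <- sqrt(1 / (1 / vc + Np / vf))
  d <- replicate(ndraw, gibbs_update_mu_feature(1, 1, 1, Y, z, rho, pr, hy))
  expect_equal(mean(d), m, tolerance = 5 * s / sqrt(ndraw))
  expect_equal(sd(d), s, tolerance = 0.02)
  ## empty cluster: draw from Normal(mu_kl, sigma2_kl)
  d0 <- replicate(ndraw, gibbs_update_mu_feature(1, 1, 1, Y, rep(2L, n),
                                                 matrix(1L, p, 1), pr, hy))
  expect_equal(mean(d0), mc, tolerance = 5 * sqrt(vc) / sqrt(ndraw))
  expect_equal(sd(d0), sqrt(vc), tolerance = 0.02)
  ## flat cluster prior: mean tends to the sample mean
  pr2 <- pr; pr2$sigma2_cluster[] <- 1e8
  d1 <- replicate(2000, gibbs_update_mu_feature(1, 1, 1, Y, z, rho, pr2, hy))
  expect_equal(mean(d1), Mp / Np, tolerance = 0.05)
})

test_that("feature-state conditionals reduce to the chain prior for empty clusters", {
  hy <- hb_hyper(2)
  p <- 4
  pr <- toy_params(p, 2)
  Y <- toy_Y(3, p)
  z <- rep(1L, 3)                       # cluster 2 empty
  rho <- matrix(c(1L, 1L, 2L, 3L, 3L, 2L, 1L, 3L), p, 2)
  lp <- gibbs_rho_logprobs(2, 2, Y, z, rho, pr, hy)
  expected <- log(pr$xi[rho[1, 2], ]) + log(pr$xi[, rho[3, 2]])
  expect_equal(softmax_log(lp), softmax_log(expected), tolerance = 1e-12)
})

test_that("cluster-label conditionals match a hand evaluation", {
  hy <- hb_hyper(2)
  p <- 2
  pr <- toy_params(p, 2)
  pr$omega <- c(0.3, 0.7)
  pr$mu_feature[, 2, ] <- pr$mu_feature[, 2, ] * 0.5
  Y <- toy_Y(2, p)
  rho <- matrix(c(1L, 2L, 2L, 3L), p, 2)
  L <- gibbs_z_logprobs(Y, rho, pr, hy)
  for (i in 1:2) {
    byhand <- numeric(2)
    for (k in 1:2) {
      lk <- log(pr$omega[k])
      for (j in 1:p) {
        l <- rho[j, k]
        mu <- if (l == 3) 0 else pr$mu_feature[j, k, l]
        v <- if (l == 3) pr$sigma2_irrelevant[j] else pr$sigma2_feature[j, k, l]
        lk <- lk + dnorm(Y[i, j], mu, sqrt(v), log = TRUE)
      }
      byhand[k] <- lk
    }
    expect_equal(softmax_log(L[i, ]), softmax_log(byhand), tolerance = 1e-12)
  }
  ## K = 1 is degenerate; identical clusters with equal weights are uniform
  hy1 <- hb_hyper(1)
  expect_true(all(gibbs_update_z(Y, rho[, 1, drop = FALSE],
                                 toy_params(p, 1) |>
                                   (\(x) { x$omega <- 1; x })(), hy1) == 1L))
  prs <- toy_params(p, 2)
  rho_same <- cbind(rho[, 1], rho[, 1])
  Ls <- gibbs_z_logprobs(Y, rho_same, prs, hy)
  expect_equal(Ls[, 1], Ls[, 2], tolerance = 1e-12)
})

test_that("state updates lock onto strongly separated data", {
  set.seed(13)
  n <- 10; p <- 6
  hy <- hb_hyper(1)
  pr <- toy_params(p, 1)
  pr$mu_feature[, , 1] <- 20
  pr$mu_feature[, , 2] <- -20
  pr$sigma2_feature[] <- 0.01
  pr$sigma2_irrelevant[] <- 0.01
  truth <- c(1L, 1L, 2L, 2L, 3L, 3L)
  mu <- c(20, 20, -20, -20, 0, 0)
  Y <- matrix(rnorm(n * p, rep(mu, each = n), 0.05), n, p)
  rho <- matrix(sample(1:3, p, replace = TRUE), ncol = 1)
  for (s in 1:3)
    rho[, 1] <- gibbs_update_rho_column(1, Y, rep(1L, n), rho, pr, hy)
  expect_equal(rho[, 1], truth)
})

test_that("truncated-normal sampler stays above the bound in both regimes", {
  set.seed(14)
  easy <- hmmbiclust:::rtnorm_lower(5000, 0.2, 0, 1)
  expect_true(all(easy > 0.2))
  mom <- tnorm_moments(0.2, 0, 1)
  expect_equal(mean(easy), mom["mean"], ignore_attr = TRUE,
               tolerance = 5 * mom["sd"] / sqrt(5000))
  hard <- hmmbiclust:::rtnorm_lower(2000, 8, 0, 1)   # rejection branch
  expect_true(all(hard > 8 & is.finite(hard)))
  expect_lt(mean(hard), 8.2)
})
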