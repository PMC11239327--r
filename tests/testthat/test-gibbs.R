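## Fit-level behaviour of the full Gibbs sampler.

small_sim <- function(seed = 30, sigma2 = 0.3)
  simulate_expression(n = 60, K = 2, p = 80, sigma2 = sigma2,
                      n_over = 15, n_under = 15, seed = seed)

test_that("a fixed seed makes the whole fit bit-reproducible", {
  sim <- small_sim()
  f1 <- hmm_biclust(sim$Y, 2, n_iter = 120, burn_in = 60, seed = 99)
  f2 <- hmm_biclust(sim$Y, 2, n_iter = 120, burn_in = 60, seed = 99)
  expect_identical(f1$draws$z, f2$draws$z)
  expect_identical(f1$draws$rho, f2$draws$rho)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$map$params$mu_feature, f2$map$params$mu_feature)
  f3 <- hmm_biclust(sim$Y, 2, n_iter = 120, burn_in = 60, seed = 100)
  expect_false(identical(f1$loglik, f3$loglik))
})

test_that("trace bookkeeping matches the iteration plan", {
  sim <- small_sim()
  fit <- hmm_biclust(sim$Y, 2, n_iter = 101, burn_in = 100, seed = 1)
  expect_equal(fit$S, 1)
  expect_equal(fit$map$index, 1)
  fit2 <- hmm_biclust(sim$Y, 2, n_iter = 200, burn_in = 80, thin = 3, seed = 1)
  expect_equal(fit2$S, ceiling((200 - 80) / 3))
  expect_equal(dim(fit2$draws$z), c(60, fit2$S))
  expect_equal(dim(fit2$draws$rho), c(80, 2, fit2$S))
  expect_true(all(is.finite(fit2$loglik)))
  expect_error(hmm_biclust(sim$Y, 2, n_iter = 50, burn_in = 50), "burn_in")
})

test_that("well-separated data are recovered up to label permutation", {
  sim <- small_sim(seed = 31, sigma2 = 0.2)
  fit <- hmm_biclust(sim$Y, 2, n_iter = 600, burn_in = 300, seed = 32)
  perm <- match_clusters(fit$map$z, sim$truth$z, 2)
  expect_equal(perm[fit$map$z], sim$truth$z)
  ## feature states of the matched clusters agree with the truth
  ## at this miniature scale a contiguous block of features can lock into
  ## the swapped relevant state (a well-known single-site-sampler mode);
  ## the bound allows one such block
  for (k in 1:2) {
    err <- mean(fit$map$rho[, k] != sim$truth$rho[, perm[k]])
    expect_lte(err, 0.125)
  }
  expect_gt(f1_biclusters(biclusters(fit), truth_biclusters(sim$truth)), 0.9)
})

test_that("constrained draws always satisfy the sign/truncation bounds", {
  sim <- small_sim()
  fit <- hmm_biclust(sim$Y, 2, n_iter = 300, burn_in = 100, seed = 5)
  mc <- fit$draws$mu_cluster            # K x 2 x S
  expect_true(all(mc[, 1, ] > fit$hyper$t))
  expect_true(all(mc[, 2, ] < -fit$hyper$t))
  ## unconstrained fits are free of the bound but get relabelled at the MAP
  fitn <- hmm_biclust(sim$Y, 2, n_iter = 300, burn_in = 100,
                      constraint = FALSE, seed = 5)
  expect_true(all(fitn$map$params$mu_cluster[, 1] >=
                    fitn$map$params$mu_cluster[, 2]))
})

test_that("feature-level parameter draws can be retained in full", {
  sim <- small_sim()
  fit <- hmm_biclust(sim$Y, 2, n_iter = 120, burn_in = 100, seed = 9,
                     keep_feature_params = TRUE)
  expect_equal(dim(fit$draws$mu_feature), c(80, 2, 2, fit$S))
  expect_equal(dim(fit$draws$sigma2_irrelevant), c(80, fit$S))
  expect_true(all(fit$draws$sigma2_feature > 0))
  ## the stored MAP parameters equal the stored draw at the MAP index
  i <- fit$map$index
  expect_equal(fit$map$params$mu_feature[, , 1],
               fit$draws$mu_feature[, , 1, i])
  expect_equal(fit$map$params$sigma2_irrelevant,
               as.numeric(fit$draws$sigma2_irrelevant[, i]))
})

test_that("over-specified K leaves empty clusters without failing", {
  sim <- simulate_expression(n = 30, K = 1, p = 60, sigma2 = 0.5,
                             n_over = 10, n_under = 10, seed = 33)
  fit <- hmm_biclust(sim$Y, 3, n_iter = 200, burn_in = 100, seed = 34)
  expect_s3_class(fit, "hmm_biclust")
  expect_gte(fit$n_empty_cluster_draws, 0)
  sizes <- tabulate(fit$map$z, 3)
  expect_equal(sum(sizes), 30)
})

test_that("the four model variants all run and are labelled correctly", {
  sim <- small_sim()
  for (hmm in c(TRUE, FALSE)) for (con in c(TRUE, FALSE)) {
    fit <- hmm_biclust(sim$Y, 2, n_iter = 150, burn_in = 50,
                       hmm = hmm, constraint = con, seed = 7)
    expect_equal(fit$hyper$hmm, hmm)
    expect_equal(fit$hyper$constraint, con)
    expect_true(all(is.finite(fit$loglik)))
  }
})

test_that("engine conditionals agree with the exact enumeration on a toy", {
  ## n = 2, p = 3, K = 1 with fixed continuous parameters: the normalized
  ## full conditionals of every site must match the conditionals of the
  ## enumerated joint to numerical accuracy
  hy <- hb_hyper(1)
  p <- 3
  pr <- toy_params(p, 1)
  pr$omega <- 1
  Y <- toy_Y(2, p)
  cfg <- rho_configs(p)
  dist <- oracle_chain_dist(Y, pr, hy)
  for (r in seq_len(nrow(cfg))) {
    rho <- matrix(as.integer(cfg[r, ]), ncol = 1)
    for (j in 1:p) {
      exact <- oracle_site_conditional(j, cfg[r, ], dist, cfg)
      ours <- softmax_log(gibbs_rho_logprobs(j, 1, Y, c(1L, 1L), rho, pr, hy))
      expect_lt(max(abs(exact - ours)), 1e-10)
    }
  }
})

test_that("fixed-parameter latent Gibbs runs and tracks the likelihood", {
  hy <- hb_hyper(2)
  p <- 4; n <- 6
  pr <- toy_params(p, 2)
  pr$omega <- c(0.5, 0.5)
  Y <- toy_Y(n, p)
  out <- gibbs_latents(Y, pr, hy, sweeps = 50, seed = 3)
  expect_equal(dim(out$z), c(n, 50))
  expect_equal(dim(out$rho), c(p, 2, 50))
  expect_true(all(out$z %in% 1:2))
  expect_true(all(out$rho %in% 1:3))
  ## per-sweep log-likelihood matches the R implementation on a draw
  s <- 17
  ll <- complete_loglik(Y, out$z[, s], out$rho[, , s], pr, hy)
  expect_equal(out$loglik[s], ll, tolerance = 1e-8)
})
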