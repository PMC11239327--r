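#' Fit the Bayesian HMM biclustering model by Gibbs sampling
#'
#' Fits the three-state biclustering model to an expression matrix for a
#' fixed number of sample clusters K. Each sample belongs to one of K
#' clusters; within each cluster every feature is latently overexpressed,
#' underexpressed or irrelevant, with a first-order Markov prior along the
#' feature ordering (columns are assumed pre-ordered by biological
#' similarity; see [order_features()]). All full conditionals are conjugate
#' and the sampler cycles: cluster probabilities; feature-level then
#' cluster-level means; variances; transition matrix; cluster labels;
#' feature-state chains. Latent labels are initialized uniformly at random;
#' continuous parameters start at fixed neutral values (unit variances,
#' cluster means +/-1, uniform probabilities).
#'
#' The four model variants are selected by `hmm` (Markov prior vs i.i.d.
#' uniform feature states) and `constraint` (sign-constrained cluster means
#' `mu_k1 > t`, `mu_k2 < -t` vs unconstrained). For unconstrained fits the
#' feature-state labels 1/2 are unidentifiable and the reported point
#' estimate is relabelled so state 1 carries the larger mean
#' (see [align_feature_labels()]).
#'
#' @param Y numeric matrix, samples x features (log-scale expression), no
#'   missing values.
#' @param K number of sample clusters.
#' @param n_iter total Gibbs iterations (default 10000, as in the
#'   large-scale analyses).
#' @param burn_in iterations discarded (default `n_iter/2`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param hmm,constraint model variant switches; see [hb_hyper()].
#' @param hyper optional [hb_hyper()] object; overrides `hmm`/`constraint`.
#' @param seed integer seed (recorded in the fit); `NULL` draws one.
#' @param init `"neutral"` (default) starts the continuous parameters from
#'   fixed neutral values on the scale of standardized data (unit
#'   variances, cluster means +/-1, uniform probabilities); `"random"`
#'   draws them from their priors, with the cluster-mean prior scale capped
#'   at 1 so that starting means stay on the data scale. Latent labels are
#'   always initialized uniformly at random.
#' @param keep_feature_params if `TRUE`, store the feature-level parameter
#'   draws (`mu_jkl`, `sigma2_jkl`, `sigma2_j3`) for every retained draw
#'   rather than only for the MAP draws (memory-heavy for large p).
#' @param verbose print progress every 500 iterations.
#' @return an object of class `"hmm_biclust"`; see [biclusters()],
#'   [map_estimate()], [dic()], and the `print`, `summary`, `coef`, `plot`,
#'   `logLik`, `fitted`, `residuals`, `predict` and `simulate` methods.
#' @examples
#' sim <- simulate_expression(n = 30, K = 2, p = 60, sigma2 = 0.5,
#'                            n_over = 10, n_under = 10, seed = 1)
#' fit <- hmm_biclust(sim$Y, K = 2, n_iter = 400, burn_in = 200, seed = 1)
#' summary(fit)
#' f1_biclusters(biclusters(fit), truth_biclusters(sim$truth))
#' @export
hmm_biclust <- function(Y, K, n_iter = 10000, burn_in = floor(n_iter / 2),
                        thin = 1, hmm = TRUE, constraint = TRUE,
                        hyper = NULL, seed = NULL,
                        init = c("neutral", "random"),
                        keep_feature_params = FALSE, verbose = FALSE) {
  init <- match.arg(init)
  Y <- as.matrix(Y)
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y)))
    stop("'Y' must be a numeric matrix without missing values")
  n <- nrow(Y); p <- ncol(Y)
  if (n < 1 || p < 1) stop("'Y' must have at least one row and column")
  if (is.null(hyper))
    hyper <- hb_hyper(K, hmm = hmm, constraint = constraint)
  stopifnot(inherits(hyper, "hb_hyper"), hyper$K == K)
  if (n_iter <= burn_in || burn_in < 0)
    stop("need n_iter > burn_in >= 0")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)
  z0 <- sample.int(K, n, replace = TRUE)
  rho0 <- matrix(sample.int(3L, p * K, replace = TRUE), p, K)
  params0 <- switch(init,
                    random = hb_init_params(p, K, hyper),
                    neutral = hb_params(p, K, hyper))
  t0 <- proc.time()[["elapsed"]]
  eng <- gibbs_engine_cpp(Y, K, hyper$alpha, hyper$delta, hyper$t,
                          hyper$mu0, hyper$sigma2_mu0, hyper$a0, hyper$b0,
                          hyper$v, hyper$hmm, hyper$constraint,
                          as.integer(n_iter), as.integer(burn_in),
                          as.integer(thin),
                          as.integer(z0), rho0, params0,
                          TRUE, isTRUE(keep_feature_params),
                          isTRUE(verbose))
  elapsed <- proc.time()[["elapsed"]] - t0
  fit <- build_fit(eng, Y, hyper, n_iter, burn_in, thin, seed, elapsed,
                   match.call())
  fit
}

## assemble an "hmm_biclust" object from the engine output
build_fit <- function(eng, Y, hyper, n_iter, burn_in, thin, seed, elapsed,
                      call) {
  wrap_map <- function(m) {
    list(index = m$index,
         score = m$score,
         z = as.integer(m$z),
         rho = matrix(as.integer(m$rho), nrow = nrow(m$rho)),
         params = list(omega = as.numeric(m$omega),
                       xi = m$xi,
                       mu_cluster = m$mu_cluster,
                       sigma2_cluster = m$sigma2_cluster,
                       mu_feature = m$mu_feature,
                       sigma2_feature = m$sigma2_feature,
                       sigma2_irrelevant = as.numeric(m$sigma2_irrelevant)))
  }
  map <- wrap_map(eng$map)
  map_lik <- wrap_map(eng$map_lik)
  if (!hyper$constraint) {
    map <- align_feature_labels(map)
    map_lik <- align_feature_labels(map_lik)
  }
  draws <- list(z = eng$z, rho = eng$rho, omega = eng$omega, xi = eng$xi,
                mu_cluster = eng$mu_cluster,
                sigma2_cluster = eng$sigma2_cluster)
  if (!is.null(eng$mu_feature)) {
    draws$mu_feature <- eng$mu_feature
    draws$sigma2_feature <- eng$sigma2_feature
    draws$sigma2_irrelevant <- eng$sigma2_irrelevant
  }
  structure(list(call = call,
                 n = nrow(Y), p = ncol(Y), K = hyper$K,
                 sample_ids = rownames(Y), feature_ids = colnames(Y),
                 hyper = hyper,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 S = length(eng$cloglik), seed = seed,
                 draws = draws,
                 loglik = as.numeric(eng$cloglik),
                 obs_loglik = as.numeric(eng$obsloglik),
                 log_prior = as.numeric(eng$logprior),
                 map = map, map_lik = map_lik,
                 n_empty_cluster_draws = eng$n_empty_cluster_draws,
                 elapsed = elapsed),
            class = "hmm_biclust")
}

#' Run the latent-state Gibbs sampler with fixed continuous parameters
#'
#' Updates only the cluster labels z and the feature-state chains rho while
#' holding all continuous parameters at the supplied values, through the
#' same compiled kernels used by [hmm_biclust()]. Useful for diagnostics
#' and for checking the sampler against exact enumeration on small
#' problems.
#'
#' @inheritParams hmm_biclust
#' @param params fixed parameter list (same layout as built internally;
#'   see package conventions).
#' @param sweeps number of Gibbs sweeps; every sweep is retained.
#' @param thin keep every `thin`-th sweep.
#' @param z0,rho0 optional initial states (defaults: uniform draws).
#' @return a list with `z` (n x S draws), `rho` (p x K x S draws) and the
#'   per-sweep complete-data log-likelihood.
#' @export
gibbs_latents <- function(Y, params, hyper, sweeps, thin = 1, seed = NULL,
                          z0 = NULL, rho0 = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y); K <- hyper$K
  check_params(params, p, K)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(z0)) z0 <- sample.int(K, n, replace = TRUE)
  if (is.null(rho0)) rho0 <- matrix(sample.int(3L, p * K, replace = TRUE), p, K)
  eng <- gibbs_engine_cpp(Y, K, hyper$alpha, hyper$delta, hyper$t,
                          hyper$mu0, hyper$sigma2_mu0, hyper$a0, hyper$b0,
                          hyper$v, hyper$hmm, hyper$constraint,
                          as.integer(sweeps + 1L), 1L, as.integer(thin),
                          as.integer(z0), rho0, params,
                          FALSE, FALSE, FALSE)
  list(z = eng$z, rho = eng$rho, loglik = as.numeric(eng$cloglik))
}
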