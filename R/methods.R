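#' @export
print.hmm_biclust <- function(x, ...) {
  variant <- paste0(if (x$hyper$hmm) "HMM" else "NoHMM", "Bi-",
                    if (x$hyper$constraint) "C" else "NoC")
  cat("Bayesian HMM biclustering fit (", variant, ")\n", sep = "")
  cat(sprintf("  %d samples x %d features, K = %d clusters\n",
              x$n, x$p, x$K))
  cat(sprintf("  %d iterations (%d burn-in, thin %d): %d retained draws\n",
              x$n_iter, x$burn_in, x$thin, x$S))
  cat(sprintf("  MAP draw %d, complete-data log-likelihood %.2f\n",
              x$map$index, x$loglik[x$map$index]))
  sizes <- tabulate(x$map$z, nbins = x$K)
  cat("  MAP cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hmm_biclust <- function(object, ...) {
  est <- object$map
  K <- object$K
  sizes <- tabulate(est$z, nbins = K)
  counts <- t(vapply(seq_len(K), function(k)
    tabulate(est$rho[, k], nbins = 3), integer(3)))
  tab <- data.frame(cluster = seq_len(K), size = sizes,
                    mu_over = est$params$mu_cluster[, 1],
                    mu_under = est$params$mu_cluster[, 2],
                    over = counts[, 1], under = counts[, 2],
                    irrelevant = counts[, 3])
  out <- list(fit = object, table = tab,
              dic = dic(object),
              mean_loglik = mean(object$loglik))
  class(out) <- "summary.hmm_biclust"
  out
}

#' @export
print.summary.hmm_biclust <- function(x, ...) {
  print(x$fit)
  cat("\nMAP cluster composition (feature states and cluster means):\n")
  tab <- x$table
  tab$mu_over <- round(tab$mu_over, 3)
  tab$mu_under <- round(tab$mu_under, 3)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$dic)
  invisible(x)
}

#' @export
coef.hmm_biclust <- function(object, ...) {
  object$map$params
}

#' @export
logLik.hmm_biclust <- function(object, ...) {
  est <- object$map
  val <- object$obs_loglik[est$index]
  K <- object$K; p <- object$p
  df <- (K - 1) + (if (object$hyper$hmm) 6 else 0) +
    2 * K + 2 * K + 2 * p * K + 2 * p * K + p
  structure(val, df = df, nobs = object$n, class = "logLik")
}

#' @export
fitted.hmm_biclust <- function(object, ...) {
  est <- object$map
  sm <- lapply(seq_len(object$K), function(k)
    state_moments(est$rho[, k], est$params, k))
  M <- t(vapply(seq_len(object$n), function(i) sm[[est$z[i]]]$mu,
                numeric(object$p)))
  dimnames(M) <- list(object$sample_ids, object$feature_ids)
  M
}

#' @export
residuals.hmm_biclust <- function(object, y = NULL, ...) {
  if (is.null(y))
    stop("supply the data matrix as 'y' (it is not stored in the fit)")
  y - fitted(object)
}

#' Posterior predictive simulation from the MAP parameters
#'
#' Draws new expression matrices from the fitted model at the MAP draw:
#' each cell is Gaussian with the mean and variance implied by the MAP
#' cluster label of its sample and feature state of its column.
#'
#' @param object an [hmm_biclust()] fit.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` matrices.
#' @export
simulate.hmm_biclust <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- object$map
  sm <- lapply(seq_len(object$K), function(k)
    state_moments(est$rho[, k], est$params, k))
  M <- t(vapply(seq_len(object$n), function(i) sm[[est$z[i]]]$mu,
                numeric(object$p)))
  V <- t(vapply(seq_len(object$n), function(i) sm[[est$z[i]]]$var,
                numeric(object$p)))
  lapply(seq_len(nsim), function(s) {
    out <- M + matrix(rnorm(length(M), sd = sqrt(V)), nrow(M), ncol(M))
    dimnames(out) <- list(object$sample_ids, object$feature_ids)
    out
  })
}

#' Classify new samples with a fitted model
#'
#' Assigns new samples to the fitted clusters by evaluating, at the MAP
#' draw, the same conditional used for the cluster labels during sampling
#' (cluster probability times the Gaussian likelihood of the row under each
#' cluster's feature states).
#'
#' @param object an [hmm_biclust()] fit.
#' @param newdata numeric matrix with the same features (columns) as the
#'   training data.
#' @param type `"class"` for hard labels, `"prob"` for the n x K posterior
#'   probability matrix.
#' @param ... unused.
#' @return integer labels or a probability matrix.
#' @export
predict.hmm_biclust <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("'newdata' must have ", object$p, " columns")
  est <- object$map
  L <- gibbs_z_logprobs(newdata, est$rho, est$params, object$hyper)
  if (type == "class") return(max.col(L, ties.method = "first"))
  pr <- exp(L - apply(L, 1, max))
  pr / rowSums(pr)
}

#' Trace plot of a fit
#'
#' Plots the complete-data log-likelihood of the retained draws (a quick
#' mixing/convergence diagnostic) and marks the MAP draw.
#'
#' @param x an [hmm_biclust()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hmm_biclust <- function(x, ...) {
  graphics::plot(seq_len(x$S), x$loglik, type = "l",
                 xlab = "retained draw", ylab = "complete-data log-likelihood",
                 ...)
  graphics::abline(v = x$map$index, col = 2, lty = 2)
  invisible(x)
}
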