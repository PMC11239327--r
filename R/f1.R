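#' Biclusters and bicluster sets
#'
#' A bicluster is a rectangle: a set of sample indices crossed with a set of
#' feature indices. `bicluster()` builds one; `bicluster_set()` collects
#' several into the unit on which the F1 similarity operates. Empty sample
#' or feature sets are allowed (a state unused by a cluster yields an empty
#' rectangle that matches nothing).
#'
#' @param samples integer sample indices.
#' @param features integer feature indices.
#' @param cluster,state optional labels recording provenance.
#' @return `bicluster()` an object of class `"bicluster"`;
#'   `bicluster_set()` a list of them with class `"bicluster_set"`.
#' @export
bicluster <- function(samples, features, cluster = NA_integer_,
                      state = NA_integer_) {
  structure(list(samples = as.integer(samples),
                 features = as.integer(features),
                 cluster = cluster, state = state),
            class = "bicluster")
}

#' @param x for `bicluster_set()`, a list of `"bicluster"` objects.
#' @rdname bicluster
#' @export
bicluster_set <- function(x) {
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "bicluster")))
  structure(x, class = "bicluster_set")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("Bicluster (cluster %s, state %s): %d samples x %d features\n",
              x$cluster, x$state, length(x$samples), length(x$features)))
  invisible(x)
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat("Set of", length(x), "biclusters\n")
  for (b in x) print(b)
  invisible(x)
}

#' F1 similarity between two biclusters
#'
#' `F1(A, B) = 2 r c / (n_A + n_B)` where r and c are the numbers of shared
#' samples and shared features and `n_A = |samples_A| * |features_A|` is the
#' rectangle size (the harmonic mean of precision and recall on matrix
#' cells). Equal nonempty rectangles score 1; two empty rectangles score 0
#' by convention.
#'
#' @param A,B `"bicluster"` objects.
#' @return a number in `[0, 1]`.
#' @export
f1_pair <- function(A, B) {
  nA <- length(A$samples) * length(A$features)
  nB <- length(B$samples) * length(B$features)
  if (nA + nB == 0) return(0)
  r <- length(intersect(A$samples, B$samples))
  cc <- length(intersect(A$features, B$features))
  2 * r * cc / (nA + nB)
}

#' One-sided bicluster-set similarity
#'
#' `S(M1, M2)` is the mean over the rectangles of M1 of their best F1 match
#' in M2. It is not symmetric; see [f1_biclusters()] for the symmetrized
#' version.
#'
#' @param M1,M2 `"bicluster_set"` objects; M1 must be nonempty.
#' @return a number in `[0, 1]`; 0 with a warning if M2 is empty.
#' @export
bicluster_similarity <- function(M1, M2) {
  if (!length(M1)) stop("'M1' must be a nonempty bicluster set")
  if (!length(M2)) {
    warning("empty reference bicluster set; similarity is 0")
    return(0)
  }
  best <- vapply(M1, function(A)
    max(vapply(M2, function(B) f1_pair(A, B), numeric(1))), numeric(1))
  mean(best)
}

#' Symmetrized F1 similarity between two bicluster sets
#'
#' `(S(M1, M2) + S(M2, M1)) / 2`: the average of the two one-sided
#' best-match similarities. Bounded by 1, with equality when the two sets
#' contain the same rectangles.
#'
#' @inheritParams bicluster_similarity
#' @return a number in `[0, 1]`; 0 with a warning if either set is empty.
#' @export
f1_biclusters <- function(M1, M2) {
  if (!length(M1) || !length(M2)) {
    warning("empty bicluster set; F1 is 0")
    return(0)
  }
  (bicluster_similarity(M1, M2) + bicluster_similarity(M2, M1)) / 2
}
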