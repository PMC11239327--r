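## Expression matrices are plain numeric matrices, samples in rows and
## features in columns, with row/column names as identifiers. On disk:
## delimited text with a header row of feature ids and the sample ids in
## the first column.

#' Read an expression matrix from delimited text
#'
#' Expects a header row of feature identifiers and sample identifiers in
#' the first column; the delimiter is taken from the file extension
#' (`.csv` = comma, otherwise tab) unless given. Missing or non-numeric
#' cells and duplicated identifiers are errors.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return a numeric matrix, samples x features.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicated feature identifiers: ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "))
  Y <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(Y)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in feature column '%s'",
                 names(df)[-1][bad]))
  }
  if (anyNA(Y)) {
    idx <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 ids[idx[1]], colnames(Y)[idx[2]]))
  }
  rownames(Y) <- ids
  Y
}

#' Write an expression matrix as delimited text
#'
#' @param Y numeric matrix, samples x features.
#' @param path output path; extension picks the delimiter as in
#'   [read_expression()].
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @export
write_expression <- function(Y, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample = rownames(Y), Y, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit variance
#'
#' Per-feature (column) centring and scaling, matching the model's
#' per-feature means and variances. Constant columns are rejected: features
#' with no variance should be filtered before analysis.
#'
#' @param Y numeric matrix, samples x features.
#' @return the standardized matrix.
#' @export
standardize_features <- function(Y) {
  sds <- apply(Y, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(Y)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance feature(s): ", paste(head(bad, 5), collapse = ", "))
  }
  out <- scale(Y)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Order features by a precomputed similarity matrix
#'
#' Greedy nearest-neighbour seriation: the path is seeded with the most
#' similar feature pair, then repeatedly extended at whichever endpoint has
#' the most similar unplaced feature. Intended for pre-ordering features by
#' an external biological similarity (for example a Gene Ontology semantic
#' similarity matrix, computed elsewhere) before fitting, so that the
#' Markov prior can borrow strength between functionally close features.
#'
#' @param Y numeric matrix, samples x features.
#' @param similarity symmetric p x p similarity matrix (larger = more
#'   similar).
#' @return `Y` with columns permuted; the permutation applied is recorded
#'   in `attr(, "feature_order")`.
#' @export
order_features <- function(Y, similarity) {
  p <- ncol(Y)
  similarity <- as.matrix(similarity)
  if (!all(dim(similarity) == c(p, p)))
    stop("'similarity' must be ", p, " x ", p)
  if (max(abs(similarity - t(similarity))) > 1e-8)
    stop("'similarity' must be symmetric")
  if (p == 1) {
    attr(Y, "feature_order") <- 1L
    return(Y)
  }
  S <- similarity
  diag(S) <- -Inf
  start <- which(S == max(S), arr.ind = TRUE)[1, ]
  path <- sort(as.integer(start))
  placed <- logical(p)
  placed[path] <- TRUE
  while (sum(placed) < p) {
    free <- which(!placed)
    left <- path[1]
    right <- path[length(path)]
    sl <- S[left, free]
    sr <- S[right, free]
    if (max(sr) >= max(sl)) {      # ties extend the right end
      nxt <- free[which.max(sr)]
      path <- c(path, nxt)
    } else {
      nxt <- free[which.max(sl)]
      path <- c(nxt, path)
    }
    placed[nxt] <- TRUE
  }
  if (path[1] > path[p]) path <- rev(path)   # canonical orientation
  stopifnot(identical(sort(path), seq_len(p)))
  out <- Y[, path, drop = FALSE]
  attr(out, "feature_order") <- path
  out
}
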