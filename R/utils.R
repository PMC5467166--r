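# internal validation helpers

validate_expression <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(X))) stop("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(X))) {
    stop("duplicated gene id(s): ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  }
  if (is.null(colnames(X))) stop("expression matrix must have sample ids as colnames")
  if (anyDuplicated(colnames(X))) stop("duplicated sample ids")
  if (any(!is.finite(X))) stop("expression matrix contains non-finite values")
  X
}

check_square_symmetric <- function(M, what = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || !is.numeric(M)) stop(what, " must be a numeric matrix")
  if (nrow(M) != ncol(M)) stop(what, " must be square")
  if (any(!is.finite(M))) stop(what, " contains non-finite values")
  if (max(abs(M - t(M))) > tol) stop(what, " must be symmetric")
  invisible(M)
}

check_similarity <- function(S) {
  check_square_symmetric(S, "similarity")
  if (any(S < 0) || any(S > 1)) stop("similarity values must lie in [0, 1]")
  invisible(S)
}

# standardize genes (rows) to zero mean / unit SD across samples
standardize_rows <- function(X) {
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s) cannot be standardized: ",
         paste(utils::head(rownames(X)[sds == 0], 5L), collapse = ", "))
  }
  sweep(sweep(X, 1L, rowMeans(X)), 1L, sds, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
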