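#' Pairwise absolute-correlation similarity
#'
#' Forms the co-expression similarity matrix `s_ij = |cor(x_i, x_j)|` over all
#' gene pairs of a log2 expression matrix (genes in rows, samples in columns).
#'
#' @param X Numeric matrix, genes x samples, with unique rownames (gene ids)
#'   and at least 3 samples. All values must be finite and every gene must have
#'   nonzero variance across samples.
#' @param max_genes Hard cap on the number of genes; dense n x n matrices above
#'   this size are refused with an error.
#' @return Symmetric numeric matrix in \[0, 1\] with unit diagonal, dimnames =
#'   gene ids.
#' @export
compute_similarity <- function(X, max_genes = 20000L) {
  X <- validate_expression(X)
  if (nrow(X) > max_genes) {
    stop("expression matrix has ", nrow(X), " genes; cap is ", max_genes,
         " (raise max_genes explicitly to override)")
  }
  if (ncol(X) < 3L) stop("at least 3 samples are required to correlate genes")
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ", paste(utils::head(rownames(X)[v == 0], 5L),
                                          collapse = ", "))
  }
  S <- abs(stats::cor(t(X)))
  diag(S) <- 1
  S
}

#' Soft-threshold adjacency
#'
#' Raises the similarity matrix elementwise to the power `beta`, the soft
#' threshold: `a_ij = s_ij^beta`. The diagonal is stored as 1.
#'
#' @param S Symmetric similarity matrix with values in \[0, 1\].
#' @param beta Positive integer soft-thresholding power.
#' @return Adjacency matrix in \[0, 1\], symmetric, unit diagonal.
#' @export
soft_adjacency <- function(S, beta) {
  check_similarity(S)
  if (length(beta) != 1L || is.na(beta) || beta < 1 || beta != as.integer(beta)) {
    stop("beta must be a single positive integer")
  }
  A <- S^beta
  diag(A) <- 1
  A
}

#' Whole-network connectivity
#'
#' The degree of each gene: `k_i = sum_{j != i} a_ij` (diagonal excluded).
#'
#' @param A Symmetric adjacency matrix.
#' @return Named numeric vector of connectivities, one per gene.
#' @export
connectivity <- function(A) {
  check_square_symmetric(A, "adjacency")
  k <- rowSums(A) - diag(A)
  names(k) <- rownames(A)
  k
}

#' Scale-free topology fit
#'
#' Bins connectivity into `n_bins` equal-width bins, computes the empirical
#' degree frequency p(k) and mean k per non-empty bin, and regresses
#' log10 p(k) on log10 mean-k. The regression R-squared is the scale-free fit
#' criterion; the slope estimates minus the power-law exponent.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `r_squared`, `slope`, and `fit_table` (per-bin mean k and
#'   frequency used in the regression).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (any(!is.finite(k)) || any(k < 0)) stop("connectivity must be finite and non-negative")
  if (length(unique(k)) < 2L) stop("degenerate connectivity: zero variance")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  mean_k <- as.vector(tapply(k, bin, mean))
  keep <- !is.na(mean_k) & freq > 0 & mean_k > 0
  if (sum(keep) < 3L) stop("fewer than 3 non-empty bins; cannot fit scale-free model")
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep])
  if (stats::var(lx) == 0) stop("zero variance in binned connectivity")
  fit <- stats::lm(ly ~ lx)
  # an exactly linear log-log relation triggers a perfect-fit warning; fine here
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2L]),
       fit_table = data.frame(mean_k = mean_k[keep], p_k = freq[keep]))
}

#' Choose the soft-thresholding power by the scale-free criterion
#'
#' Scans `beta_grid` in ascending order and returns the smallest power whose
#' scale-free fit R-squared reaches `r2_threshold`. If no power qualifies, the
#' power with maximal R-squared is returned and the result is flagged.
#'
#' @param S Similarity matrix.
#' @param beta_grid Ascending integer powers to scan (default 1:12).
#' @param r2_threshold R-squared required to accept a power (default 0.8).
#' @param n_bins Bins passed to [scale_free_fit()].
#' @return List with `beta`, `r_squared` (at the chosen power), `flagged`
#'   (TRUE when no power reached the threshold) and `scan`, a data frame of
#'   R-squared and slope per candidate power.
#' @export
pick_beta <- function(S, beta_grid = 1:12, r2_threshold = 0.8, n_bins = 10L) {
  check_similarity(S)
  if (length(beta_grid) == 0L) stop("beta_grid must be non-empty")
  if (is.unsorted(beta_grid, strictly = TRUE)) stop("beta_grid must be strictly ascending")
  scan <- lapply(beta_grid, function(b) {
    A <- soft_adjacency(S, b)
    f <- tryCatch(scale_free_fit(connectivity(A), n_bins = n_bins),
                  error = function(e) list(r_squared = NA_real_, slope = NA_real_))
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope)
  })
  scan <- do.call(rbind, scan)
  ok <- which(!is.na(scan$r_squared) & scan$r_squared >= r2_threshold)
  if (length(ok)) {
    i <- ok[1L]
    flagged <- FALSE
  } else {
    i <- which.max(scan$r_squared)
    flagged <- TRUE
  }
  list(beta = scan$beta[i], r_squared = scan$r_squared[i], flagged = flagged,
       scan = scan)
}

#' Topological overlap matrix
#'
#' Unsigned topological overlap: for i != j,
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and k is whole-network connectivity
#' (diagonal excluded); `w_ii = 1`. High overlap means the two genes share
#' their network neighbourhood, not merely each other.
#'
#' @param A Adjacency matrix: symmetric, values in \[0, 1\], unit diagonal.
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
compute_tom <- function(A) {
  check_square_symmetric(A, "adjacency")
  if (any(A < 0) || any(A > 1)) stop("adjacency values must lie in [0, 1]")
  if (any(abs(diag(A) - 1) > 1e-12)) stop("adjacency diagonal must be 1")
  k <- rowSums(A) - 1
  # (A %*% A)_ij counts u = i and u = j; with unit diagonal each contributes a_ij
  L <- A %*% A - 2 * A
  W <- (L + A) / (outer(k, k, pmin) + 1 - A)
  diag(W) <- 1
  W <- (W + t(W)) / 2  # remove numerical asymmetry from the matrix product
  dimnames(W) <- dimnames(A)
  W
}

#' Topological overlap dissimilarity
#'
#' `d_ij = 1 - w_ij`; the distance used for module clustering.
#'
#' @param TOM Topological overlap matrix in \[0, 1\].
#' @return Dissimilarity matrix with zero diagonal.
#' @export
tom_dissimilarity <- function(TOM) {
  check_square_symmetric(TOM, "TOM")
  if (any(TOM < -1e-12) || any(TOM > 1 + 1e-12)) stop("TOM values must lie in [0, 1]")
  D <- 1 - TOM
  diag(D) <- 0
  D
}

#' Build the full co-expression network
#'
#' Convenience wrapper running similarity, soft-threshold selection (or a
#' user-fixed power), adjacency, connectivity, TOM and dissimilarity.
#'
#' @param X Expression matrix, genes x samples.
#' @param beta Fixed soft power; if `NULL` (default) the power is chosen by
#'   [pick_beta()].
#' @param beta_grid,r2_threshold,n_bins Passed to [pick_beta()].
#' @param max_genes Passed to [compute_similarity()].
#' @return Object of class `coexpression_network`: list with `S`, `A`, `beta`,
#'   `beta_flagged`, `beta_scan`, `TOM`, `D`, `k`.
#' @export
build_network <- function(X, beta = NULL, beta_grid = 1:12, r2_threshold = 0.8,
                          n_bins = 10L, max_genes = 20000L) {
  S <- compute_similarity(X, max_genes = max_genes)
  if (is.null(beta)) {
    pb <- pick_beta(S, beta_grid = beta_grid, r2_threshold = r2_threshold,
                    n_bins = n_bins)
    beta <- pb$beta
    flagged <- pb$flagged
    scan <- pb$scan
  } else {
    flagged <- FALSE
    scan <- NULL
  }
  A <- soft_adjacency(S, beta)
  TOM <- compute_tom(A)
  net <- list(S = S, A = A, beta = beta, beta_flagged = flagged,
              beta_scan = scan, TOM = TOM, D = tom_dissimilarity(TOM),
              k = connectivity(A))
  class(net) <- "coexpression_network"
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", nrow(x$A), "genes\n")
  cat("  soft power beta =", x$beta,
      if (isTRUE(x$beta_flagged)) "(scale-free R2 below threshold)" else "", "\n")
  cat("  mean connectivity =", signif(mean(x$k), 4L), "\n")
  invisible(x)
}
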