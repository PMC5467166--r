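#' Detect co-expression modules by average-linkage clustering
#'
#' Clusters the topological overlap dissimilarity with average linkage and cuts
#' the dendrogram. Clusters smaller than `min_module_size` are relabelled 0
#' (background); remaining modules are renumbered 1..n by decreasing size.
#'
#' Because soft thresholding concentrates TOM dissimilarities near 1, a fixed
#' absolute height is rarely meaningful across data sets. The default
#' `cut_height = "auto"` therefore scans the merge-height midpoints and cuts at
#' the lowest height that maximizes the number of clusters reaching
#' `min_module_size`. A numeric `cut_height` in (0, 1) applies a static cut at
#' that height instead.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal (see
#'   [tom_dissimilarity()]).
#' @param min_module_size Minimum module size; smaller clusters become
#'   background (label 0). Default 30.
#' @param cut_height `"auto"` (default) or a number in (0, 1).
#' @return Object of class `module_partition`: list with `labels` (named
#'   integer vector, 0 = background), `n_modules`, `min_module_size`,
#'   `cut_height` (the height actually used) and `tree` (the hclust object).
#' @export
detect_modules <- function(D, min_module_size = 30L, cut_height = "auto") {
  check_square_symmetric(D, "dissimilarity")
  if (nrow(D) < 2L) stop("at least 2 genes are required")
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity diagonal must be 0")
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  if (identical(cut_height, "auto")) {
    hh <- sort(unique(tree$height))
    cand <- if (length(hh) > 1L) utils::head(hh, -1L) + diff(hh) / 2 else hh
    n_big <- vapply(cand, function(cc) {
      sum(table(stats::cutree(tree, h = cc)) >= min_module_size)
    }, numeric(1L))
    h_used <- cand[which.max(n_big)]  # lowest height on ties
  } else {
    if (!is.numeric(cut_height) || length(cut_height) != 1L ||
        cut_height <= 0 || cut_height >= 1) {
      stop("cut_height must be \"auto\" or a number in (0, 1)")
    }
    h_used <- cut_height
  }
  cl <- stats::cutree(tree, h = h_used)
  partition_from_raw_labels(cl, rownames(D), min_module_size,
                            cut_height = h_used, tree = tree)
}

#' Build a module partition from known labels
#'
#' Wraps a gene -> module label vector (0 = background) as a
#' `module_partition`, e.g. to analyse planted truth labels with the same
#' downstream operations as detected modules. Labels are renumbered by
#' decreasing module size and clusters below `min_module_size` become
#' background.
#'
#' @param labels Named integer vector (names = gene ids, 0 = background).
#' @param min_module_size Minimum module size (default 2).
#' @return A `module_partition`.
#' @export
as_module_partition <- function(labels, min_module_size = 2L) {
  if (is.null(names(labels))) stop("labels must be named by gene id")
  nm <- names(labels)
  labels <- as.integer(labels)
  names(labels) <- nm
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be non-negative integers")
  sz <- table(labels[labels > 0L])
  keep <- names(sz)[sz >= min_module_size]
  lab <- integer(length(labels))
  if (length(keep)) {
    ord <- keep[order(sz[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) lab[labels == as.integer(ord[i])] <- i
  }
  names(lab) <- names(labels)
  out <- list(labels = lab, n_modules = length(keep),
              min_module_size = as.integer(min_module_size),
              cut_height = NA_real_, tree = NULL)
  class(out) <- "module_partition"
  out
}

# relabel raw cluster ids: drop small clusters to 0, renumber by decreasing size
partition_from_raw_labels <- function(cl, gene_ids, min_module_size,
                                      cut_height = NA_real_, tree = NULL) {
  sz <- table(cl)
  keep <- names(sz)[sz >= min_module_size]
  lab <- integer(length(cl))
  if (length(keep)) {
    ord <- keep[order(sz[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) lab[cl == as.integer(ord[i])] <- i
  }
  names(lab) <- gene_ids
  out <- list(labels = lab, n_modules = length(keep),
              min_module_size = as.integer(min_module_size),
              cut_height = cut_height, tree = tree)
  class(out) <- "module_partition"
  out
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules,",
      sum(x$labels == 0L), "background genes of", length(x$labels), "\n")
  if (x$n_modules > 0L) {
    print(table(factor(x$labels[x$labels > 0L], levels = seq_len(x$n_modules))))
  }
  invisible(x)
}

#' Refine module membership by eigengene correlation
#'
#' Recomputes each module's eigengene and reassigns every gene to the module
#' whose eigengene it correlates with most strongly (in absolute value),
#' provided that correlation reaches `kme_min`; genes below the threshold
#' become background. Iterates until the labels stabilize. This is the
#' standard kME-based membership cleanup that removes boundary errors left by
#' the dendrogram cut.
#'
#' @param X Expression matrix, genes x samples (same genes as the partition).
#' @param partition A `module_partition`.
#' @param kme_min Minimum absolute gene-eigengene correlation for membership
#'   (default 0.3).
#' @param max_iter Maximum reassignment sweeps (default 5).
#' @return A refined `module_partition` (module numbering follows decreasing
#'   size after the final sweep).
#' @export
refine_modules <- function(X, partition, kme_min = 0.3, max_iter = 5L) {
  X <- validate_expression(X)
  stopifnot(inherits(partition, "module_partition"))
  if (!identical(sort(rownames(X)), sort(names(partition$labels)))) {
    stop("partition genes do not match the expression matrix")
  }
  lab <- partition$labels[rownames(X)]
  min_size <- partition$min_module_size
  Z <- standardize_rows(X)
  for (it in seq_len(max_iter)) {
    mods <- sort(unique(lab[lab > 0L]))
    if (!length(mods)) break
    ME <- vapply(mods, function(m) {
      first_pc(Z[lab == m, , drop = FALSE])$vector
    }, numeric(ncol(Z)))
    kme <- stats::cor(t(Z), ME)
    best <- max.col(abs(kme), ties.method = "first")
    best_val <- abs(kme)[cbind(seq_len(nrow(kme)), best)]
    new_lab <- ifelse(best_val >= kme_min, mods[best], 0L)
    sz <- table(new_lab[new_lab > 0L])
    small <- as.integer(names(sz)[sz < min_size])
    new_lab[new_lab %in% small] <- 0L
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  sz <- table(lab[lab > 0L])
  keep <- names(sz)[sz >= min_size]
  lab2 <- integer(length(lab))
  if (length(keep)) {
    ord <- keep[order(sz[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) lab2[lab == as.integer(ord[i])] <- i
  }
  names(lab2) <- rownames(X)
  out <- list(labels = lab2, n_modules = length(keep),
              min_module_size = min_size,
              cut_height = partition$cut_height, tree = partition$tree)
  class(out) <- "module_partition"
  out
}

# first right singular vector of a rows-standardized genes x samples block,
# sign-aligned to the mean member profile (fallback: first member row)
first_pc <- function(Z) {
  sv <- svd(Z, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  mp <- colMeans(Z)
  al <- sum(mp * v)
  flipped <- FALSE
  if (abs(al) < 1e-12) {       # exact cancellation (e.g. module = {x, -x})
    al <- sum(Z[1L, ] * v)
  }
  if (al < 0) {
    v <- -v
    flipped <- TRUE
  }
  list(vector = v, var_explained = sv$d[1L]^2 / sum(sv$d^2), flipped = flipped)
}

#' Module eigengene
#'
#' The eigengene is the first principal component of the module's expression:
#' member genes are standardized across samples (zero mean, unit SD) and the
#' first right singular vector of the members x samples matrix is returned.
#' The sign is chosen so the eigengene correlates positively with the mean
#' standardized member profile; if that profile cancels exactly (a constructed
#' tie such as a module of `{x, -x}`), the sign is aligned to the first member
#' gene and `sign_flipped` records whether the raw SVD sign was flipped.
#'
#' @param X Expression matrix, genes x samples.
#' @param partition A `module_partition` over the same genes.
#' @param module_id Nonzero module label.
#' @return Object of class `eigengene`: list with `module_id`, `values`
#'   (named per-sample vector, zero mean and unit Euclidean norm),
#'   `variance_explained` and `sign_flipped`.
#' @export
module_eigengene <- function(X, partition, module_id) {
  X <- validate_expression(X)
  stopifnot(inherits(partition, "module_partition"))
  members <- names(partition$labels)[partition$labels == module_id]
  if (length(members) == 0L) stop("module ", module_id, " not present in the partition")
  if (length(members) < 2L) stop("module ", module_id, " is a singleton; eigengene undefined")
  Z <- standardize_rows(X[members, , drop = FALSE])
  pc <- first_pc(Z)
  values <- pc$vector
  names(values) <- colnames(X)
  out <- list(module_id = module_id, values = values,
              variance_explained = pc$var_explained, sign_flipped = pc$flipped)
  class(out) <- "eigengene"
  out
}

#' Eigengenes for every module
#'
#' @param X Expression matrix.
#' @param partition A `module_partition`.
#' @return Named list of [module_eigengene()] results, one per nonzero module.
#' @export
module_eigengenes <- function(X, partition) {
  mods <- sort(unique(partition$labels[partition$labels > 0L]))
  out <- lapply(mods, function(m) module_eigengene(X, partition, m))
  names(out) <- paste0("ME", mods)
  out
}

#' Intramodular connectivity
#'
#' For a gene in module m, `k_in` is the sum of its adjacencies to the other
#' genes of m. Background genes (label 0) get their connectivity relative to
#' the other background genes, flagged as such.
#'
#' @param A Adjacency matrix.
#' @param partition A `module_partition` covering the genes of `A`.
#' @return Data frame with columns `gene_id`, `module`, `k_in`, `background`.
#' @export
intramodular_connectivity <- function(A, partition) {
  check_square_symmetric(A, "adjacency")
  stopifnot(inherits(partition, "module_partition"))
  genes <- rownames(A)
  if (!all(genes %in% names(partition$labels))) {
    stop("partition does not cover all genes of the adjacency matrix")
  }
  lab <- partition$labels[genes]
  k_in <- numeric(length(genes))
  for (m in unique(lab)) {
    idx <- which(lab == m)
    block <- A[idx, idx, drop = FALSE]
    k_in[idx] <- rowSums(block) - diag(block)
  }
  data.frame(gene_id = genes, module = unname(lab), k_in = k_in,
             background = unname(lab) == 0L, row.names = NULL)
}
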