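#' Build a differential-expression signature
#'
#' Per-gene contrast of a binary group on the log2 scale: without covariates,
#' `log2fc` is the difference of group means (group 1 minus group 0) and `p`
#' the two-sample t-test p-value of the group term; with covariates the
#' contrast is the group coefficient of the per-gene linear model
#' `expression ~ group + covariates`.
#'
#' @param X Expression matrix (log2), genes x samples.
#' @param pheno Phenotype data frame with `sample_id` and the group column.
#' @param group_trait Name of the binary grouping column (e.g. `t2d_status`).
#' @param gene_set Optional character vector restricting the signature to a
#'   subset of genes.
#' @param covariates Covariate column names adjusted for in the linear model.
#' @param contrast_label Label stored with the signature.
#' @return Data frame of class `differential_signature`: `gene_id`, `log2fc`,
#'   `p_value`, `direction` (sign of log2fc), with attribute `contrast_label`.
#' @export
build_signature <- function(X, pheno, group_trait = "t2d_status",
                            gene_set = NULL, covariates = character(),
                            contrast_label = group_trait) {
  X <- validate_expression(X)
  if (!group_trait %in% names(pheno)) stop("group trait '", group_trait, "' not found")
  if (!is.null(gene_set)) {
    gene_set <- intersect(gene_set, rownames(X))
    if (!length(gene_set)) stop("no gene_set members found in the expression matrix")
    X <- X[gene_set, , drop = FALSE]
  }
  g <- pheno[[group_trait]][match(colnames(X), pheno$sample_id)]
  if (anyNA(g)) stop("group trait missing for some samples")
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("group trait must be binary")
  g01 <- as.numeric(g == lev[2L])
  if (min(table(g01)) < 3L) stop("each group needs at least 3 samples")

  cov_mat <- NULL
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(pheno))
    if (length(missing_cov)) stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
    cov_mat <- as.matrix(pheno[match(colnames(X), pheno$sample_id), covariates, drop = FALSE])
  }
  design <- cbind(1, g01, cov_mat)
  colnames(design)[1:2] <- c("(Intercept)", "group")

  qr_d <- qr(design)
  coefs <- qr.coef(qr_d, t(X))          # p x genes
  res <- t(X) - design %*% coefs
  df_res <- nrow(design) - qr_d$rank
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  beta <- coefs["group", ]
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  out <- data.frame(gene_id = rownames(X), log2fc = unname(beta),
                    p_value = unname(p),
                    direction = sign(unname(beta)), row.names = NULL)
  attr(out, "contrast_label") <- contrast_label
  class(out) <- c("differential_signature", class(out))
  out
}

sig_check <- function(sig, what = "signature") {
  need <- c("gene_id", "log2fc", "p_value", "direction")
  if (!is.data.frame(sig) || !all(need %in% names(sig))) {
    stop(what, " must be a data frame with columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sig$gene_id)) stop(what, " has duplicated gene ids")
  sig
}

#' Directional concordance between two signatures
#'
#' Over the genes shared by both signatures, restricted to `gene_set` and to
#' genes differentially expressed in `test` at `p < alpha`, counts those whose
#' direction of change matches the reference. Enrichment of concordant-DE
#' genes in the set relative to the background genes is tested by a one-sided
#' Fisher exact test; `fold_enrichment` is the ratio of concordant-DE rates.
#' A binomial test of the concordant fraction against 0.5 is also reported
#' (`p_binomial`).
#'
#' @param reference,test `differential_signature` data frames.
#' @param gene_set Optional set of focal gene ids (default: all shared genes;
#'   the Fisher enrichment is then skipped).
#' @param alpha Nominal DE threshold applied to `test` (default 0.05).
#' @param background Optional character vector of background gene ids
#'   (default: shared genes not in `gene_set`).
#' @return One-row data frame of class `concordance_result`: `n_compared`,
#'   `n_concordant`, `concordant_fraction`, `fold_enrichment`, `p`,
#'   `p_binomial`.
#' @export
directional_concordance <- function(reference, test, gene_set = NULL,
                                    alpha = 0.05, background = NULL) {
  sig_check(reference, "reference")
  sig_check(test, "test")
  shared <- intersect(reference$gene_id, test$gene_id)
  if (!length(shared)) stop("signatures share no genes")
  if (length(shared) < 10L) stop("fewer than 10 shared genes")
  ref_dir <- reference$direction[match(shared, reference$gene_id)]
  tst_dir <- test$direction[match(shared, test$gene_id)]
  tst_p <- test$p_value[match(shared, test$gene_id)]
  de <- tst_p < alpha & tst_dir != 0 & ref_dir != 0
  conc <- de & (tst_dir == ref_dir)

  in_set <- if (is.null(gene_set)) rep(TRUE, length(shared)) else shared %in% gene_set
  if (is.null(background)) bg <- !in_set else bg <- shared %in% background & !in_set

  n_compared <- sum(de & in_set)
  n_concordant <- sum(conc & in_set)
  frac <- if (n_compared > 0) n_concordant / n_compared else NA_real_

  if (any(bg)) {
    rate_set <- sum(conc & in_set) / sum(in_set)
    rate_bg <- sum(conc & bg) / sum(bg)
    tab <- matrix(c(sum(conc & in_set), sum(in_set) - sum(conc & in_set),
                    sum(conc & bg), sum(bg) - sum(conc & bg)), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    fold <- if (rate_bg > 0) rate_set / rate_bg else Inf
  } else {
    p <- NA_real_
    fold <- NA_real_
  }
  p_binom <- if (n_compared > 0) {
    stats::binom.test(n_concordant, n_compared, 0.5, alternative = "greater")$p.value
  } else NA_real_
  out <- data.frame(n_compared = n_compared, n_concordant = n_concordant,
                    concordant_fraction = frac, fold_enrichment = fold,
                    p = p, p_binomial = p_binom, row.names = NULL)
  class(out) <- c("concordance_result", class(out))
  out
}

#' Genes responding consistently to opposite perturbations
#'
#' Returns the genes that change in the reference direction under knockdown
#' and in the opposite direction under overexpression, each at `p < alpha`
#' (the "consistent" responders that implicate the perturbed factor as a
#' regulator of the signature). Enrichment of the observed qualifying count
#' among genes DE in both perturbations is tested one-sided against the null
#' probability 1/4 of drawing that sign pattern with independent random
#' directions (binomial test); `fold_enrichment` is observed over expected.
#'
#' @param reference,kd,oe `differential_signature` data frames (reference
#'   contrast, knockdown, overexpression).
#' @param alpha Per-signature DE threshold (default 0.05).
#' @return List with `genes` (character vector) and `result` (one-row data
#'   frame: `n_qualifying`, `n_both_de`, `fold_enrichment`, `p`).
#' @export
consistent_gene_set <- function(reference, kd, oe, alpha = 0.05) {
  sig_check(reference, "reference")
  sig_check(kd, "kd")
  sig_check(oe, "oe")
  shared <- Reduce(intersect, list(reference$gene_id, kd$gene_id, oe$gene_id))
  if (!length(shared)) stop("the three signatures share no genes")
  rd <- reference$direction[match(shared, reference$gene_id)]
  kdd <- kd$direction[match(shared, kd$gene_id)]
  oed <- oe$direction[match(shared, oe$gene_id)]
  kdp <- kd$p_value[match(shared, kd$gene_id)]
  oep <- oe$p_value[match(shared, oe$gene_id)]
  both_de <- kdp < alpha & oep < alpha & kdd != 0 & oed != 0 & rd != 0
  qual <- both_de & kdd == rd & oed == -rd
  n_q <- sum(qual)
  n_b <- sum(both_de)
  expected <- n_b / 4
  p <- if (n_b > 0) stats::binom.test(n_q, n_b, 0.25, alternative = "greater")$p.value
       else NA_real_
  res <- data.frame(n_qualifying = n_q, n_both_de = n_b,
                    fold_enrichment = if (expected > 0) n_q / expected else NA_real_,
                    p = p, row.names = NULL)
  list(genes = shared[qual], result = res)
}

#' CDF separation between two fold-change samples
#'
#' Two-sample Kolmogorov-Smirnov statistic together with the two empirical
#' CDF polylines, for the standard cumulative-distribution display of a gene
#' set's fold changes against the array background.
#'
#' @param fold_changes_set,fold_changes_background Numeric vectors.
#' @return List with `ks_statistic`, `p`, and `curves` (data frame: `value`,
#'   `cdf`, `group`).
#' @export
cdf_shift <- function(fold_changes_set, fold_changes_background) {
  if (!length(fold_changes_set) || !length(fold_changes_background)) {
    stop("both samples must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(fold_changes_set, fold_changes_background))
  curve_of <- function(x, group) {
    xs <- sort(x)
    data.frame(value = xs, cdf = seq_along(xs) / length(xs), group = group)
  }
  curves <- rbind(curve_of(fold_changes_set, "set"),
                  curve_of(fold_changes_background, "background"))
  list(ks_statistic = unname(ks$statistic), p = ks$p.value, curves = curves)
}

#' Chi-squared test for overlap of two DE gene lists
#'
#' 2x2 chi-squared test (continuity correction off by default) of joint
#' membership in two differentially-expressed gene sets over a common
#' universe. When any expected cell count falls below 1 the test falls back
#' to Fisher's exact test with a message.
#'
#' @param deA,deB Character vectors of DE gene ids.
#' @param universe Character vector, the common gene universe.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `chi2` (NA when the Fisher fallback is used), `p`,
#'   `table`, `method`.
#' @export
de_overlap_chi2 <- function(deA, deB, universe, correct = FALSE) {
  universe <- unique(universe)
  deA <- intersect(unique(deA), universe)
  deB <- intersect(unique(deB), universe)
  inA <- universe %in% deA
  inB <- universe %in% deB
  tab <- table(factor(inA, c(TRUE, FALSE)), factor(inB, c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    message("expected cell count < 1; falling back to Fisher's exact test")
    ft <- stats::fisher.test(tab)
    return(list(chi2 = NA_real_, p = ft$p.value, table = tab, method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab, method = "chisq")
}

#' Remove intensity-dependent variation against a reference
#'
#' Fits a B-spline regression of per-gene mean intensities on reference mean
#' intensities and returns the de-trended values (residuals re-centred on the
#' reference), aligning a sample's intensity scale to the reference platform
#' summary.
#'
#' @param sample_means,reference_means Equal-length per-gene mean vectors.
#' @param spline_df Degrees of freedom of the B-spline basis (default 8,
#'   minimum 3).
#' @return Numeric vector of corrected per-gene values.
#' @export
intensity_detrend <- function(sample_means, reference_means, spline_df = 8L) {
  if (length(sample_means) != length(reference_means)) stop("length mismatch")
  if (spline_df < 3L) stop("spline_df must be at least 3")
  if (length(sample_means) < spline_df + 2L) stop("fewer genes than spline_df + 2")
  fit <- stats::lm(sample_means ~ splines::bs(reference_means, df = spline_df))
  stats::residuals(fit) + reference_means
}

#' Scan studies for excess variance of a gene signature
#'
#' For each study (column of a genes x studies variance matrix), compares the
#' mean variance of the signature genes with `n_resample` random gene sets of
#' the same size; the add-one-smoothed fraction of random sets at least as
#' variable is the per-study p-value.
#'
#' @param variance_matrix Numeric matrix, genes x studies, rownames = gene ids.
#' @param gene_set Character vector of signature gene ids (must index rows).
#' @param n_resample Number of random sets (default 1000, minimum 100).
#' @param seed Integer seed making the resampling reproducible.
#' @return Named numeric vector of p-values, one per study.
#' @export
signature_variance_scan <- function(variance_matrix, gene_set,
                                    n_resample = 1000L, seed = 1L) {
  if (is.null(rownames(variance_matrix))) stop("variance matrix needs gene rownames")
  gene_set <- intersect(gene_set, rownames(variance_matrix))
  if (!length(gene_set)) stop("no signature genes found in the variance matrix")
  if (length(gene_set) > nrow(variance_matrix)) stop("set larger than the gene universe")
  if (n_resample < 100L) stop("n_resample must be at least 100")
  set.seed(seed)
  idx_set <- match(gene_set, rownames(variance_matrix))
  obs <- colMeans(variance_matrix[idx_set, , drop = FALSE])
  draws <- replicate(n_resample, {
    idx <- sample.int(nrow(variance_matrix), length(idx_set))
    colMeans(variance_matrix[idx, , drop = FALSE])
  })
  draws <- matrix(draws, nrow = length(obs))
  p <- (1 + rowSums(draws >= obs)) / (n_resample + 1)
  names(p) <- colnames(variance_matrix)
  p
}
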