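#' Associate a module eigengene with a phenotype trait
#'
#' Fits `trait ~ eigengene + covariates` with logistic regression for binary
#' traits and linear regression otherwise. Insulin-secretion traits (columns
#' whose name starts with `"secretion"`) are log-transformed before fitting,
#' because secretion measures are strictly positive and right-skewed. The
#' returned beta and p-value are the Wald statistics of the eigengene term.
#'
#' By default the eigengene is standardized to unit sample SD before fitting,
#' so the beta is the effect per SD of eigengene and is directly comparable to
#' effect sizes expressed on the latent-factor scale.
#'
#' @param eig An [module_eigengene()] object, or a numeric vector named by
#'   sample id.
#' @param pheno Phenotype data frame with a `sample_id` column.
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("age", "sex", "bmi")`).
#' @param sample_filter Optional predicate: a function taking the phenotype
#'   data frame and returning a logical vector, or a logical vector directly.
#'   Association is computed on the retained samples; at least 10 must remain.
#' @param one_sided If TRUE, the p-value is halved when the estimated beta has
#'   the hypothesized `direction`, and reported as `1 - p/2` otherwise.
#' @param direction `"negative"` or `"positive"`; the hypothesized sign used
#'   when `one_sided = TRUE`.
#' @param standardize Standardize the eigengene to unit SD (default TRUE).
#' @return One-row data frame: `predictor_id`, `trait_name`, `model`, `beta`,
#'   `se`, `p_value`, `n`, `covariates`, `converged`.
#' @export
associate_eigengene_trait <- function(eig, pheno, trait, covariates = character(),
                                      sample_filter = NULL, one_sided = FALSE,
                                      direction = c("negative", "positive"),
                                      standardize = TRUE) {
  direction <- match.arg(direction)
  if (inherits(eig, "eigengene")) {
    predictor_id <- paste0("ME", eig$module_id)
    values <- eig$values
  } else {
    predictor_id <- "eigengene"
    values <- eig
  }
  if (is.null(names(values))) stop("eigengene values must be named by sample id")
  if (!"sample_id" %in% names(pheno)) stop("phenotype table needs a sample_id column")
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not found in the phenotype table")
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov)) stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))

  df <- pheno[match(names(values), pheno$sample_id), , drop = FALSE]
  if (anyNA(df$sample_id)) stop("eigengene samples missing from the phenotype table")
  df$.eig <- unname(values)

  keep <- if (is.null(sample_filter)) rep(TRUE, nrow(df))
          else if (is.function(sample_filter)) sample_filter(df)
          else as.logical(sample_filter)
  keep <- keep & !is.na(df[[trait]])
  for (cv in covariates) keep <- keep & !is.na(df[[cv]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 10L) stop("fewer than 10 samples after filtering")

  y <- df[[trait]]
  if (length(unique(y)) < 2L) stop("trait '", trait, "' is constant in the analyzed samples")
  binary <- length(unique(y)) == 2L
  if (!binary && startsWith(trait, "secretion")) {
    if (any(y <= 0)) stop("secretion trait must be strictly positive for log transform")
    y <- log(y)
  }
  if (standardize) df$.eig <- df$.eig / stats::sd(df$.eig)

  rhs <- paste(c(".eig", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  converged <- TRUE
  if (binary) {
    yb <- as.integer(factor(y)) - 1L
    fml <- stats::as.formula(paste("yb ~", rhs))
    fit <- withCallingHandlers(
      stats::glm(fml, data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged) converged <- FALSE
    co <- summary(fit)$coefficients
    model <- "logistic"
  } else {
    fit <- stats::lm(fml, data = df)
    co <- summary(fit)$coefficients
    model <- "linear"
  }
  beta <- co[".eig", 1L]
  se <- co[".eig", 2L]
  p <- co[".eig", 4L]
  if (one_sided) {
    hypo_sign <- if (direction == "negative") -1 else 1
    p <- if (sign(beta) == hypo_sign) p / 2 else 1 - p / 2
  }
  data.frame(predictor_id = predictor_id, trait_name = trait, model = model,
             beta = unname(beta), se = unname(se), p_value = unname(p),
             n = nrow(df),
             covariates = paste(covariates, collapse = ","),
             converged = converged, row.names = NULL)
}

#' Per-gene correlation with a trait
#'
#' Pearson correlation of each gene's expression with a numeric or binary
#' trait (binary traits are coded 0/1, giving the point-biserial correlation).
#'
#' @param X Expression matrix, genes x samples.
#' @param pheno Phenotype data frame with `sample_id`.
#' @param trait Trait column name.
#' @return Named numeric vector of correlations, one per gene.
#' @export
gene_trait_correlations <- function(X, pheno, trait) {
  X <- validate_expression(X)
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not found")
  y <- pheno[[trait]][match(colnames(X), pheno$sample_id)]
  if (anyNA(y)) stop("trait has missing values for some samples")
  if (!is.numeric(y)) y <- as.integer(factor(y)) - 1L
  if (stats::var(y) == 0) stop("trait '", trait, "' has zero variance")
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(X)[v == 0], 5L), collapse = ", "))
  }
  r <- as.vector(stats::cor(t(X), y))
  names(r) <- rownames(X)
  r
}

#' Correlation between intramodular connectivity and trait association
#'
#' Correlates `k_in` with the absolute gene-trait correlation across genes —
#' the hub analysis asking whether trait-associated genes sit at the module
#' core.
#'
#' @param k_in Connectivity vector over the module genes.
#' @param gene_trait_r Gene-trait correlations for the same genes (signed;
#'   absolute values are used).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r`, `p` and `method`.
#' @export
connectivity_trait_correlation <- function(k_in, gene_trait_r,
                                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(k_in) != length(gene_trait_r)) stop("k_in and gene_trait_r differ in length")
  ct <- suppressWarnings(stats::cor.test(k_in, abs(gene_trait_r), method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}
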