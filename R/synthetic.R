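#' Default planted trait effects
#'
#' Effects of the planted module latent factors on the cohort traits, on the
#' latent-factor (unit SD) scale: log-odds of T2D, HbA1c percentage points,
#' and log insulin secretion per SD of the module factor. The defaults plant
#' all effects on module 1, mirroring a single disease-associated module:
#' the factor lowers secretion and raises T2D risk and HbA1c.
#'
#' @return Named list of named numeric vectors (`trait -> module -> effect`).
#' @export
default_trait_effects <- function() {
  list(t2d_status = c("1" = 1.5),
       hba1c = c("1" = 0.4),
       secretion_glucose = c("1" = -0.5),
       secretion_K = c("1" = -0.4))
}

#' Simulate an islet-style expression cohort with planted modules
#'
#' Generates a log2 expression matrix from a planted factor model: each
#' module m has a per-sample latent factor `e_m ~ N(0, 1)`; a gene g of
#' module m is `x_g = u_g * e_m + noise`, `noise ~ N(0, noise_sd^2)`, with
#' loading `u_g = loading` for ordinary members and `loading + hub_boost` for
#' a labelled subset emulating genes in islet-selective open chromatin
#' (elevated intramodular connectivity). Genes beyond the module blocks are
#' pure noise (module label 0).
#'
#' Traits: T2D status is Bernoulli with logit equal to a baseline plus the
#' planted module effects; HbA1c and log-secretion are linear in the factors
#' plus Gaussian noise; age, sex and BMI are drawn independently (sex is a
#' balanced binary covariate with no planted effect, BMI ~ N(27, 4^2) so
#' median-split analyses are meaningful).
#'
#' The default shape mirrors a 64-donor cohort with about 19 T2D donors and
#' 5 planted modules of 50 genes in 300 genes total.
#'
#' @param n_samples Number of samples (>= 10; default 64).
#' @param n_genes Total genes (default 300).
#' @param module_sizes Planted module sizes (default five modules of 50).
#' @param loading Factor loading of ordinary module genes, in (0, 1\]
#'   (default 0.8).
#' @param hub_boost Extra loading of the labelled subset (default 0.2).
#' @param labelled_frac Fraction of each module labelled as the hub-emulating
#'   set (default 0.2).
#' @param trait_effects See [default_trait_effects()].
#' @param noise_sd Gene-level noise SD (> 0; default 1).
#' @param t2d_base_rate Baseline T2D prevalence entering the logistic
#'   intercept (default 19/64).
#' @param seed Integer seed; fully determines the output.
#' @return List with `expression` (genes x samples matrix), `phenotype`
#'   (data frame), `truth` (module assignment, loadings, labelled set,
#'   trait effects, latent factors, seed).
#' @export
generate_cohort <- function(n_samples = 64L, n_genes = 300L,
                            module_sizes = rep(50L, 5L), loading = 0.8,
                            hub_boost = 0.2, labelled_frac = 0.2,
                            trait_effects = default_trait_effects(),
                            noise_sd = 1, t2d_base_rate = 19 / 64,
                            seed = 1L) {
  if (n_samples < 10L) stop("n_samples must be at least 10")
  if (sum(module_sizes) > n_genes) stop("sum(module_sizes) exceeds n_genes")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (loading <= 0 || loading > 1) stop("loading must be in (0, 1]")
  if (hub_boost < 0) stop("hub_boost must be non-negative")
  set.seed(seed)
  n_mod <- length(module_sizes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  labels <- c(rep(seq_len(n_mod), module_sizes),
              rep(0L, n_genes - sum(module_sizes)))
  names(labels) <- gene_ids

  E <- matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
  X <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples,
              dimnames = list(gene_ids, sample_ids))
  u <- numeric(n_genes)
  names(u) <- gene_ids
  labelled <- character(0L)
  for (m in seq_len(n_mod)) {
    idx <- which(labels == m)
    n_lab <- round(labelled_frac * length(idx))
    lab_idx <- idx[seq_len(n_lab)]
    u[idx] <- loading
    u[lab_idx] <- loading + hub_boost
    labelled <- c(labelled, gene_ids[lab_idx])
    X[idx, ] <- X[idx, ] + outer(u[idx], E[m, ])
  }

  eff <- function(trait) {
    b <- rep(0, n_mod)
    te <- trait_effects[[trait]]
    if (!is.null(te)) b[as.integer(names(te))] <- te
    as.vector(b %*% E)
  }
  logit <- stats::qlogis(t2d_base_rate) + eff("t2d_status")
  t2d <- stats::rbinom(n_samples, 1L, stats::plogis(logit))
  hba1c <- 5.7 + eff("hba1c") + stats::rnorm(n_samples, sd = 0.5)
  secretion_glucose <- exp(2 + eff("secretion_glucose") + stats::rnorm(n_samples, sd = 0.6))
  secretion_K <- exp(1.5 + eff("secretion_K") + stats::rnorm(n_samples, sd = 0.6))
  age <- pmin(pmax(round(stats::rnorm(n_samples, 60, 10)), 30L), 85L)
  sex <- sample(rep_len(c(0L, 1L), n_samples))
  bmi <- round(stats::rnorm(n_samples, 27, 4), 1L)

  pheno <- data.frame(sample_id = sample_ids, t2d_status = t2d, hba1c = hba1c,
                      secretion_glucose = secretion_glucose,
                      secretion_K = secretion_K, age = age, sex = sex,
                      bmi = bmi, row.names = NULL)
  truth <- list(module_assignment = labels, loadings = u,
                labelled_set = labelled, trait_effects = trait_effects,
                factors = E, causal_scenario = NA_character_,
                seed = as.integer(seed))
  list(expression = X, phenotype = pheno, truth = truth)
}

#' Simulate a perturbation signature against a reference contrast
#'
#' Draws a differential-expression signature over the genes of `reference`:
#' each gene receives the reference direction with probability `concordance`
#' and the opposite direction otherwise (`flip` negates the target
#' direction, emulating an opposite-acting perturbation such as
#' overexpression vs knockdown). A fraction `alpha_frac` of genes are made
#' nominally significant (p drawn Uniform(0, 0.05)), the rest get
#' p ~ Uniform(0.05, 1). Fold-change magnitudes are LogNormal(meanlog -0.5,
#' sdlog 0.5).
#'
#' @param reference A `differential_signature` with nonzero directions.
#' @param concordance Probability in \[0, 1\] that a gene keeps the reference
#'   direction.
#' @param flip Negate the assigned directions (default FALSE).
#' @param alpha_frac Fraction of genes with p < 0.05 (default 0.3).
#' @param seed Integer seed.
#' @param contrast_label Label for the generated signature.
#' @return A `differential_signature` data frame.
#' @export
generate_perturbation_signature <- function(reference, concordance,
                                            flip = FALSE, alpha_frac = 0.3,
                                            seed = 1L,
                                            contrast_label = "perturbation") {
  sig_check(reference, "reference")
  if (any(reference$direction == 0)) stop("reference must have a nonzero direction for every gene")
  if (concordance < 0 || concordance > 1) stop("concordance must lie in [0, 1]")
  if (alpha_frac < 0 || alpha_frac > 1) stop("alpha_frac must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(reference)
  keep <- stats::runif(n) < concordance
  dir <- ifelse(keep, reference$direction, -reference$direction)
  if (flip) dir <- -dir
  mag <- stats::rlnorm(n, meanlog = -0.5, sdlog = 0.5)
  sig_idx <- sample.int(n, round(alpha_frac * n))
  p <- stats::runif(n, 0.05, 1)
  p[sig_idx] <- stats::runif(length(sig_idx), 0, 0.05)
  out <- data.frame(gene_id = reference$gene_id, log2fc = dir * mag,
                    p_value = p, direction = dir, row.names = NULL)
  attr(out, "contrast_label") <- contrast_label
  class(out) <- c("differential_signature", class(out))
  out
}

#' Simulate a dose - mediator - outcome triplet
#'
#' Balanced assignment of `n` observations to the dose levels, then:
#' causal scenario, `G = b_LG * L_num + e1`, `T = b_GT * G + e2`;
#' reactive, `T = b_LG * L_num + e1`, `G = b_GT * T + e2`;
#' independent, G and T pure noise. All noise is N(0, noise_sd^2).
#'
#' @param n Number of observations (>= 30).
#' @param scenario `"causal"`, `"reactive"` or `"independent"`.
#' @param dose_levels Numeric dose values (default 0, 0.1, 1 mM).
#' @param b_LG Dose-to-first-variable slope (default 2).
#' @param b_GT Chain second slope (default 0.5).
#' @param noise_sd Noise SD (default 1).
#' @param seed Integer seed.
#' @return Data frame with columns `L` (factor), `L_num`, `G`, `T`.
#' @export
generate_cit_triplet <- function(n = 300L,
                                 scenario = c("causal", "reactive", "independent"),
                                 dose_levels = c(0, 0.1, 1), b_LG = 2,
                                 b_GT = 0.5, noise_sd = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n < 30L) stop("n must be at least 30")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(seed)
  L_num <- rep_len(dose_levels, n)
  e1 <- stats::rnorm(n, sd = noise_sd)
  e2 <- stats::rnorm(n, sd = noise_sd)
  if (scenario == "causal") {
    G <- b_LG * L_num + e1
    T_out <- b_GT * G + e2
  } else if (scenario == "reactive") {
    T_out <- b_LG * L_num + e1
    G <- b_GT * T_out + e2
  } else {
    G <- e1
    T_out <- e2
  }
  data.frame(L = factor(L_num, levels = sort(dose_levels)), L_num = L_num,
             G = G, T = T_out, row.names = NULL)
}
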