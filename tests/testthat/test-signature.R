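sim_groups <- function(n_genes = 50, n_per = 10, shift_gene = "g01", shift = 1,
                       seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%02d", 1:n_genes), sprintf("s%03d", 1:n)))
  grp <- rep(0:1, each = n_per)
  X[shift_gene, grp == 1] <- X[shift_gene, grp == 1] + shift
  ph <- data.frame(sample_id = colnames(X), t2d_status = grp,
                   z = rnorm(n))
  list(X = X, pheno = ph)
}

test_that("signature log2fc is the group mean difference, p the group-term p", {
  d <- sim_groups(shift = 1, seed = 3)
  sig <- build_signature(d$X, d$pheno)
  grp <- d$pheno$t2d_status
  for (g in c("g01", "g07")) {
    expect_equal(sig$log2fc[sig$gene_id == g],
                 mean(d$X[g, grp == 1]) - mean(d$X[g, grp == 0]),
                 tolerance = 1e-12)
    tt <- t.test(d$X[g, grp == 1], d$X[g, grp == 0], var.equal = TRUE)
    expect_equal(sig$p_value[sig$gene_id == g], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(sig$direction, sign(sig$log2fc))
  expect_lt(abs(sig$log2fc[sig$gene_id == "g01"] - 1), 1)
})

test_that("a confounder fully explaining the shift is adjusted away", {
  set.seed(8)
  n <- 40
  grp <- rep(0:1, each = 20)
  conf <- grp + rnorm(n, sd = 0.05)     # near-perfect proxy of the groups
  X <- matrix(rnorm(10 * n), 10, n,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%03d", 1:n)))
  X["g01", ] <- X["g01", ] + 2 * conf   # effect runs through the confounder
  ph <- data.frame(sample_id = colnames(X), t2d_status = grp, conf = conf)
  raw <- build_signature(X, ph)
  adj <- build_signature(X, ph, covariates = "conf")
  expect_gt(abs(raw$log2fc[raw$gene_id == "g01"]), 1.5)
  # oracle: partial regression coefficient
  o <- coef(lm(X["g01", ] ~ grp + conf))["grp"]
  expect_equal(adj$log2fc[adj$gene_id == "g01"], unname(o), tolerance = 1e-10)
  expect_lt(abs(adj$log2fc[adj$gene_id == "g01"]), 0.5)
})

test_that("null signatures have uniform p-values", {
  d <- sim_groups(n_genes = 300, shift = 0, seed = 11)
  sig <- build_signature(d$X, d$pheno)
  expect_gt(suppressWarnings(ks.test(sig$p_value, "punif"))$p.value, 0.01)
})

test_that("directional concordance handles the identity and flip cases", {
  ref <- toy_signature(sprintf("g%03d", 1:200), rep(c(1, -1), 100), rep(0.01, 200))
  same <- directional_concordance(ref, ref, alpha = 1)
  expect_equal(same$concordant_fraction, 1)
  flip <- toy_signature(ref$gene_id, -ref$log2fc, ref$p_value)
  res_flip <- directional_concordance(ref, flip, alpha = 1)
  expect_equal(res_flip$concordant_fraction, 0)

  set.seed(21)
  rand <- toy_signature(ref$gene_id, sample(c(-1, 1), 200, TRUE), rep(0.01, 200))
  res_rand <- directional_concordance(ref, rand, alpha = 1)
  expect_lt(abs(res_rand$concordant_fraction - 0.5), 3 * sqrt(0.25 / 200))
  expect_error(directional_concordance(ref, toy_signature("zz", 1, 0.5)), "share")
})

test_that("concordance enrichment compares the set against the background", {
  set.seed(22)
  genes <- sprintf("g%03d", 1:400)
  ref <- toy_signature(genes, rep(1, 400), rep(0.01, 400))
  # set genes concordant-DE, background genes discordant
  test_dir <- c(rep(1, 100), rep(-1, 300))
  tst <- toy_signature(genes, test_dir, rep(0.01, 400))
  res <- directional_concordance(ref, tst, gene_set = genes[1:100], alpha = 0.05)
  expect_equal(res$concordant_fraction, 1)
  expect_lt(res$p, 1e-10)
  expect_true(is.infinite(res$fold_enrichment) || res$fold_enrichment > 10)
})

test_that("consistent gene set returns exactly the qualifying genes", {
  genes <- sprintf("g%03d", 1:100)
  ref <- toy_signature(genes, rep(c(1, -1), 50), rep(0.01, 100))
  kd <- toy_signature(genes, ref$log2fc, rep(0.001, 100))
  oe <- toy_signature(genes, -ref$log2fc, rep(0.001, 100))
  res <- consistent_gene_set(ref, kd, oe)
  expect_setequal(res$genes, genes)

  same_dir <- consistent_gene_set(ref, kd, kd)
  expect_length(same_dir$genes, 0)

  # constructed 40-gene qualifying subset
  kd2 <- kd; oe2 <- oe
  kd2$p_value[41:100] <- 0.5          # only g001..g040 DE in both
  res2 <- consistent_gene_set(ref, kd2, oe2)
  expect_setequal(res2$genes, genes[1:40])
  # invariant to gene order and to monotone transforms of magnitudes
  shuf <- sample(100)
  res3 <- consistent_gene_set(ref[shuf, ], kd2[rev(shuf), ], oe2)
  expect_setequal(res3$genes, genes[1:40])
  kd3 <- kd2; kd3$log2fc <- kd3$log2fc * 7
  expect_setequal(consistent_gene_set(ref, kd3, oe2)$genes, genes[1:40])
})

test_that("cdf shift equals the brute-force ECDF statistic", {
  x <- rnorm(50)
  expect_equal(cdf_shift(x, x)$ks_statistic, 0)
  expect_equal(cdf_shift(1:10, 101:110)$ks_statistic, 1)
  set.seed(31)
  a <- rnorm(80); b <- rnorm(60, 0.4)
  res <- cdf_shift(a, b)
  expect_equal(res$ks_statistic, oracle_ks(a, b), tolerance = 1e-12)
  # invariance under a common strictly monotone transform
  res2 <- cdf_shift(exp(a), exp(b))
  expect_equal(res2$ks_statistic, res$ks_statistic, tolerance = 1e-12)
  expect_error(cdf_shift(numeric(0), a), "non-empty")
  expect_equal(nrow(res$curves), 140)
})

test_that("DE-overlap chi-squared matches hand computation and falls back to Fisher", {
  # build sets inducing the table [[30,20],[20,130]]
  uni <- sprintf("g%03d", 1:200)
  deA <- uni[1:50]                      # 30 shared, 20 A-only
  deB <- uni[c(1:30, 51:70)]
  res <- de_overlap_chi2(deA, deB, uni)
  O <- matrix(c(30, 20, 20, 130), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / 200
  expect_equal(unname(res$chi2), sum((O - E)^2 / E), tolerance = 1e-10)

  big <- de_overlap_chi2(deA, deA, uni)
  expect_lt(big$p, 1e-6)

  set.seed(41)
  ind <- de_overlap_chi2(sample(uni, 50), sample(uni, 50), uni)
  expect_gt(ind$p, 1e-4)

  expect_message(fb <- de_overlap_chi2(uni[1], uni[1], uni), "Fisher")
  expect_equal(fb$method, "fisher")
})

test_that("intensity detrend removes smooth distortions", {
  set.seed(51)
  ref <- sort(rnorm(300, 8, 2))
  expect_equal(intensity_detrend(ref, ref), ref, tolerance = 1e-8,
               ignore_attr = TRUE)
  distorted <- ref + 0.5 * ref
  corrected <- intensity_detrend(distorted, ref)
  slope <- coef(lm(corrected ~ ref))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-6)
  cubic <- ref + 0.01 * (ref - 8)^3
  corr2 <- intensity_detrend(cubic, ref, spline_df = 8)
  r2 <- summary(lm(I(corr2 - ref) ~ ref))$r.squared
  expect_lt(r2, 0.01)
  expect_error(intensity_detrend(1:5, 1:5, spline_df = 8), "fewer genes")
})

test_that("variance scan flags studies where the signature is extreme", {
  set.seed(61)
  V <- matrix(rexp(500 * 3), 500, 3,
              dimnames = list(sprintf("g%03d", 1:500), paste0("study", 1:3)))
  sig_genes <- sprintf("g%03d", 1:20)
  V[sig_genes, 2] <- max(V[, 2]) + rexp(20)   # top variances in study 2
  p <- signature_variance_scan(V, sig_genes, n_resample = 500, seed = 2)
  expect_equal(unname(p["study2"]), 1 / 501)
  expect_gt(p["study3"], 0.05)
  expect_identical(p, signature_variance_scan(V, sig_genes, n_resample = 500, seed = 2))
  expect_error(signature_variance_scan(V, "nope"), "no signature genes")
  expect_error(signature_variance_scan(V, sig_genes, n_resample = 10), "100")
})
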