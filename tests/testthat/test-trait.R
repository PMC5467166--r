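make_pheno <- function(n, ...) {
  data.frame(sample_id = sprintf("s%03d", 1:n), ...)
}

test_that("a trait equal to the eigengene is recovered with beta 1", {
  set.seed(1)
  e <- rnorm(40)
  names(e) <- sprintf("s%03d", 1:40)
  ph <- make_pheno(40, y = unname(e))
  res <- suppressWarnings(associate_eigengene_trait(e, ph, "y", standardize = FALSE))
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-200)
  expect_equal(res$model, "linear")
})

test_that("type-I error is controlled for an independent trait", {
  rej <- 0L
  for (s in 1:200) {
    set.seed(s)
    e <- rnorm(40); names(e) <- sprintf("s%03d", 1:40)
    ph <- make_pheno(40, y = rnorm(40))
    p <- associate_eigengene_trait(e, ph, "y")$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 200, 0.03)
  expect_lte(rej / 200, 0.08)
})

test_that("planted logistic effect matches an independent maximum-likelihood oracle", {
  set.seed(64)
  n <- 64
  z <- rnorm(n); z <- z / sd(z)
  y <- rbinom(n, 1, plogis(0.2 + 1.5 * z))
  names(z) <- sprintf("s%03d", 1:n)
  ph <- make_pheno(n, status = y)
  res <- associate_eigengene_trait(z, ph, "status", standardize = FALSE)
  expect_equal(res$model, "logistic")
  # independent oracle: direct optimisation of the Bernoulli likelihood
  nll <- function(b) -sum(dbinom(y, 1, plogis(b[1] + b[2] * z), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(res$beta, opt$par[2], tolerance = 1e-4)
  expect_lt(abs(res$beta - 1.5), 3 * res$se)
})

test_that("secretion traits are log-transformed so scale cancels", {
  set.seed(5)
  e <- rnorm(40); names(e) <- sprintf("s%03d", 1:40)
  secretion <- exp(1 + 0.5 * e + rnorm(40, sd = 0.3))
  ph1 <- make_pheno(40, secretion_glucose = secretion)
  ph2 <- make_pheno(40, secretion_glucose = secretion * 1000)
  r1 <- associate_eigengene_trait(e, ph1, "secretion_glucose")
  r2 <- associate_eigengene_trait(e, ph2, "secretion_glucose")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("sample filters, one-sided p and covariates behave as documented", {
  set.seed(9)
  n <- 60
  e <- rnorm(n); names(e) <- sprintf("s%03d", 1:n)
  bmi <- rnorm(n, 27, 4)
  y <- 1 - 0.5 * e + rnorm(n, sd = 0.8)
  ph <- make_pheno(n, y = y, bmi = bmi, age = rnorm(n, 60, 10), sex = rep(0:1, 30))
  above <- function(df) df$bmi > median(df$bmi)
  res <- associate_eigengene_trait(e, ph, "y", sample_filter = above)
  expect_equal(res$n, sum(above(ph)))

  two <- associate_eigengene_trait(e, ph, "y")
  one <- associate_eigengene_trait(e, ph, "y", one_sided = TRUE, direction = "negative")
  expect_equal(one$p_value, two$p_value / 2)
  wrong <- associate_eigengene_trait(e, ph, "y", one_sided = TRUE, direction = "positive")
  expect_equal(wrong$p_value, 1 - two$p_value / 2)

  adj <- associate_eigengene_trait(e, ph, "y", covariates = c("age", "sex", "bmi"))
  expect_equal(adj$covariates, "age,sex,bmi")
  expect_error(associate_eigengene_trait(e, ph, "y", covariates = "smoking"), "smoking")
  expect_error(associate_eigengene_trait(e, ph, "nope"), "nope")
  expect_error(associate_eigengene_trait(e, make_pheno(n, y = rep(1, n)), "y"), "constant")
})

test_that("complete separation is flagged rather than silently estimated", {
  e <- seq(-2, 2, length.out = 20)
  names(e) <- sprintf("s%03d", 1:20)
  ph <- make_pheno(20, status = as.integer(e > 0))
  res <- associate_eigengene_trait(e, ph, "status")
  expect_false(res$converged)
})

test_that("gene-trait correlations match the closed-form oracle", {
  set.seed(13)
  X <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), sprintf("s%03d", 1:30)))
  y <- rnorm(30)
  X["g1", ] <- y
  X["g2", ] <- -y
  ph <- make_pheno(30, y = y)
  r <- gene_trait_correlations(X, ph, "y")
  expect_equal(unname(r["g1"]), 1)
  expect_equal(unname(r["g2"]), -1)
  for (g in paste0("g", 3:5)) {
    num <- sum((X[g, ] - mean(X[g, ])) * (y - mean(y)))
    den <- sqrt(sum((X[g, ] - mean(X[g, ]))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r[g]), num / den, tolerance = 1e-12)
  }
  # binary traits are point-biserial
  phb <- make_pheno(30, grp = rep(c("a", "b"), 15))
  rb <- gene_trait_correlations(X, phb, "grp")
  expect_equal(unname(rb["g3"]),
               cor(X["g3", ], as.integer(phb$grp == "b")), tolerance = 1e-12)
})

test_that("connectivity-trait correlation honours rank invariance", {
  set.seed(17)
  r_abs <- runif(50)
  ident <- connectivity_trait_correlation(r_abs, r_abs, method = "pearson")
  expect_equal(ident$r, 1)
  ident_s <- connectivity_trait_correlation(r_abs, r_abs, method = "spearman")
  expect_equal(ident_s$r, 1)

  k <- exp(5 * r_abs)   # strictly monotone, nonlinear
  sp <- connectivity_trait_correlation(k, r_abs, method = "spearman")
  pe <- connectivity_trait_correlation(k, r_abs, method = "pearson")
  expect_equal(sp$r, 1)
  expect_lt(pe$r, 1)

  ind <- connectivity_trait_correlation(runif(200), runif(200))
  expect_lt(abs(ind$r), 0.2)
  expect_error(connectivity_trait_correlation(1:3, 1:4), "length")
})
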