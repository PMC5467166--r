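test_that("similarity is absolute Pearson correlation with unit diagonal", {
  X <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 4, 3), g3 = c(4, 3, 2, 1))
  colnames(X) <- paste0("s", 1:4)
  S <- compute_similarity(X)
  expect_equal(diag(S), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(S["g1", "g3"], 1)            # perfect anticorrelation
  expect_equal(S["g1", "g2"], 0.8)          # hand covariance: r = 4/5
  expect_equal(S, t(S))
})

test_that("similarity rejects zero-variance genes, tiny cohorts and oversize inputs", {
  X <- rbind(flat = c(1, 1, 1), g2 = c(1, 2, 3))
  colnames(X) <- paste0("s", 1:3)
  expect_error(compute_similarity(X), "flat")
  expect_error(compute_similarity(X[, 1:2, drop = FALSE]), "3 samples")
  X2 <- matrix(rnorm(12), 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_error(compute_similarity(X2, max_genes = 2L), "cap")
})

test_that("soft adjacency is an elementwise power, non-increasing in beta", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(soft_adjacency(S, 1L), S)
  expect_equal(soft_adjacency(S, 5L)["a", "b"], 0.03125)
  expect_error(soft_adjacency(S, 0L), "positive integer")
  set.seed(42)
  A <- random_adjacency(8)
  S8 <- A; diag(S8) <- 1
  prev <- soft_adjacency(S8, 1L)
  for (b in 2:6) {
    cur <- soft_adjacency(S8, b)
    expect_true(all(cur <= prev + 1e-15))
    expect_equal(diag(cur), rep(1, 8), ignore_attr = TRUE)
    prev <- cur
  }
})

test_that("connectivity sums off-diagonal adjacency", {
  A1 <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_equal(unname(connectivity(A1)), rep(3, 4))
  A0 <- diag(4); dimnames(A0) <- dimnames(A1)
  expect_equal(unname(connectivity(A0)), rep(0, 4))
  star <- diag(5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  dimnames(star) <- list(paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(unname(connectivity(star)), c(4, 1, 1, 1, 1))
})

test_that("scale-free fit recovers exact power laws and matches a regression oracle", {
  # k values whose bin frequencies are exactly proportional to k^-1.5:
  # counts 512, 64, 8, 1 at k = 1, 4, 16, 64
  centers <- c(1, 4, 16, 64)
  counts <- c(512, 64, 8, 1)
  k <- rep(centers, counts)
  fit <- scale_free_fit(k, n_bins = 63L)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -1.5, tolerance = 1e-10)

  expect_error(scale_free_fit(rep(2, 50)), "zero variance")

  set.seed(7)
  k2 <- rexp(500, 0.2)
  fit2 <- scale_free_fit(k2, n_bins = 10L)
  # independent bin-and-regress oracle
  br <- seq(min(k2), max(k2), length.out = 11L)
  bin <- cut(k2, br, include.lowest = TRUE)
  pk <- as.vector(table(bin)) / length(k2)
  mk <- as.vector(tapply(k2, bin, mean))
  ok <- !is.na(mk) & pk > 0
  o <- summary(lm(log10(pk[ok]) ~ log10(mk[ok])))
  expect_equal(fit2$r_squared, o$r.squared, tolerance = 1e-10)

  # R^2 invariant to rescaling all connectivities (log-log shift)
  fit3 <- scale_free_fit(3.7 * k2, n_bins = 10L)
  expect_equal(fit3$r_squared, fit2$r_squared, tolerance = 1e-10)
})

test_that("pick_beta selects the smallest qualifying power and matches a grid-scan oracle", {
  set.seed(11)
  X <- generate_cohort(n_samples = 40, n_genes = 120, module_sizes = rep(40, 2),
                       seed = 11)$expression
  S <- compute_similarity(X)
  expect_equal(pick_beta(S, r2_threshold = 0)$beta, 1L)
  g1 <- pick_beta(S, beta_grid = 1L)
  expect_equal(g1$beta, 1L)
  expect_error(pick_beta(S, beta_grid = integer(0)), "non-empty")

  pb <- pick_beta(S, beta_grid = 1:10, r2_threshold = 0.8)
  r2 <- sapply(1:10, function(b) {
    scale_free_fit(connectivity(soft_adjacency(S, b)))$r_squared
  })
  oracle_beta <- if (any(r2 >= 0.8)) min(which(r2 >= 0.8)) else which.max(r2)
  expect_equal(pb$beta, oracle_beta)
  expect_equal(pb$flagged, !any(r2 >= 0.8))
})

test_that("TOM matches hand calculation and brute-force oracle", {
  A <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  W <- compute_tom(A)
  expect_equal(unname(W), matrix(1, 4, 4))  # (2+1)/(3+1-1) = 1 off-diagonal

  A0 <- diag(4); dimnames(A0) <- dimnames(A)
  W0 <- compute_tom(A0)
  expect_equal(unname(W0), diag(4))

  set.seed(3)
  A20 <- random_adjacency(20)
  expect_lt(max(abs(compute_tom(A20) - oracle_tom(A20))), 1e-12)
})

test_that("TOM is symmetric, unit-diagonal and in [0,1] on random inputs", {
  set.seed(9)
  for (n in c(5, 9, 14)) {
    A <- random_adjacency(n)
    W <- compute_tom(A)
    expect_equal(W, t(W))
    expect_equal(diag(W), setNames(rep(1, n), rownames(A)))
    expect_true(all(W >= 0 & W <= 1 + 1e-12))
  }
})

test_that("dissimilarity is the complement of TOM", {
  set.seed(5)
  W <- compute_tom(random_adjacency(6))
  D <- tom_dissimilarity(W)
  expect_equal(unname(D + W), matrix(1, 6, 6))  # elementwise complement
  expect_equal(diag(D), setNames(rep(0, 6), rownames(W)))
})
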