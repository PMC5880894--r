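test_that("variation matrix closed forms", {
  # identical composition in every sample -> all zero
  f <- matrix(rep(c(0.2, 0.3, 0.5), each = 4), nrow = 4)
  expect_equal(variation_matrix(f), matrix(0, 3, 3))

  # proportional taxa -> zero log-ratio variance for that pair
  set.seed(3)
  a <- rexp(10)
  f2 <- cbind(a, 2 * a, rexp(10))
  f2 <- f2 / rowSums(f2)
  expect_equal(variation_matrix(f2)[1, 2], 0, tolerance = 1e-12)

  # 2 taxa, log-ratios (0, 2): sample variance 2
  f3 <- rbind(c(0.5, 0.5), c(exp(2) / (1 + exp(2)), 1 / (1 + exp(2))))
  expect_equal(variation_matrix(f3)[1, 2], 2, tolerance = 1e-12)
  expect_error(variation_matrix(f[1, , drop = FALSE]), "2 samples")
  expect_error(variation_matrix(f - 0.3), "positive")
})

test_that("basis solve matches the 3-taxon closed form exactly", {
  T3 <- matrix(2, 3, 3); diag(T3) <- 0
  res <- basis_correlations(T3)
  expect_equal(res$omega2, c(1, 1, 1))
  expect_equal(res$rho, diag(3))

  # general D: with no exclusions the solve equals the stated closed form
  set.seed(8)
  D <- 6
  M <- matrix(runif(D * D), D); Tm <- (M + t(M)); diag(Tm) <- 0
  res2 <- basis_correlations(Tm, exclusion_threshold = Inf)
  t_i <- rowSums(Tm)
  W <- sum(t_i) / (2 * (D - 1))
  expect_equal(res2$omega2, (t_i - W) / (D - 2), tolerance = 1e-12)
})

test_that("independent taxa give small rho; planted pair is recovered", {
  ct <- lognormal_counts(D = 20, n = 200, seed = 11)
  frac <- t(sweep(ct$counts, 2, colSums(ct$counts), "/"))
  res <- basis_correlations(variation_matrix(frac))
  off <- res$rho[upper.tri(res$rho)]
  expect_lt(max(abs(off), na.rm = TRUE), 0.3)
  expect_lt(stats::median(abs(off), na.rm = TRUE), 0.1)

  ct2 <- lognormal_counts(D = 20, n = 200, rho = 0.95, seed = 12)
  r2 <- sparcc_correlation(ct2, n_resample = 10, seed = 1)
  expect_gt(r2$rho[1, 2], 0.8)
})

test_that("sparcc point estimates: determinism and large-count limit", {
  ct <- lognormal_counts(D = 8, n = 60, depth = 2e5, seed = 21)
  a <- sparcc_correlation(ct, n_resample = 5, seed = 42)
  b <- sparcc_correlation(ct, n_resample = 5, seed = 42)
  expect_identical(a$rho, b$rho)  # bitwise reproducible

  # huge counts: Dirichlet draw concentrates on plug-in fractions
  frac <- t(sweep(ct$counts, 2, colSums(ct$counts), "/"))
  plug <- basis_correlations(variation_matrix(frac))$rho
  one <- sparcc_correlation(ct, n_resample = 1, seed = 7)
  expect_lt(max(abs(one$rho - plug), na.rm = TRUE), 0.02)

  expect_true(all(abs(a$rho) <= 1))
  expect_equal(unname(diag(a$rho)), rep(1, 8))
  expect_equal(a$rho, t(a$rho))
})

test_that("bootstrap pseudo-p-values are valid and detect strong pairs", {
  ct <- lognormal_counts(D = 6, n = 40, rho = 0.95, seed = 31)
  res <- sparcc_correlation(ct, n_resample = 5, seed = 2)
  res <- bootstrap_pvalues(ct, res, B = 60, seed = 3, n_resample = 2)
  p <- res$pvals[upper.tri(res$pvals)]
  expect_true(all(is.na(p) | (p > 0 & p <= 1)))
  expect_lt(res$pvals[1, 2], 0.05)        # exceeds every valid null draw

  net <- build_network(res, r_thresh = 0.6, p_thresh = 0.05)
  expect_true(any(net$source == "t01" & net$target == "t02"))
  # thresholds are strict on both axes
  fake <- res
  fake$rho[1, 3] <- fake$rho[3, 1] <- 0.61
  fake$pvals[1, 3] <- fake$pvals[3, 1] <- 0.02
  net2 <- build_network(fake, r_thresh = 0.6, p_thresh = 0.01)
  expect_false(any(net2$source == "t01" & net2$target == "t03"))
  fake$rho[1, 4] <- fake$rho[4, 1] <- -0.65
  fake$pvals[1, 4] <- fake$pvals[4, 1] <- 0.001
  net3 <- build_network(fake, r_thresh = 0.6, p_thresh = 0.01)
  row <- net3[net3$source == "t01" & net3$target == "t04", ]
  expect_identical(row$sign, "negative")
})
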