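test_that("p-distance closed forms and gap exclusion", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # gap site excluded
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("A-GT", "ACGA"), 1 / 3)
  expect_error(p_distance("--", "AC"), "zero compared")
  expect_error(p_distance("ACG", "AC"), "equal length")
})

test_that("distance matrix is symmetric and matches the ape oracle", {
  ss <- sequence_set(c(a = "ACGT", b = "ACGA", c = "ATGA"))
  d <- pairwise_distance_matrix(ss)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(d["b", "c"], 0.25)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # independent oracle: ape raw distance with pairwise gap deletion
  set.seed(15)
  for (rep in 1:5) {
    n <- 6; L <- 40
    mat <- matrix(sample(c("a", "c", "g", "t", "-"), n * L, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), n, L)
    rownames(mat) <- paste0("s", 1:n)
    seqs <- sequence_set(apply(mat, 1, paste0, collapse = ""))
    ours <- pairwise_distance_matrix(seqs)
    oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                                      pairwise.deletion = TRUE))
    expect_equal(ours, oracle[rownames(ours), colnames(ours)],
                 tolerance = 1e-12)
    # semimetric properties
    expect_true(all(ours >= 0 & ours <= 1))
  }
  expect_equal(pairwise_distance_matrix(
    sequence_set(c(x = "AAAA", y = "AAAA", z = "AAAA"))),
    matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z"))))
})

test_that("co-occurrence decay recovers a planted linear law", {
  set.seed(25)
  n <- 200
  d <- runif(n, 0, 0.05)
  r <- 0.8 - 10 * d + rnorm(n, sd = 0.05)
  pairs <- data.frame(distance = d, statistic = r, significant = TRUE)
  fit <- cooccurrence_decay(pairs)
  expect_identical(fit$degree, 1L)
  # closed-form OLS slope as the oracle
  slope_oracle <- cov(d, r) / var(d)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$slope, -10, tolerance = 0.8)
  expect_lt(fit$p_value, 1e-3)
  expect_identical(unname(fit$df), c(1, n - 2))

  # invariance to row permutation
  perm <- pairs[sample(n), ]
  expect_equal(cooccurrence_decay(perm)$slope, fit$slope)

  # null: no dependence -> slope near zero, p not extreme on average
  set.seed(26)
  ps <- replicate(50, {
    cooccurrence_decay(data.frame(distance = runif(300, 0, 0.05),
                                  statistic = rnorm(300, 0, 0.2),
                                  significant = TRUE))$p_value
  })
  expect_gt(mean(ps < 0.05), 0)  # occasionally significant...
  expect_lt(mean(ps < 0.05), 0.2)  # ...but near the nominal rate

  # perfect line: adjusted R^2 = 1
  perf <- cooccurrence_decay(data.frame(distance = c(0, 0.01, 0.02, 0.03),
                                        statistic = c(1, 0.9, 0.8, 0.7),
                                        significant = TRUE))
  expect_equal(perf$adj_r2, 1)
  expect_error(cooccurrence_decay(data.frame(distance = rep(0.01, 5),
                                             statistic = rnorm(5),
                                             significant = TRUE)),
               "identical")
  expect_error(cooccurrence_decay(data.frame(distance = 1:2 / 100,
                                             statistic = c(1, 2),
                                             significant = TRUE)),
               "3 pairs")
})

test_that("only_significant filters pairs before regression", {
  pairs <- data.frame(distance = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06),
                      statistic = c(1, 2, 3, -50, -60, -70),
                      significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  fit <- cooccurrence_decay(pairs, only_significant = TRUE)
  expect_identical(fit$n_pairs, 3L)
  expect_gt(fit$slope, 0)
  fit_all <- cooccurrence_decay(pairs, only_significant = FALSE)
  expect_identical(fit_all$n_pairs, 6L)
})

test_that("niche decay AIC selects the generating degree", {
  set.seed(35)
  d <- runif(150, 0, 0.05)
  u <- 1 - 80 * d + 1500 * d^2 + rnorm(150, sd = 0.05)   # U-shape
  ufit <- niche_decay(data.frame(distance = d, statistic = u,
                                 significant = TRUE))
  expect_identical(ufit$degree, 2L)

  lin <- 0.9 - 12 * d + rnorm(150, sd = 0.05)
  lfit <- niche_decay(data.frame(distance = d, statistic = lin,
                                 significant = TRUE))
  expect_identical(lfit$degree, 1L)

  # minimal n for degree 2: returned with a df warning
  tiny <- data.frame(distance = c(0.01, 0.02, 0.03, 0.045),
                     statistic = c(1, 0.2, 0.4, 0.9), significant = TRUE)
  expect_warning(tfit <- niche_decay(tiny), "minimal sample size")
  expect_true(tfit$degree %in% c(1L, 2L))
})

test_that("partner divergence regressions behave per partner", {
  set.seed(45)
  focal <- paste0("f", 1:6)
  dmat <- matrix(0, 6, 6, dimnames = list(focal, focal))
  pos <- seq(0, 0.05, length.out = 6)   # taxa on a line
  for (i in 1:6) for (j in 1:6) dmat[i, j] <- abs(pos[i] - pos[j])

  # partner P1: r varies smoothly with position -> |dr| grows with distance
  r <- cbind(P1 = 0.9 - 12 * pos, P2 = rep(0.4, 6))
  rownames(r) <- focal
  res <- partner_divergence(r, dmat)
  expect_gt(res$P1$slope, 0)
  expect_lt(res$P1$p_value, 1e-6)
  # identical correlations -> |dr| constant zero -> slope 0
  expect_equal(res$P2$slope, 0, tolerance = 1e-12)

  # partner with too many missing correlations is skipped with a log entry
  r2 <- cbind(r, P3 = c(0.1, NA, NA, NA, 0.3, NA))
  expect_message(res2 <- partner_divergence(r2, dmat), "P3 skipped")
  expect_named(res2, c("P1", "P2"))

  expect_error(partner_divergence(r[1:2, , drop = FALSE], dmat),
               "insufficient focal pairs")
})
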