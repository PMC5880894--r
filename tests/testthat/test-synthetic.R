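test_that("tree/sequence simulation hits the distance target and is reproducible", {
  a <- simulate_tree_and_sequences(25, 250, 0.05, seed = 5, prefix = "x")
  b <- simulate_tree_and_sequences(25, 250, 0.05, seed = 5, prefix = "x")
  expect_identical(unclass(a$seqs), unclass(b$seqs))
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))

  # realized max distance within +-50% of the target scale
  expect_gt(max(a$dist), 0.025)
  expect_lt(max(a$dist), 0.075)
  expect_false(any(grepl("-", unclass(a$seqs), fixed = TRUE)))

  zero <- simulate_tree_and_sequences(5, 100, 0, seed = 6)
  expect_identical(length(unique(unclass(zero$seqs))), 1L)
  expect_equal(max(zero$dist), 0)
})

test_that("niche coefficient GP follows the kernel limits", {
  d <- as.matrix(dist(seq(0, 0.05, length.out = 10)))
  dimnames(d) <- list(paste0("t", 1:10), paste0("t", 1:10))

  # infinite length scale: all taxa share one coefficient vector
  wide <- simulate_niche_coefficients(d, list(name = "exponential",
                                              ell = 1e9), 4, seed = 1)
  expect_lt(max(abs(sweep(wide$beta, 2, wide$beta[1, ]))), 1e-3)
  expect_equal(min(wide$true_corr), 1, tolerance = 1e-6)

  # vanishing length scale: coefficients essentially independent
  narrow <- simulate_niche_coefficients(d, list(name = "exponential",
                                                ell = 1e-6), 200, seed = 2)
  offs <- cor(t(narrow$beta))[upper.tri(diag(10))]
  expect_lt(max(abs(offs)), 0.3)

  # non-monotone kernel: implied similarity dips then rebounds
  ker <- list(name = "damped_cosine", ell = 0.05, ell2 = 0.1,
              weight = 0.6, period = 0.03)
  K <- kernel_matrix(matrix(c(0, 0.015, 0.015, 0), 2), ker)
  K2 <- kernel_matrix(matrix(c(0, 0.03, 0.03, 0), 2), ker)
  expect_lt(K[1, 2], 0)          # dip below zero at half period
  expect_gt(K2[1, 2], 0.5)       # rebound at the period
  expect_error(kernel_matrix(d, list(name = "nope")), "unknown kernel")
})

test_that("simulated counts: depths exact, softmax uniform limit, bursts", {
  set.seed(55)
  n <- 40; D <- 12
  X <- matrix(rnorm(n * 2), n, dimnames = list(sprintf("s%03d", 1:n),
                                               c("x1", "x2")))
  depths <- sample(2000:4000, n, replace = TRUE)
  sim <- simulate_counts(beta0 = rep(0, D),
                         beta = matrix(0, D, 2), X = X, Lambda = NULL,
                         eta_noise_sd = 0, depths = depths, seed = 3)
  expect_equal(unname(colSums(sim$ct$counts)), depths)
  # flat eta: multinomial uniform; chi-square GoF should not explode
  pooled <- rowSums(sim$ct$counts)
  chi <- sum((pooled - mean(pooled))^2 / mean(pooled))
  expect_lt(chi, qchisq(0.999, D - 1))

  # planted burst reaches the detectability scale
  sim2 <- simulate_counts(beta0 = rep(0, D), beta = matrix(0, D, 2), X = X,
                          eta_noise_sd = 0.15, depths = depths,
                          burst_taxa = 1L, burst = 100,
                          burst_baseline = 2e-4, burst_fraction = 0.05,
                          seed = 4)
  rel <- sim2$ct$counts[1, ] / colSums(sim2$ct$counts)
  expect_gte(max(rel), 0.005)
  expect_true(all(colSums(sim2$ct$counts) == depths))
})

test_that("generate_study is deterministic and structurally complete", {
  cfg <- sim_config(seed = 31, n_samples = 40, n_background = 20,
                    genera = list(gA = list(n_taxa = 8, target_dist = 0.05),
                                  gB = list(n_taxa = 4, target_dist = 0.01)),
                    crt = list(n = 3, baseline = 2e-4, burst = 100,
                               burst_fraction = 0.05))
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$ct$counts, s2$ct$counts)
  expect_identical(unclass(s1$seqs), unclass(s2$seqs))

  expect_identical(nrow(s1$ct$counts), 8L + 4L + 20L)
  expect_identical(ncol(s1$ct$counts), 40L)
  expect_identical(sum(s1$truth$genus_map == "gA"), 8L)
  expect_length(s1$truth$crt_taxa, 3L)
  expect_identical(nrow(s1$env$values), 40L)

  # written bundle: refuses to overwrite, byte-identical on same seed
  dir1 <- tempfile(); dir2 <- tempfile()
  generate_study(cfg, out_dir = dir1)
  expect_error(generate_study(cfg, out_dir = dir1), "exists")
  generate_study(cfg, out_dir = dir2)
  for (f in c("counts.tsv", "env.tsv", "sequences.fasta", "manifest.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # round-trip: the written files load back into the same counts
  back <- read_count_table(file.path(dir1, "counts.tsv"))
  expect_equal(back$counts, s1$ct$counts)
  expect_identical(back$sample_meta$site[1], "littoral")
})

test_that("stage seeds are distinct per stage and below 2^31", {
  s <- vapply(c("tree_gA", "env", "counts", "sparcc", "lvm_gA"),
              function(nm) stage_seed(7, nm), 0L)
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(stage_seed(7, "env"), stage_seed(7, "env"))
  expect_false(stage_seed(7, "env") == stage_seed(8, "env"))
})
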