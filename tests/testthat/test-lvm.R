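make_env <- function(vals) {
  env_matrix(vals)
}

test_that("design matrix standardizes and squares correctly", {
  v <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  X <- build_design(make_env(v))
  expect_equal(unname(X[, "a"]), c(-1, 0, 1))
  expect_equal(unname(X[, "a_sq"]), c(1, 0, 1))
  expect_equal(unname(colMeans(X[, c("a", "b")])), c(0, 0))
  expect_equal(unname(apply(X[, c("a", "b")], 2, sd)), c(1, 1))

  X1 <- build_design(make_env(v), include_quadratic = FALSE)
  expect_identical(ncol(X1), 2L)

  const <- make_env(matrix(c(1, 1, 1, 1, 2, 3), ncol = 2,
                           dimnames = list(paste0("s", 1:3), c("c", "d"))))
  expect_error(build_design(const), "zero-variance covariate: c")

  # listwise missing handling drops incomplete samples
  v2 <- v; v2[2, 1] <- NA
  expect_message(X2 <- build_design(make_env(v2)), "dropped 1 samples")
  expect_identical(nrow(X2), 2L)
})

test_that("prevalence filter keeps >= threshold on raw counts", {
  m <- rbind(hi = c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),     # 0.7
             lo = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0))     # 0.6
  colnames(m) <- sprintf("s%02d", 1:10)
  ct <- count_table(m + matrix(1, 2, 10) * 0)  # keep integers
  clr_m <- nichepart:::clr_matrix(matrix(0, 2, 10,
                                         dimnames = dimnames(m)), "intra-genus")
  f <- prevalence_filter(clr_m, ct, 0.70)
  expect_identical(rownames(f$values), "hi")
  expect_identical(nrow(prevalence_filter(clr_m, ct, 0)$values), 2L)
  expect_error(prevalence_filter(clr_m, ct, 0.99), "no taxa")
})

test_that("d = 0 fit equals per-taxon OLS exactly", {
  set.seed(51)
  n <- 60; p <- 3; D <- 5
  X <- matrix(rnorm(n * p), n, dimnames = list(sprintf("s%02d", 1:n),
                                               paste0("x", 1:p)))
  beta <- matrix(rnorm(D * p), D)
  Y <- t(cbind(1, X) %*% rbind(rnorm(D), t(beta)) + rnorm(n * D, sd = 0.3))
  rownames(Y) <- paste0("t", 1:D)
  fit <- fit_lvm(Y, X, d = 0)
  for (j in 1:D) {
    ols <- stats::lm.fit(cbind(1, X), Y[j, ])
    expect_equal(unname(fit$beta0[j]), unname(ols$coefficients[1]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$beta[j, ]), unname(ols$coefficients[-1]),
                 tolerance = 1e-8)
  }
  # duplicate taxon rows give identical coefficient rows
  Y2 <- rbind(Y, dup = Y[1, ])
  fit2 <- fit_lvm(Y2, X, d = 0)
  expect_equal(unname(fit2$beta["dup", ]), unname(fit2$beta[1, ]))
})

test_that("parameter recovery with latent structure (n=200, D=10, d=2)", {
  set.seed(202)
  n <- 200; p <- 4; D <- 10; d <- 2
  X <- matrix(rnorm(n * p), n, dimnames = list(sprintf("s%03d", 1:n),
                                               paste0("x", 1:p)))
  beta <- matrix(rnorm(D * p, sd = 1), D)
  Lambda <- matrix(rnorm(D * d, sd = 0.5), D)
  Z <- matrix(rnorm(n * d), n)
  Y <- t(X %*% t(beta) + Z %*% t(Lambda) + rnorm(n * D, sd = 0.1))
  rownames(Y) <- paste0("t", 1:D)
  fit <- fit_lvm(Y, X, d = d)
  expect_true(fit$converged)
  rmse <- sqrt(mean((fit$beta - beta)^2))
  expect_lt(rmse, 0.1)
  expect_true(all(fit$sigma2 > 0))
  # loadings identified lower-triangular with positive diagonal
  expect_equal(unname(fit$Lambda[1, 2]), 0, tolerance = 1e-8)
  expect_gte(fit$Lambda[1, 1], 0)
})

test_that("environmental correlations: symmetry, trivial pairs, recovery", {
  set.seed(61)
  n <- 100; p <- 3
  X <- matrix(rnorm(n * p), n, dimnames = list(sprintf("s%03d", 1:n),
                                               paste0("x", 1:p)))
  beta <- rbind(a = c(1, 0.5, -1), b = c(1, 0.5, -1), c = -c(1, 0.5, -1),
                d = c(0.3, -2, 0.8))
  Y <- t(X %*% t(beta) + rnorm(n * 4, sd = 0.05))
  fit <- fit_lvm(Y, X, d = 0)
  ec <- environmental_correlations(fit, B = 0)
  expect_equal(ec$correlation["a", "b"], 1, tolerance = 1e-3)
  expect_equal(ec$correlation["a", "c"], -1, tolerance = 1e-3)
  expect_equal(ec$correlation, t(ec$correlation))
  expect_equal(unname(diag(ec$correlation)), rep(1, 4))

  # bootstrap flags clear pairs as significant
  ec2 <- environmental_correlations(fit, B = 40, seed = 9)
  expect_true(ec2$significant["a", "b"])
  expect_true(ec2$significant["a", "c"])

  # all-zero response: correlation undefined -> NA
  beta0 <- rbind(a = c(1, 1, 1), z = c(0, 0, 0))
  Y0 <- t(X %*% t(beta0)); Y0["z", ] <- 5   # constant series
  fit0 <- fit_lvm(Y0, X, d = 0)
  ec0 <- environmental_correlations(fit0, B = 0)
  expect_true(is.na(ec0$correlation["a", "z"]))
})

test_that("residual correlations follow the loading formula", {
  fit <- structure(list(taxa = c("a", "b", "c"),
                        Lambda = rbind(c(1, 0), c(1, 0), c(0, 1)),
                        sigma2 = c(0, 0, 1), d = 2L), class = "lvm_fit")
  r <- residual_correlations(fit)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], 0)
  expect_equal(unname(diag(r)), rep(1, 3))
  # large residual variance shrinks the correlation toward zero
  fit$sigma2 <- c(1e6, 1e6, 1e6)
  expect_lt(abs(residual_correlations(fit)["a", "b"]), 1e-5)
  fit$d <- 0L; fit$Lambda <- matrix(0, 3, 0)
  expect_equal(residual_correlations(fit), diag(3),
               ignore_attr = TRUE)
})

test_that("univariate best fit selects the right degree by AIC", {
  set.seed(71)
  x <- rnorm(100)
  lin <- univariate_best_fit(2 * x + rnorm(100, sd = 0.1), x)
  expect_identical(lin$degree, 1L)
  expect_equal(unname(lin$coefficients["x"]), 2, tolerance = 0.05)
  expect_lt(lin$p_value, 1e-10)
  quad <- univariate_best_fit(x^2 - x + rnorm(100, sd = 0.1), x)
  expect_identical(quad$degree, 2L)

  # perfect linear fit: RSS = 0 convention selects degree 1, adj R^2 = 1
  perf <- univariate_best_fit(3 * x + 1, x)
  expect_identical(perf$degree, 1L)
  expect_equal(perf$adj_r2, 1)
  expect_error(univariate_best_fit(1:4, 1:4), "n >= 5")
})

test_that("adjusted R^2 matches the textbook formula on a fixture", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1.1, 1.9, 3.2, 3.8, 5.3, 5.7)
  f <- univariate_best_fit(y, x)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  n <- 6; k <- 1
  expect_equal(summary(fit)$adj.r.squared,
               1 - (1 - r2) * (n - 1) / (n - k - 1))
  expect_equal(f$adj_r2, summary(fit)$adj.r.squared, tolerance = 1e-12)
})
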