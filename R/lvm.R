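# Latent variable model of clr abundances on environmental covariates:
# y_ij = beta0_j + x_i' beta_j + z_i' lambda_j + eps_ij with z_i ~ N(0, I_d)
# and eps_ij ~ N(0, sigma_j^2). Estimated by alternating maximization:
# regression given latent scores, then EM factor analysis on the residuals.
# The environmental correlation matrix (correlations between fitted X beta
# vectors) is the niche-similarity statistic downstream.

#' Build a standardized (+ quadratic) design matrix
#'
#' Each covariate is standardized to mean zero and unit (sample) variance;
#' when `include_quadratic` is TRUE the elementwise squares of the
#' standardized columns are appended, named `<var>_sq`. Samples with any
#' missing covariate are dropped (listwise), logged.
#'
#' @param env an [env_matrix()].
#' @param include_quadratic append squared columns (default TRUE).
#' @return numeric matrix, samples x columns, with a `degree` attribute
#'   (1 or 2 per column).
#' @export
build_design <- function(env, include_quadratic = TRUE) {
  vals <- env$values
  keep <- stats::complete.cases(vals)
  if (!all(keep))
    log_msg("design: dropped %d samples with missing covariates", sum(!keep))
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 2L) stop("need at least 2 complete samples")
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  X <- scale(vals)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X <- as.matrix(X)
  degree <- rep(1L, ncol(X))
  if (include_quadratic) {
    Q <- X^2
    colnames(Q) <- paste0(colnames(X), "_sq")
    X <- cbind(X, Q)
    degree <- c(degree, rep(2L, ncol(Q)))
  }
  attr(X, "degree") <- degree
  X
}

#' Filter taxa by prevalence
#'
#' Retains the rows of a clr matrix whose underlying raw counts are nonzero
#' in at least `min_prevalence` of samples.
#'
#' @param clr_mat a `clr_matrix`.
#' @param ct the [count_table()] the clr matrix was derived from.
#' @param min_prevalence presence fraction threshold (default 0.70).
#' @return the filtered `clr_matrix`.
#' @export
prevalence_filter <- function(clr_mat, ct, min_prevalence = 0.70) {
  stopifnot(inherits(clr_mat, "clr_matrix"), is.count_table(ct))
  taxa <- rownames(clr_mat$values)
  samp <- intersect(colnames(clr_mat$values), sample_ids(ct))
  prev <- rowMeans(ct$counts[taxa, samp, drop = FALSE] > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no taxa meet the prevalence threshold")
  clr_matrix(clr_mat$values[keep, , drop = FALSE], clr_mat$grain)
}

# EM update for the factor model R ~ N(0, Lambda Lambda' + Psi), S = cov(R)
fa_em_step <- function(S, Lambda, psi) {
  D <- nrow(S); d <- ncol(Lambda)
  B <- t(Lambda) %*% solve(Lambda %*% t(Lambda) + diag(psi, nrow = D))  # d x D
  G <- diag(d) - B %*% Lambda + B %*% S %*% t(B)
  Lambda_new <- S %*% t(B) %*% solve(G)
  psi_new <- pmax(diag(S - Lambda_new %*% B %*% S), 1e-8)
  list(Lambda = Lambda_new, psi = psi_new)
}

fa_loglik <- function(S, n, Lambda, psi) {
  Sigma <- Lambda %*% t(Lambda) + diag(psi, nrow = nrow(S))
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  -0.5 * n * (nrow(S) * log(2 * pi) + as.numeric(ld) +
                sum(diag(solve(Sigma, S))))
}

#' Fit the latent variable model
#'
#' Maximum likelihood in two exact blocks: because every taxon shares the
#' same design matrix, the ML regression coefficients equal per-taxon
#' ordinary least squares regardless of the residual covariance, so the
#' regression part is solved directly; the latent part is then an EM factor
#' analysis of the residual covariance (monotone in the marginal
#' log-likelihood), with posterior-mean latent scores. With `d = 0` the fit
#' is exactly per-taxon OLS.
#'
#' @param Y a `clr_matrix` (taxa x samples) or numeric matrix in that
#'   orientation.
#' @param X design matrix from [build_design()] (samples x columns); sample
#'   sets are intersected by name when both are named.
#' @param d number of latent variables (default 2).
#' @param seed RNG seed (the fit is deterministic; kept for interface
#'   stability).
#' @param max_iter,tol outer-loop control.
#' @return an object of class `lvm_fit`: `beta0`, `beta` (taxa x columns),
#'   `Lambda` (taxa x d, rotated lower-triangular with positive diagonal),
#'   `sigma2`, `scores` (samples x d), `loglik`, `converged`, `X`, `taxa`.
#' @export
fit_lvm <- function(Y, X, d = 2, seed = NULL, max_iter = 500, tol = 1e-6) {
  if (inherits(Y, "clr_matrix")) Y <- Y$values
  Ymat <- t(Y)                                   # samples x taxa
  if (!is.null(rownames(Ymat)) && !is.null(rownames(X))) {
    shared <- intersect(rownames(Ymat), rownames(X))
    if (!length(shared)) stop("no shared samples between response and design")
    Ymat <- Ymat[shared, , drop = FALSE]
    X <- X[shared, , drop = FALSE]
  }
  n <- nrow(Ymat); D <- ncol(Ymat); p <- ncol(X)
  if (n <= p + d) stop("need more samples than design columns + latent dims")
  Xfull <- cbind(`(intercept)` = 1, X)

  ols <- function(resp) {
    fit <- stats::lm.fit(Xfull, resp)
    coefs <- as.matrix(fit$coefficients)
    list(beta0 = coefs[1, ], beta = t(coefs[-1, , drop = FALSE]),
         resid = as.matrix(fit$residuals))
  }

  reg <- ols(Ymat)
  if (d == 0) {
    sigma2 <- colMeans(reg$resid^2)
    return(structure(list(beta0 = reg$beta0, beta = reg$beta,
                          Lambda = matrix(0, D, 0), sigma2 = sigma2,
                          scores = matrix(0, n, 0), d = 0L,
                          loglik = sum(stats::dnorm(reg$resid,
                                                    sd = rep(sqrt(sigma2),
                                                             each = n),
                                                    log = TRUE)),
                          converged = TRUE, X = X, Y = Ymat,
                          taxa = colnames(Ymat)),
                     class = "lvm_fit"))
  }

  # regression block is exact; factor-analyze the residual covariance
  R <- reg$resid
  S <- crossprod(R) / n
  eg <- eigen(S, symmetric = TRUE)
  Lambda <- eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(d)], 1e-8)), d)
  psi <- pmax(diag(S) - rowSums(Lambda^2), 1e-8)

  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    up <- fa_em_step(S, Lambda, psi)
    Lambda <- up$Lambda; psi <- up$psi
    ll <- fa_loglik(S, n, Lambda, psi)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("LVM did not converge in ", max_iter, " iterations")
  B <- t(Lambda) %*% solve(Lambda %*% t(Lambda) + diag(psi, nrow = D))
  Z <- R %*% t(B)

  # identify loadings: rotate to lower-triangular with positive diagonal
  qrr <- qr(t(Lambda[seq_len(d), , drop = FALSE]))
  Rot <- qr.Q(qrr)
  Lambda <- Lambda %*% Rot
  Z <- Z %*% Rot
  sgn <- sign(diag(as.matrix(Lambda[seq_len(d), seq_len(d)])))
  sgn[sgn == 0] <- 1
  Lambda <- sweep(Lambda, 2L, sgn, "*")
  Z <- sweep(Z, 2L, sgn, "*")

  structure(list(beta0 = reg$beta0, beta = reg$beta, Lambda = Lambda,
                 sigma2 = psi, scores = Z, d = as.integer(d),
                 loglik = ll, converged = converged, X = X, Y = Ymat,
                 taxa = colnames(Ymat)),
            class = "lvm_fit")
}

#' @export
print.lvm_fit <- function(x, ...) {
  cat(sprintf("<lvm_fit> %d taxa, %d design columns, d=%d, loglik %.2f%s\n",
              length(x$taxa), ncol(x$beta), x$d, x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Environmental (niche-similarity) correlation matrix
#'
#' For every taxon pair, the Pearson correlation across samples of the
#' fitted environmental responses `X beta_j` and `X beta_k` (intercepts
#' excluded). Significance is assessed by a nonparametric bootstrap over
#' samples: the model is refit on each resample and a pair is significant
#' when the central `level` percentile interval of its correlation excludes
#' zero.
#'
#' @param fit an `lvm_fit`.
#' @param X design matrix (default: the one stored in the fit).
#' @param B bootstrap refits (default 100; 0 skips significance).
#' @param level interval level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list with `correlation` (taxa x taxa), `lower`, `upper`,
#'   `significant` (logical, NA when not assessed or undefined).
#' @export
environmental_correlations <- function(fit, X = fit$X, B = 100,
                                       level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "lvm_fit"))
  eta_cor <- function(beta, X) {
    eta <- X %*% t(beta)                       # samples x taxa
    sds <- apply(eta, 2L, stats::sd)
    flat <- sds < 1e-10 * max(sds, 1e-300)     # numerically constant response
    r <- suppressWarnings(stats::cor(eta))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
    diag(r) <- 1
    r
  }
  point <- eta_cor(fit$beta, X)
  dimnames(point) <- list(fit$taxa, fit$taxa)
  lower <- upper <- signif_mat <- array(NA_real_, dim(point),
                                        dimnames = dimnames(point))
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(X)
    D <- length(fit$taxa)
    boots <- array(NA_real_, c(D, D, B))
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      Yb <- t(fit$Y[idx, , drop = FALSE])      # refit on resampled rows
      Xb <- fit$X[idx, , drop = FALSE]
      rownames(Yb) <- NULL                     # duplicated sample ids are fine
      rownames(Xb) <- NULL
      fb <- tryCatch(
        fit_lvm(Yb, Xb, d = fit$d, max_iter = 50, tol = 1e-5),
        error = function(e) NULL)
      if (!is.null(fb)) boots[, , b] <- eta_cor(fb$beta, fb$X)
    }
    alpha <- (1 - level) / 2
    lower <- apply(boots, c(1, 2), stats::quantile, probs = alpha,
                   na.rm = TRUE)
    upper <- apply(boots, c(1, 2), stats::quantile, probs = 1 - alpha,
                   na.rm = TRUE)
    signif_mat <- (lower > 0) | (upper < 0)
    diag(signif_mat) <- NA
    dimnames(lower) <- dimnames(upper) <- dimnames(signif_mat) <-
      dimnames(point)
  }
  list(correlation = point, lower = lower, upper = upper,
       significant = signif_mat)
}

#' Residual (latent-factor) correlation matrix
#'
#' `rho_jk = lambda_j . lambda_k / sqrt((|lambda_j|^2 + sigma_j^2)
#' (|lambda_k|^2 + sigma_k^2))`, with unit diagonal by convention; with
#' `d = 0` the off-diagonal is zero.
#'
#' @param fit an `lvm_fit`.
#' @return taxa x taxa correlation matrix.
#' @export
residual_correlations <- function(fit) {
  stopifnot(inherits(fit, "lvm_fit"))
  D <- length(fit$taxa)
  if (fit$d == 0) {
    r <- diag(D)
    dimnames(r) <- list(fit$taxa, fit$taxa)
    return(r)
  }
  cross <- fit$Lambda %*% t(fit$Lambda)
  tot <- sqrt(rowSums(fit$Lambda^2) + fit$sigma2)
  r <- cross / outer(tot, tot)
  diag(r) <- 1
  dimnames(r) <- list(fit$taxa, fit$taxa)
  r
}

#' AIC-selected univariate polynomial fit
#'
#' Fits degree-1 and degree-2 least-squares polynomials of one response on
#' one covariate and reports the lower-AIC model with its adjusted R^2 and
#' overall F test. `AIC = n log(RSS / n) + 2k` with `k` counting the
#' coefficients plus the variance. A perfect linear fit (RSS = 0) selects
#' degree 1 by convention.
#'
#' @param y response vector (one taxon's clr series).
#' @param x covariate vector.
#' @return list with `degree`, `coefficients`, `aic` (both degrees),
#'   `adj_r2`, `f_stat`, `p_value`.
#' @export
univariate_best_fit <- function(y, x) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 5)
  fit1 <- stats::lm(y ~ x)
  fit2 <- stats::lm(y ~ x + I(x^2))
  aic_of <- function(fit, k) {
    rss <- sum(stats::resid(fit)^2)
    if (rss <= 0) -Inf else n * log(rss / n) + 2 * k
  }
  aic <- c(degree1 = aic_of(fit1, 3), degree2 = aic_of(fit2, 4))
  degree <- if (aic["degree1"] <= aic["degree2"]) 1L else 2L
  best <- if (degree == 1L) fit1 else fit2
  sm <- summary(best)
  fstat <- sm$fstatistic
  list(degree = degree,
       coefficients = stats::coef(best),
       aic = aic,
       adj_r2 = sm$adj.r.squared,
       f_stat = unname(fstat["value"]),
       df = unname(fstat[c("numdf", "dendf")]),
       p_value = if (is.null(fstat)) NA_real_ else
         unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                          lower.tail = FALSE)))
}
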