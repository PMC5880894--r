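# SparCC-style inference of correlations among unobserved absolute ("basis")
# abundances from compositional counts: log-ratio variance matrix, sparse
# basis solve with iterative strong-pair exclusion, Dirichlet fraction
# resampling for point estimates, and permutation bootstrap pseudo-p-values.

#' Log-ratio variation matrix
#'
#' `t_ij = var_samples(log(f_i / f_j))` for strictly positive fractions.
#'
#' @param fractions samples x taxa matrix of strictly positive fractions.
#' @return symmetric taxa x taxa matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  if (nrow(fractions) < 2L) stop("need at least 2 samples")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  L <- log(fractions)
  C <- stats::cov(L)               # n-1 denominator
  v <- diag(C)
  T <- outer(v, v, "+") - 2 * C
  T[T < 0] <- 0                    # numerical guard
  diag(T) <- 0
  (T + t(T)) / 2
}

#' Basis variances and correlations under the sparsity assumption
#'
#' Solves the linear system implied by assuming most taxa are uncorrelated:
#' with no exclusions, `omega_i^2 = (t_i - W) / (D - 2)` where
#' `t_i = sum_j t_ij` and `W = sum_i t_i / (2 (D - 1))`; correlations follow
#' as `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`. The
#' single pair with the largest `|rho|` above `exclusion_threshold` is then
#' removed from the system and the solve repeated, up to `max_exclusions`
#' rounds.
#'
#' @param T variation matrix from [variation_matrix()].
#' @param exclusion_threshold exclude pairs with `|rho|` above this
#'   (default 0.1).
#' @param max_exclusions maximum exclusion rounds (default 10).
#' @return list with `omega2` (basis variances), `rho` (correlations, clipped
#'   to `[-1, 1]`), and `excluded` (m x 2 matrix of excluded pair indices).
#' @export
basis_correlations <- function(T, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  D <- nrow(T)
  if (D < 3L) stop("need at least 3 taxa for the basis solve")
  M0 <- matrix(1, D, D) + diag(D - 2, D)
  excluded <- matrix(integer(0), ncol = 2)
  Texc <- T
  M <- M0
  solve_once <- function(M, Texc) {
    t_i <- rowSums(Texc)
    omega2 <- as.numeric(solve(M, t_i))
    bad <- omega2 <= 0
    omega <- sqrt(pmax(omega2, 0))
    rho <- (outer(omega2, omega2, "+") - T) /
      (2 * outer(omega, omega))
    rho[bad, ] <- NA_real_
    rho[, bad] <- NA_real_
    if (any(bad))
      log_msg("non-positive basis variance for %d taxa; correlations set NA",
              sum(bad))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    list(omega2 = omega2, rho = rho)
  }
  fit <- solve_once(M, Texc)
  for (k in seq_len(max_exclusions)) {
    r <- fit$rho
    diag(r) <- 0
    r[is.na(r)] <- 0
    if (nrow(excluded)) r[excluded] <- 0
    amax <- max(abs(r))
    if (amax <= exclusion_threshold) break
    ij <- which(abs(r) == amax, arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    excluded <- rbind(excluded, c(i, j), c(j, i))
    Texc[i, j] <- Texc[j, i] <- 0
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    fit <- solve_once(M, Texc)
  }
  list(omega2 = fit$omega2, rho = fit$rho, excluded = excluded)
}

# one Dirichlet draw of fractions per sample: rows of `counts` are taxa
dirichlet_fractions <- function(counts) {
  D <- nrow(counts); n <- ncol(counts)
  g <- matrix(stats::rgamma(D * n, shape = counts + 1), nrow = D)
  t(sweep(g, 2L, colSums(g), "/"))   # samples x taxa
}

#' SparCC correlation point estimates
#'
#' For each of `n_resample` rounds, per-sample fractions are drawn from
#' `Dirichlet(counts + 1)`, the basis correlations are solved, and the point
#' estimate is the elementwise median across rounds.
#'
#' @param ct a [count_table()] with at least 3 taxa.
#' @param n_resample Dirichlet resampling rounds (default 20).
#' @param seed RNG seed for reproducibility.
#' @param exclusion_threshold,max_exclusions passed to
#'   [basis_correlations()].
#' @return object of class `sparcc_result` with `taxon_ids`, `rho`,
#'   `n_resample`, and (after [bootstrap_pvalues()]) `pvals`.
#' @export
sparcc_correlation <- function(ct, n_resample = 20, seed = NULL,
                               exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  stopifnot(is.count_table(ct))
  if (!is.null(seed)) set.seed(seed)
  D <- nrow(ct$counts)
  if (D < 3L) stop("need at least 3 taxa")
  rhos <- vapply(seq_len(n_resample), function(b) {
    f <- dirichlet_fractions(ct$counts)
    basis_correlations(variation_matrix(f), exclusion_threshold,
                       max_exclusions)$rho
  }, matrix(0, D, D))
  rho <- apply(rhos, c(1, 2), stats::median, na.rm = TRUE)
  dimnames(rho) <- list(taxon_ids(ct), taxon_ids(ct))
  diag(rho) <- 1
  structure(list(taxon_ids = taxon_ids(ct), rho = rho, pvals = NULL,
                 n_resample = n_resample, n_bootstrap = 0L),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat(sprintf("<sparcc_result> %d taxa, %d resamples, %d bootstraps\n",
              length(x$taxon_ids), x$n_resample, x$n_bootstrap))
  invisible(x)
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' The null is built by independently permuting each taxon's counts across
#' samples (association broken, marginals preserved); correlations are
#' recomputed per bootstrap and the two-sided pseudo-p is
#' `(1 + #{|rho_b| >= |rho_obs|}) / (B + 1)`, never zero.
#'
#' @param ct the [count_table()] used for the observed estimate.
#' @param res a `sparcc_result` from [sparcc_correlation()].
#' @param B bootstrap rounds (default 500).
#' @param seed RNG seed.
#' @param n_resample Dirichlet rounds per bootstrap (default: as in `res`).
#' @return `res` with the `pvals` matrix filled in (entries in (0, 1]).
#' @export
bootstrap_pvalues <- function(ct, res, B = 500, seed = NULL,
                              n_resample = res$n_resample) {
  stopifnot(inherits(res, "sparcc_result"), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- nrow(ct$counts); n <- ncol(ct$counts)
  obs <- abs(res$rho)
  exceed <- matrix(0, D, D)
  valid <- matrix(0, D, D)   # null draws can be NA (non-positive variances)
  for (b in seq_len(B)) {
    perm <- ct$counts
    for (i in seq_len(D)) perm[i, ] <- perm[i, sample.int(n)]
    ctb <- count_table(perm)
    rb <- sparcc_correlation(ctb, n_resample = n_resample)$rho
    ok <- !is.na(rb)
    exceed <- exceed + (ok & abs(rb) >= obs)
    valid <- valid + ok
  }
  p <- (1 + exceed) / (valid + 1)
  p[valid == 0] <- NA_real_
  diag(p) <- 1
  dimnames(p) <- dimnames(res$rho)
  res$pvals <- p
  res$n_bootstrap <- B
  res
}

#' Thresholded co-occurrence edge list
#'
#' Keeps taxon pairs with `|rho| > r_thresh` and `p < p_thresh`.
#'
#' @param res a `sparcc_result` with p-values.
#' @param r_thresh correlation magnitude threshold (default 0.6).
#' @param p_thresh significance threshold (default 0.01).
#' @return data.frame with `source`, `target`, `rho`, `p`, `sign`.
#' @export
build_network <- function(res, r_thresh = 0.6, p_thresh = 0.01) {
  stopifnot(inherits(res, "sparcc_result"))
  if (is.null(res$pvals)) stop("run bootstrap_pvalues() first")
  D <- length(res$taxon_ids)
  pairs <- which(upper.tri(res$rho), arr.ind = TRUE)
  rho <- res$rho[pairs]
  p <- res$pvals[pairs]
  keep <- !is.na(rho) & abs(rho) > r_thresh & p < p_thresh
  data.frame(source = res$taxon_ids[pairs[keep, 1]],
             target = res$taxon_ids[pairs[keep, 2]],
             rho = rho[keep], p = p[keep],
             sign = ifelse(rho[keep] >= 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}
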