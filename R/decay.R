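# Genetic distance (p-distance) and decay analyses: how co-occurrence and
# per-dimension niche similarity change with pairwise genetic distance.

#' p-distance between two aligned sequences
#'
#' Proportion of compared sites at which the sequences differ; sites where
#' either sequence carries a gap are excluded from the comparison.
#'
#' @param a,b aligned sequences of equal length (strings over `A,C,G,T,-`).
#' @return proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(sa) != length(sb)) stop("sequences must have equal length")
  use <- sa != "-" & sb != "-"
  if (!any(use)) stop("zero compared sites (gaps everywhere)")
  sum(sa[use] != sb[use]) / sum(use)
}

#' Pairwise p-distance matrix
#'
#' @param seqs a [sequence_set()] with at least 2 sequences.
#' @return symmetric matrix of p-distances with zero diagonal.
#' @export
pairwise_distance_matrix <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]])
    }
  }
  d
}

# shared polynomial decay regression; AIC = n log(RSS/n) + 2k as in the
# univariate environmental fits, for comparability
decay_fit <- function(stat, dist, max_degree = 1) {
  n <- length(stat)
  stopifnot(length(dist) == n)
  if (stats::sd(dist) == 0) stop("all distances identical")
  if (n < max_degree + 2) stop("too few pairs for the requested degree")
  fits <- list(stats::lm(stat ~ dist))
  if (max_degree >= 2) fits[[2]] <- stats::lm(stat ~ dist + I(dist^2))
  aic <- vapply(seq_along(fits), function(k) {
    rss <- sum(stats::resid(fits[[k]])^2)
    if (rss <= 0) -Inf else n * log(rss / n) + 2 * (k + 2)
  }, 0)
  degree <- which.min(aic)
  best <- fits[[degree]]
  sm <- summary(best)
  fstat <- sm$fstatistic
  if (n <= degree + 2)
    warning("decay regression at minimal sample size; df2 = ",
            n - degree - 1)
  list(degree = degree,
       coefficients = stats::coef(best),
       slope = unname(stats::coef(best)["dist"]),
       aic = aic,
       adj_r2 = sm$adj.r.squared,
       f_stat = if (is.null(fstat)) NA_real_ else unname(fstat["value"]),
       df = if (is.null(fstat)) c(NA, NA) else
         unname(fstat[c("numdf", "dendf")]),
       p_value = if (is.null(fstat)) NA_real_ else
         unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                          lower.tail = FALSE)),
       n_pairs = n)
}

# assemble per-pair records from symmetric statistic/distance matrices
pair_records <- function(stat_mat, dist_mat, signif_mat = NULL) {
  taxa <- rownames(dist_mat)
  idx <- which(upper.tri(dist_mat), arr.ind = TRUE)
  out <- data.frame(taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
                    distance = dist_mat[idx],
                    statistic = stat_mat[taxa, taxa][idx],
                    stringsAsFactors = FALSE)
  out$significant <- if (is.null(signif_mat)) TRUE
                     else as.logical(signif_mat[taxa, taxa][idx])
  out
}

#' Co-occurrence decay with genetic distance
#'
#' Degree-1 least squares of pairwise co-occurrence correlations on
#' p-distance, over the pairs whose correlation is significant (when a
#' significance matrix or flag is supplied).
#'
#' @param stat_mat symmetric matrix of pairwise correlations (e.g. SparCC
#'   rho), or a data.frame of pair records with columns `distance`,
#'   `statistic`, `significant`.
#' @param dist_mat symmetric p-distance matrix over the same taxa (ignored
#'   when `stat_mat` is a pair data.frame).
#' @param signif_mat optional logical matrix marking significant pairs.
#' @param only_significant restrict to significant pairs (default TRUE).
#' @return a decay regression: list with `degree`, `slope`, `f_stat`, `df`,
#'   `p_value`, `adj_r2`, `n_pairs`, plus the `pairs` used.
#' @export
cooccurrence_decay <- function(stat_mat, dist_mat = NULL, signif_mat = NULL,
                               only_significant = TRUE) {
  pairs <- if (is.data.frame(stat_mat)) stat_mat
           else pair_records(stat_mat, dist_mat, signif_mat)
  if (only_significant) pairs <- pairs[pairs$significant %in% TRUE, ]
  pairs <- pairs[is.finite(pairs$statistic), ]
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  res <- decay_fit(pairs$statistic, pairs$distance, max_degree = 1)
  res$pairs <- pairs
  res
}

#' Niche-similarity decay for one niche dimension
#'
#' Fits degree-1 and degree-2 polynomials of pairwise co-response on
#' p-distance and selects by AIC, mirroring the univariate environmental
#' model selection.
#'
#' @inheritParams cooccurrence_decay
#' @param max_degree highest polynomial degree to consider (default 2).
#' @return a decay regression (see [cooccurrence_decay()]) with the selected
#'   `degree`.
#' @export
niche_decay <- function(stat_mat, dist_mat = NULL, signif_mat = NULL,
                        only_significant = TRUE, max_degree = 2) {
  pairs <- if (is.data.frame(stat_mat)) stat_mat
           else pair_records(stat_mat, dist_mat, signif_mat)
  if (only_significant) pairs <- pairs[pairs$significant %in% TRUE, ]
  pairs <- pairs[is.finite(pairs$statistic), ]
  if (nrow(pairs) < max_degree + 2) stop("too few pairs")
  res <- decay_fit(pairs$statistic, pairs$distance, max_degree = max_degree)
  res$pairs <- pairs
  res
}

#' Partner-interaction divergence vs genetic distance
#'
#' For each partner taxon P and each unordered focal pair (A, B), regresses
#' `|r_AP - r_BP|` on the genetic distance between A and B (degree 1).
#' Partners with missing correlations for more than half of the focal taxa
#' are skipped with a log entry.
#'
#' @param r matrix of correlations, focal taxa (rows) x partner taxa
#'   (columns).
#' @param dist_mat symmetric p-distance matrix over the focal taxa.
#' @return named list of decay regressions, one per retained partner.
#' @export
partner_divergence <- function(r, dist_mat) {
  focal <- rownames(r)
  stopifnot(!is.null(focal), all(focal %in% rownames(dist_mat)))
  if (length(focal) < 2L) stop("need at least 2 focal taxa")
  idx <- which(upper.tri(dist_mat[focal, focal]), arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("insufficient focal pairs for regression")
  d <- dist_mat[focal, focal][idx]
  out <- list()
  for (p in colnames(r)) {
    rp <- r[, p]
    if (mean(is.na(rp)) > 0.5) {
      log_msg("partner %s skipped: >50%% missing correlations", p)
      next
    }
    dr <- abs(rp[idx[, 1]] - rp[idx[, 2]])
    ok <- is.finite(dr)
    if (sum(ok) < 3L) {
      log_msg("partner %s skipped: too few complete pairs", p)
      next
    }
    out[[p]] <- decay_fit(dr[ok], d[ok], max_degree = 1)
  }
  out
}
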