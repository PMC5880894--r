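# Conditionally rare taxa: bimodality coefficient on per-sample relative
# abundance series, plus a Fisher exact test of genus-level enrichment.

#' Sample bimodality coefficient
#'
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' bias-corrected sample skewness and `g2` the bias-corrected excess
#' kurtosis. Values near 1 indicate strong bimodality; a uniform
#' distribution gives about 0.555.
#'
#' @param x numeric vector, `n >= 4`, non-constant.
#' @return the coefficient `b`.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L) stop("bimodality coefficient requires n >= 4")
  if (any(!is.finite(x))) stop("non-finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: bimodality coefficient undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Detect conditionally rare taxa
#'
#' A taxon is conditionally rare when the bimodality coefficient of its
#' per-sample relative abundance series is at least `b_thresh` and its
#' maximum relative abundance is at least `maxrel_thresh`. Taxa for which
#' the coefficient is undefined (zero variance) are flagged not-CRT with a
#' reason.
#'
#' @param ct a [count_table()]; relative abundances are computed per sample.
#' @param b_thresh bimodality threshold (default 0.90).
#' @param maxrel_thresh maximum relative abundance threshold (default 0.005).
#' @return a data.frame with columns `taxon_id`, `b`, `max_rel`, `is_crt`,
#'   `reason`.
#' @export
detect_crt <- function(ct, b_thresh = 0.90, maxrel_thresh = 0.005) {
  stopifnot(is.count_table(ct))
  depth <- colSums(ct$counts)
  if (any(depth == 0)) stop("zero-depth sample; filter first")
  rel <- sweep(ct$counts, 2L, depth, "/")
  res <- lapply(seq_len(nrow(rel)), function(i) {
    x <- rel[i, ]
    b <- tryCatch(bimodality_coefficient(x), error = function(e) NA_real_)
    reason <- if (is.na(b)) "bimodality undefined (zero variance or n<4)"
              else NA_character_
    data.frame(taxon_id = rownames(rel)[i], b = b, max_rel = max(x),
               is_crt = !is.na(b) && b >= b_thresh && max(x) >= maxrel_thresh,
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Exact p-value for a 2x2 table with fixed margins: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. Degenerate margins give p = 1 by convention.
#'
#' @param tab 2x2 integer matrix `[[a, b], [c, d]]`.
#' @return the two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) {
    log_msg("degenerate 2x2 margins; Fisher p set to 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Genus-level enrichment of conditionally rare taxa
#'
#' Builds the 2x2 table of CRT vs non-CRT in a focal group against the rest
#' of the community (background excludes the focal group) and tests
#' enrichment with the two-sided Fisher exact test.
#'
#' @param crt_flags logical vector: is each taxon conditionally rare?
#' @param focal_mask logical vector marking the focal group.
#' @return list with `table` (2x2), `p_value`, and `proportion` of CRT in the
#'   focal group.
#' @export
crt_enrichment_test <- function(crt_flags, focal_mask) {
  stopifnot(length(crt_flags) == length(focal_mask))
  if (!any(focal_mask)) stop("empty focal group")
  if (all(focal_mask)) stop("empty background")
  tab <- matrix(c(sum(crt_flags & focal_mask), sum(!crt_flags & focal_mask),
                  sum(crt_flags & !focal_mask), sum(!crt_flags & !focal_mask)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("focal", "background"),
                                c("crt", "not_crt")))
  list(table = tab, p_value = fisher_exact_p(tab),
       proportion = tab[1, 1] / sum(tab[1, ]))
}
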