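# Centered log-ratio transforms at two grains: genus vs whole community
# (inter-genus) and strain vs its genus (intra-genus), with multiplicative
# zero replacement.

#' Multiplicative zero replacement
#'
#' Replaces zeros in a composition with `delta` and shrinks the nonzero parts
#' multiplicatively so the result still sums to one: zeros become `delta`,
#' each nonzero `x_i` becomes `x_i * (1 - Z * delta)` where `Z` is the number
#' of zeros.
#'
#' @param x non-negative vector summing to 1.
#' @param delta replacement value; must be smaller than the smallest nonzero
#'   part.
#' @return strictly positive vector summing to 1.
#' @export
multiplicative_zero_replacement <- function(x, delta) {
  if (all(x == 0)) stop("all-zero composition")
  stopifnot(all(x >= 0), delta > 0)
  nz <- x[x > 0]
  if (delta >= min(nz))
    stop("delta must be smaller than the smallest nonzero component")
  z <- sum(x == 0)
  if (z == 0L) return(x)
  out <- x * (1 - z * delta)
  out[x == 0] <- delta
  out
}

#' Centered log-ratio transform
#'
#' `clr_i = log(x_i / g(x))` with `g` the geometric mean; the output sums to
#' zero.
#'
#' @param x strictly positive composition (apply
#'   [multiplicative_zero_replacement()] first if needed).
#' @return real vector summing to 0.
#' @export
clr <- function(x) {
  if (any(x <= 0))
    stop("clr requires strictly positive input; apply zero replacement first")
  lx <- log(x)
  lx - mean(lx)
}

# default delta: half the smallest nonzero relative abundance in the matrix
default_delta <- function(rel) {
  nz <- rel[rel > 0]
  if (!length(nz)) stop("all-zero relative abundance matrix")
  0.5 * min(nz)
}

clr_matrix <- function(values, grain) {
  structure(list(values = values, grain = grain), class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("<clr_matrix> grain=%s, %d entities x %d samples\n",
              x$grain, nrow(x$values), ncol(x$values)))
  invisible(x)
}

clr_cols <- function(rel, delta) {
  apply(rel, 2L, function(p) clr(multiplicative_zero_replacement(p, delta)))
}

#' Inter-genus clr: genera relative to the whole community
#'
#' Per sample, pools counts into one part per genus plus an `other` part for
#' all unassigned taxa, converts to relative abundance, zero-replaces, and
#' applies [clr()].
#'
#' @param ct a [count_table()] with no zero-depth samples.
#' @param genus_map named character vector taxon id -> genus label; taxa not
#'   named are pooled into `other`.
#' @param delta zero replacement value; default half the smallest nonzero
#'   relative abundance in the pooled matrix.
#' @return a `clr_matrix` with grain `"inter-genus"` (genera + other in rows).
#' @export
clr_inter_genus <- function(ct, genus_map, delta = NULL) {
  stopifnot(is.count_table(ct))
  depth <- colSums(ct$counts)
  if (any(depth == 0))
    stop("sample with zero depth; filter low-depth samples first")
  grp <- genus_map[taxon_ids(ct)]
  grp[is.na(grp)] <- "other"
  pooled <- rowsum(ct$counts, grp)
  genera <- sort(unique(unname(genus_map)))
  ord <- c(genera[genera %in% rownames(pooled)],
           if ("other" %in% rownames(pooled)) "other")
  pooled <- pooled[ord, , drop = FALSE]
  rel <- sweep(pooled, 2L, depth, "/")
  if (is.null(delta)) delta <- default_delta(rel)
  vals <- clr_cols(rel, delta)
  rownames(vals) <- rownames(rel)
  clr_matrix(vals, "inter-genus")
}

#' Intra-genus clr: strains relative to their genus
#'
#' Per sample, strain counts are normalized by the genus total, then
#' zero-replaced and clr-transformed. Samples where the genus is entirely
#' absent are dropped (logged): intra-genus composition is undefined there.
#'
#' @param ct a [count_table()].
#' @param genus_taxa character vector of at least two taxon ids forming the
#'   genus.
#' @param delta zero replacement value; default half the smallest nonzero
#'   intra-genus relative abundance.
#' @return a `clr_matrix` with grain `"intra-genus"`.
#' @export
clr_intra_genus <- function(ct, genus_taxa, delta = NULL) {
  stopifnot(is.count_table(ct))
  missing <- setdiff(genus_taxa, taxon_ids(ct))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(genus_taxa) < 2L)
    stop("intra-genus clr needs at least 2 strains")
  sub <- ct$counts[genus_taxa, , drop = FALSE]
  tot <- colSums(sub)
  keep <- tot > 0
  if (!all(keep))
    log_msg("intra-genus clr: dropped %d samples where the genus is absent",
            sum(!keep))
  if (!any(keep)) stop("genus absent from every sample")
  sub <- sub[, keep, drop = FALSE]
  rel <- sweep(sub, 2L, tot[keep], "/")
  if (is.null(delta)) delta <- default_delta(rel)
  vals <- clr_cols(rel, delta)
  rownames(vals) <- genus_taxa
  clr_matrix(vals, "intra-genus")
}

#' Write a clr matrix to TSV
#' @param x a `clr_matrix`.
#' @param path output TSV path.
#' @export
write_clr_matrix <- function(x, path) {
  df <- data.frame(entity = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
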