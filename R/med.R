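# Simplified minimum entropy decomposition of aligned amplicon reads.
#
# Reads are carried as (unique sequence, multiplicity) pairs; splitting is
# recursive on the single position of maximal Shannon entropy, and child
# nodes whose most abundant unique sequence falls below the minimum
# substantive abundance M are discarded as noise (not reassigned).

#' Per-position Shannon entropy of an alignment
#'
#' Entropy (in nats) of the symbol composition at every alignment column,
#' weighting each unique sequence by its read multiplicity. The gap `-` is a
#' fifth symbol.
#'
#' @param seqs a [sequence_set()] of uniform length.
#' @param weights integer read multiplicities, one per sequence (default 1).
#' @return numeric vector of entropies, one per position, each in
#'   `[0, log(5)]`.
#' @export
positional_entropy <- function(seqs, weights = NULL) {
  if (length(seqs) == 0L) stop("empty read set")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights >= 1))
  m <- seq_matrix(seqs)
  apply(m, 2L, function(col) {
    f <- rowsum(weights, col)[, 1]
    f <- f / sum(f)
    -sum(f * log(f))
  })
}

#' Decompose reads into minimum-entropy nodes
#'
#' Recursive entropy decomposition: while the maximal positional entropy of a
#' node exceeds `entropy_threshold`, members are split by their symbol at the
#' arg-max position (ties broken toward the lowest position index). Children
#' whose most abundant unique sequence has fewer than `M` reads are discarded
#' and their reads tallied as noise. Retained plus noise reads always equal
#' the input reads.
#'
#' @param seqs a [sequence_set()] of unique aligned reads.
#' @param weights read multiplicity per unique sequence (default 1 each).
#' @param M minimum substantive abundance: a node survives only if its most
#'   abundant unique member sequence has at least `M` reads (default 500).
#' @param entropy_threshold minimal positional entropy (nats) that triggers a
#'   split (default 0.0965).
#' @return a list with `nodes` (list of `med_node`: `node_id`,
#'   `representative`, `read_count`, `members` data.frame), `noise_reads`,
#'   and `input_reads`.
#' @export
med_decompose <- function(seqs, weights = NULL, M = 500,
                          entropy_threshold = 0.0965) {
  stopifnot(M >= 1)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs))
  total <- sum(weights)
  if (M > total) {
    warning("minimum substantive abundance exceeds total reads; empty result")
    return(list(nodes = list(), noise_reads = total, input_reads = total))
  }
  m <- seq_matrix(seqs)
  w <- as.numeric(weights)

  noise <- 0
  nodes <- list()

  recurse <- function(idx) {
    # survival check: most abundant unique sequence in the node
    if (max(w[idx]) < M) {
      noise <<- noise + sum(w[idx])
      return(invisible(NULL))
    }
    sub <- m[idx, , drop = FALSE]
    H <- apply(sub, 2L, function(col) {
      f <- rowsum(w[idx], col)[, 1]
      f <- f / sum(f)
      -sum(f * log(f))
    })
    pos <- which.max(H)  # ties -> lowest index
    if (H[pos] <= entropy_threshold) {
      rep_i <- idx[which.max(w[idx])]
      nodes[[length(nodes) + 1L]] <<- structure(list(
        node_id = sprintf("node_%04d", length(nodes) + 1L),
        representative = paste0(m[rep_i, ], collapse = ""),
        read_count = sum(w[idx]),
        members = data.frame(
          sequence = apply(m[idx, , drop = FALSE], 1L, paste0, collapse = ""),
          reads = w[idx], stringsAsFactors = FALSE)),
        class = "med_node")
      return(invisible(NULL))
    }
    for (grp in split(idx, sub[, pos])) recurse(grp)
    invisible(NULL)
  }
  recurse(seq_along(w))

  list(nodes = nodes, noise_reads = noise, input_reads = total)
}

#' Node-by-sample count table from a decomposition
#'
#' When per-sample read provenance is available (a unique-sequence by sample
#' count matrix), project node membership onto samples.
#'
#' @param med result of [med_decompose()].
#' @param per_sample numeric matrix, unique sequences x samples, whose row
#'   names are the sequences passed to [med_decompose()].
#' @return a [count_table()] of nodes x samples.
#' @export
med_node_counts <- function(med, per_sample) {
  if (!length(med$nodes)) stop("no nodes in decomposition")
  rows <- lapply(med$nodes, function(nd) {
    colSums(per_sample[nd$members$sequence, , drop = FALSE])
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- vapply(med$nodes, `[[`, "", "node_id")
  count_table(counts)
}
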