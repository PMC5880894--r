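#' @keywords internal
"_PACKAGE"

# ---- CountTable -------------------------------------------------------------

#' Construct a taxon-by-sample count table
#'
#' A `count_table` holds non-negative integer read counts for taxa (rows)
#' across samples (columns), optionally with per-sample metadata (date, site).
#'
#' @param counts integer matrix, taxa x samples, with unique row and column
#'   names.
#' @param sample_meta optional data.frame with columns `sample_id`, `date`,
#'   `site`; rows for unknown sample ids are dropped with a warning.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no taxa in count table")
  if (ncol(counts) == 0L) stop("no samples in count table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts))) stop("non-finite counts")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # doubles avoid integer overflow on sums
  meta <- normalize_sample_meta(sample_meta, colnames(counts))
  structure(list(counts = counts, sample_meta = meta), class = "count_table")
}

normalize_sample_meta <- function(sample_meta, sample_ids) {
  if (is.null(sample_meta)) {
    return(data.frame(sample_id = sample_ids, date = NA_character_,
                      site = NA_character_, stringsAsFactors = FALSE))
  }
  if (!"sample_id" %in% names(sample_meta))
    stop("sample metadata needs a 'sample_id' column")
  unknown <- setdiff(sample_meta$sample_id, sample_ids)
  if (length(unknown)) {
    log_msg("ignoring %d metadata rows with unknown sample ids (%s...)",
            length(unknown), unknown[1])
    sample_meta <- sample_meta[sample_meta$sample_id %in% sample_ids, ,
                               drop = FALSE]
  }
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  idx <- match(sample_ids, sample_meta$sample_id)
  out$date <- if ("date" %in% names(sample_meta))
    as.character(sample_meta$date)[idx] else NA_character_
  out$site <- if ("site" %in% names(sample_meta))
    as.character(sample_meta$site)[idx] else NA_character_
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples, total reads %.0f\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @rdname count_table
#' @param x object to test.
#' @export
is.count_table <- function(x) inherits(x, "count_table")

taxon_ids <- function(ct) rownames(ct$counts)
sample_ids <- function(ct) colnames(ct$counts)

#' Read a taxon-by-sample count table from TSV
#'
#' Expects a header row of sample ids and a first column of taxon ids; the
#' body must be non-negative integers. If `<path minus extension>_meta.tsv`
#' exists (or `meta_path` is given) it is read as per-sample metadata keyed by
#' `sample_id`.
#'
#' @param path TSV file path.
#' @param meta_path optional path to a sample-metadata TSV.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, meta_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("no taxa: count table body is empty")
  if (ncol(raw) < 2L) stop("no samples: count table has no sample columns")
  taxa <- raw[[1]]
  if (anyDuplicated(taxa)) stop("duplicate taxon ids in ", path)
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(num) | num != floor(num))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(body)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(body)) + 1L
    stop(sprintf("non-integer cell '%s' at taxon '%s', sample '%s'",
                 body[i, j], taxa[i], colnames(body)[j]))
  }
  counts <- matrix(num, nrow = nrow(body),
                   dimnames = list(taxa, colnames(body)))
  if (is.null(meta_path)) {
    cand <- paste0(tools::file_path_sans_ext(path), "_meta.tsv")
    if (file.exists(cand)) meta_path <- cand
  }
  meta <- if (!is.null(meta_path))
    utils::read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE)
  else NULL
  count_table(counts, meta)
}

#' Write a count table to TSV
#'
#' @param ct a [count_table()].
#' @param path output TSV path; metadata (if any non-missing) is written to
#'   `<path minus extension>_meta.tsv`.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(is.count_table(ct))
  df <- data.frame(taxon_id = taxon_ids(ct), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(!is.na(ct$sample_meta$date)) || any(!is.na(ct$sample_meta$site))) {
    utils::write.table(ct$sample_meta,
                       paste0(tools::file_path_sans_ext(path), "_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- EnvMatrix --------------------------------------------------------------

#' Construct a samples-by-variables environmental matrix
#'
#' @param values numeric matrix, samples x variables, with unique row
#'   (sample) and column (variable) names; `NA` marks missing measurements.
#' @param units optional named character vector of units per variable.
#' @return an object of class `env_matrix`.
#' @export
env_matrix <- function(values, units = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("env matrix needs sample row names and variable column names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate variable names")
  storage.mode(values) <- "double"
  if (is.null(units)) {
    units <- rep(NA_character_, ncol(values))
    names(units) <- colnames(values)
  } else {
    units <- units[colnames(values)]
    names(units) <- colnames(values)
  }
  structure(list(values = values, units = units), class = "env_matrix")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("<env_matrix> %d samples x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read an environmental table from TSV
#'
#' Header row names the variables (optionally as `name (unit)`); the first
#' column holds sample ids. Blank cells become missing values.
#'
#' @param path TSV file path.
#' @return an [env_matrix()].
#' @export
read_env_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop("no samples in environmental table")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample id in ", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  nm <- colnames(vals)
  units <- rep(NA_character_, length(nm))
  has_unit <- grepl("\\(([^)]+)\\)\\s*$", nm)
  units[has_unit] <- sub("^.*\\(([^)]+)\\)\\s*$", "\\1", nm[has_unit])
  nm <- trimws(sub("\\(([^)]+)\\)\\s*$", "", nm))
  colnames(vals) <- nm
  rownames(vals) <- ids
  names(units) <- nm
  env_matrix(vals, units)
}

#' Write an environmental table to TSV
#' @param env an [env_matrix()].
#' @param path output TSV path.
#' @export
write_env_table <- function(env, path) {
  nm <- colnames(env$values)
  hdr <- ifelse(is.na(env$units), nm, sprintf("%s (%s)", nm, env$units))
  df <- data.frame(sample_id = rownames(env$values), env$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an environmental matrix with a count table
#'
#' Keeps the samples present in both objects, in count-table order.
#' @param env an [env_matrix()].
#' @param ct a [count_table()].
#' @return an [env_matrix()] restricted to shared samples.
#' @export
align_env <- function(env, ct) {
  shared <- intersect(sample_ids(ct), rownames(env$values))
  if (!length(shared))
    stop("no overlap between environmental and count-table sample ids")
  env_matrix(env$values[shared, , drop = FALSE], env$units)
}

# ---- SequenceSet ------------------------------------------------------------

#' Construct a set of aligned nucleotide sequences
#'
#' @param seqs named character vector of sequences over the alphabet
#'   `A,C,G,T,-`; lowercase is upcased and `U` mapped to `T`.
#' @param uniform require all sequences to share one length (default TRUE).
#' @return an object of class `sequence_set` (named character vector).
#' @export
sequence_set <- function(seqs, uniform = TRUE) {
  if (length(seqs) == 0L)
    return(structure(character(), class = "sequence_set"))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(grepl("[^ACGT-]", seqs)))
    stop("sequences restricted to alphabet A,C,G,T,-")
  if (uniform && length(unique(nchar(seqs))) > 1L)
    stop("sequences must have uniform length")
  out <- as.character(seqs)
  names(out) <- names(seqs)
  structure(out, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %d sequences, length %s\n", length(x),
              paste(unique(nchar(unclass(x))), collapse = "/")))
  invisible(x)
}

#' Read aligned sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param uniform require uniform sequence length (default TRUE).
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, uniform = TRUE) {
  dna <- ape::read.FASTA(path)                  # list of raw DNAbin vectors
  seqs <- vapply(as.character(dna), paste0, "", collapse = "")
  sequence_set(seqs, uniform = uniform)
}

#' Write a sequence set to FASTA
#' @param seqs a [sequence_set()].
#' @param path output FASTA path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unclass(seqs)), con, sep = "\n")
  invisible(path)
}

# sequence set as id x position character matrix
seq_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unclass(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# ---- depth filter -----------------------------------------------------------

#' Remove low-depth samples from a count table
#'
#' Samples whose total read count is strictly below `min_reads` are dropped;
#' the taxon set is unchanged. A sample with exactly `min_reads` reads is
#' retained.
#'
#' @param ct a [count_table()].
#' @param min_reads minimum column sum (default 1000).
#' @return the filtered [count_table()].
#' @export
filter_low_depth_samples <- function(ct, min_reads = 1000) {
  stopifnot(is.count_table(ct), min_reads >= 0)
  depth <- colSums(ct$counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop("empty table: all samples below minimum depth")
  if (!all(keep))
    log_msg("depth filter: removed %d/%d samples below %d reads",
            sum(!keep), length(keep), min_reads)
  count_table(ct$counts[, keep, drop = FALSE],
              ct$sample_meta[keep, , drop = FALSE])
}

# ---- logging ----------------------------------------------------------------

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[nichepart] ", fmt), ...))
}
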