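# Readers and writers for the tabular and sequence formats every stage
# touches. All tables are TSV with a header row; intervals are 0-based,
# end-exclusive (length = end - start) unless conversion is requested.

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Container for a count matrix with sample metadata
#'
#' Bundles an integer matrix of unique-read counts (features x samples) with
#' a metadata table describing each sample (species, cell line, condition,
#' dose, passage). Counts must be non-negative integers: fractional
#' multi-mapping allocations are rejected, not rounded.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param meta Data frame with one row per sample and at least the columns
#'   `sample_id`, `species`, `cell_line`, `condition`, `dose_ug_per_ml`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta` (rows of `meta` ordered to match `colnames(counts)`).
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have feature ids as rownames and sample ids as colnames")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  required <- c("sample_id", "species", "cell_line", "condition",
                "dose_ug_per_ml")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra))
    stop("metadata sample(s) absent from count matrix: ",
         paste(extra, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("species:", paste(unique(x$meta$species), collapse = ", "), "\n")
  cat("conditions:",
      paste(unique(paste0(x$meta$condition, "@", x$meta$dose_ug_per_ml)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix and its sample metadata
#'
#' The counts file is a TSV whose first column holds feature ids and whose
#' remaining header fields are sample ids. The metadata file has one row per
#' sample. Sample ids in the two files must agree exactly; non-integer count
#' values are a hard error naming the offending cell.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("counts file must have a feature column and >=1 sample")
  feature_id <- raw[[1]]
  if (anyDuplicated(feature_id))
    stop("duplicated feature id(s): ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  sample_ids <- names(raw)[-1]
  counts <- matrix(0L, nrow(raw), length(sample_ids),
                   dimnames = list(feature_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad))
      stop(sprintf(
        "non-integer count '%s' at feature '%s', sample '%s'",
        v[bad[1]], feature_id[bad[1]], sample_ids[j]))
    counts[, j] <- as.integer(num)
  }
  meta <- read_sample_meta(meta_path)
  count_matrix(counts, meta)
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `species`, `cell_line`,
#'   `condition`, `dose_ug_per_ml` and optionally `passage`.
#' @return A data frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE)
  required <- c("sample_id", "species", "cell_line", "condition",
                "dose_ug_per_ml")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample id(s) in metadata")
  meta
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param cm A [count_matrix()].
#' @param path Output path for the counts TSV.
#' @param meta_path Optional output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, meta_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(cm$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read nucleotide sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header; sequences are
#' uppercased. Empty records and non-IUPAC characters are hard errors (the
#' latter naming the offending position).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty))
    stop("empty record '", ids[empty[1]], "' in FASTA file")
  pat <- paste0("[^", paste(IUPAC_NT, collapse = ""), "]")
  bad <- regexpr(pat, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-IUPAC character '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  stats::setNames(seqs, ids)
}

#' Write nucleotide sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nchar(seqs) > 0))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an ERV/TE interval table
#'
#' Expects TSV columns `erv_id` (or `id`), `chrom`, `start`, `end`, `strand`
#' and optionally `length_bp` and `sequence`. The stored convention is 0-based
#' end-exclusive, so `length_bp = end - start`; input in 1-based inclusive
#' coordinates can be converted with `one_based_inclusive = TRUE`. Records
#' whose stated length disagrees with `end - start` are rejected.
#'
#' @param path Path to the TSV.
#' @param one_based_inclusive Logical; if `TRUE`, input `start` is 1-based and
#'   `end` inclusive, and `start` is shifted down by one on read.
#' @return Data frame with columns `erv_id`, `chrom`, `start`, `end`,
#'   `strand`, `length_bp` (and `sequence` when present).
#' @export
read_erv_table <- function(path, one_based_inclusive = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  if ("id" %in% names(df) && !"erv_id" %in% names(df))
    names(df)[names(df) == "id"] <- "erv_id"
  required <- c("erv_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("ERV table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (one_based_inclusive) df$start <- df$start - 1L
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("degenerate interval (end <= start) for record '%s'",
                 df$erv_id[bad[1]]))
  if (any(df$start < 0)) stop("negative start coordinate")
  len <- df$end - df$start
  stated <- if ("length_bp" %in% names(df)) df$length_bp
            else if ("length" %in% names(df)) df$length else NULL
  if (!is.null(stated)) {
    off <- which(stated != len)
    if (length(off))
      stop(sprintf(
        "stated length %d disagrees with end - start = %d for record '%s'",
        stated[off[1]], len[off[1]], df$erv_id[off[1]]))
  }
  df$length_bp <- as.integer(len)
  if ("sequence" %in% names(df)) {
    mism <- which(nchar(df$sequence) != df$length_bp)
    if (length(mism))
      stop(sprintf("sequence length disagrees with length_bp for record '%s'",
                   df$erv_id[mism[1]]))
  }
  keep <- c("erv_id", "chrom", "start", "end", "strand", "length_bp",
            intersect("sequence", names(df)))
  df[, keep]
}

#' Write an ERV/TE interval table to TSV
#'
#' @param records Data frame as returned by [read_erv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_erv_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
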