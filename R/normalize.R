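# The cross-species normalization chain: counts are normalized by total
# reads (CPM scale), adjusted for CDS length as reads per kb, and, for
# cross-species comparison, expressed as the ratio to the housekeeping gene
# (Gapdh) value in the same sample. TPM and TMM factors are provided for the
# within-species expression analyses.

#' Construct a normalized expression matrix with provenance
#'
#' A numeric matrix (features x samples) carrying an ordered provenance tag
#' naming every normalization step applied, and, after the housekeeping
#' ratio, the reference gene.
#'
#' @param values Non-negative numeric matrix with dimnames.
#' @param provenance Character vector of applied steps (non-empty).
#' @param reference_gene Feature id of the housekeeping reference, or `NULL`.
#' @return A matrix of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, provenance, reference_gene = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), length(provenance) >= 1)
  if (any(values < 0)) stop("normalized values must be non-negative")
  structure(values, class = c("normalized_matrix", class(values)),
            provenance = provenance, reference_gene = reference_gene)
}

#' Provenance of a normalized matrix
#' @param x A `normalized_matrix`.
#' @return Character vector of applied normalization steps.
#' @export
provenance <- function(x) attr(x, "provenance")

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d features x %d samples\n",
              nrow(x), ncol(x)))
  cat("provenance:", paste(provenance(x), collapse = " -> "), "\n")
  if (!is.null(attr(x, "reference_gene")))
    cat("reference gene:", attr(x, "reference_gene"), "\n")
  invisible(x)
}

#' Normalize counts by total reads per sample (CPM scale)
#'
#' Each count is divided by its sample's total and multiplied by 1e6. The
#' scale factor is cosmetic: it cancels in every downstream ratio.
#'
#' @param cm A [count_matrix()].
#' @return A `normalized_matrix` with provenance `"total-count"`.
#' @export
total_count_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop("zero total count for sample(s): ",
         paste(colnames(cm$counts)[zero], collapse = ", "))
  values <- sweep(cm$counts, 2, totals, "/") * 1e6
  normalized_matrix(values, "total-count")
}

#' Adjust normalized values for CDS length (per kilobase)
#'
#' @param norm A `normalized_matrix`.
#' @param annot Feature annotation with columns `feature_id` and
#'   `cds_length_bp`; every feature of `norm` must have a length.
#' @return A `normalized_matrix` with `"per-kb"` appended to provenance.
#' @export
per_kb_adjust <- function(norm, annot) {
  stopifnot(inherits(norm, "normalized_matrix"))
  idx <- match(rownames(norm), annot$feature_id)
  if (anyNA(idx))
    stop("no CDS length for feature(s): ",
         paste(rownames(norm)[is.na(idx)][1], collapse = ", "))
  len_kb <- annot$cds_length_bp[idx] / 1000
  normalized_matrix(unclass(norm) / len_kb,
                    c(provenance(norm), "per-kb"),
                    attr(norm, "reference_gene"))
}

#' Express values as the ratio to the housekeeping gene in the same sample
#'
#' Divides every value by the reference feature's value in the same sample,
#' so the reference row becomes exactly 1 everywhere. Ratios between any two
#' non-reference genes are unchanged.
#'
#' @param norm A `normalized_matrix`.
#' @param reference Feature id of the housekeeping gene (default "Gapdh").
#' @return A `normalized_matrix` with `"gapdh-ratio"` appended to provenance
#'   and `reference_gene` set.
#' @export
gapdh_ratio <- function(norm, reference = "Gapdh") {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!reference %in% rownames(norm))
    stop("reference feature '", reference, "' not present")
  ref <- norm[reference, ]
  zero <- which(ref == 0)
  if (length(zero))
    stop("reference value is zero in sample(s): ",
         paste(colnames(norm)[zero], collapse = ", "))
  values <- sweep(unclass(norm), 2, ref, "/")
  values[reference, ] <- 1  # exact, not subject to rounding
  normalized_matrix(values, c(provenance(norm), "gapdh-ratio"), reference)
}

#' Run the cross-species normalization chain
#'
#' Convenience wrapper applying [total_count_normalize()], [per_kb_adjust()]
#' and [gapdh_ratio()] in order.
#'
#' @param cm A [count_matrix()].
#' @param annot Feature annotation (feature_id, cds_length_bp).
#' @param reference Housekeeping feature id (default "Gapdh").
#' @return A `normalized_matrix` on the Gapdh-ratio scale.
#' @export
normalize_chain <- function(cm, annot, reference = "Gapdh") {
  gapdh_ratio(per_kb_adjust(total_count_normalize(cm), annot), reference)
}

#' Transcripts per million
#'
#' Counts are converted to per-kilobase rates and each sample is rescaled so
#' its column sums to 1e6.
#'
#' @param cm A [count_matrix()].
#' @param annot Feature annotation with `feature_id` and `cds_length_bp`.
#' @return A `normalized_matrix` with provenance `"tpm"`.
#' @export
tpm <- function(cm, annot) {
  stopifnot(inherits(cm, "count_matrix"))
  idx <- match(rownames(cm$counts), annot$feature_id)
  if (anyNA(idx))
    stop("no CDS length for feature(s): ",
         paste(rownames(cm$counts)[is.na(idx)][1], collapse = ", "))
  rate <- cm$counts / (annot$cds_length_bp[idx] / 1000)
  totals <- colSums(rate)
  if (any(totals == 0))
    stop("zero total per-kb rate for sample(s): ",
         paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  normalized_matrix(sweep(rate, 2, totals, "/") * 1e6, "tpm")
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Standard TMM library-composition factors (reference sample chosen by
#' upper quartile closest to the mean upper quartile; 30 percent trim on
#' M-values, 5 percent on A-values; precision-weighted mean of M), computed
#' by edgeR and normalized to geometric mean 1.
#'
#' @param cm A [count_matrix()] with at least two samples.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2) stop("TMM needs at least two samples")
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM")
  if (any(!is.finite(f)))
    stop("TMM factor undefined for sample(s): ",
         paste(colnames(cm$counts)[!is.finite(f)], collapse = ", "),
         " (no co-expressed features shared with the reference sample)")
  stats::setNames(f, colnames(cm$counts))
}

#' Elementwise log transform with documented offset handling
#'
#' @param norm A `normalized_matrix` or numeric matrix.
#' @param base One of `"e"`, `"2"`, `"10"`.
#' @param offset Non-negative value added before taking logs; with offset 0,
#'   any non-positive value is an error.
#' @return Plain numeric matrix of logarithms.
#' @export
log_transform <- function(norm, base = c("e", "2", "10"), offset = 0) {
  base <- match.arg(as.character(base), c("e", "2", "10"))
  stopifnot(offset >= 0)
  values <- unclass(norm) + offset
  if (any(values <= 0))
    stop("log of non-positive value; supply a positive offset")
  b <- switch(base, e = exp(1), `2` = 2, `10` = 10)
  log(values, base = b)
}
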