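# Six-frame scan for translatable open reading frames with a Kozak-type
# initiation context: ATG start (A at +1), at least `min_codons` sense
# codons, a purine (A/G) at -3 and a G at +4. An ORF runs from a qualifying
# ATG to the first in-frame stop wholly within the sequence; by default only
# the 5'-most qualifying ATG per (strand, frame, stop) segment is reported.

COMPLEMENT_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
COMPLEMENT_TO   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of a nucleotide sequence
#'
#' Standard complement, reversed; IUPAC ambiguity codes map to their
#' complements (N to N). Invalid characters are an error naming the
#' position.
#'
#' @param seq Nucleotide string (IUPAC alphabet).
#' @return The reverse-complemented string (case preserved).
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  bad <- regexpr(paste0("[^", COMPLEMENT_FROM, "]"), seq)
  if (bad > 0)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(seq, bad, bad), bad))
  paste(rev(strsplit(chartr(COMPLEMENT_FROM, COMPLEMENT_TO, seq),
                     "")[[1]]), collapse = "")
}

#' Find Kozak-context open reading frames on both strands
#'
#' Scans all three frames of each strand. A hit requires: `ATG` start codon
#' with at least 3 bases upstream on the scanned strand, a purine (A or G)
#' at position -3 and `G` at position +4 (the first base of codon 2, always
#' inside the ORF), at least `min_codons` sense codons (ATG included, stop
#' excluded), and an in-frame stop codon (TAA/TAG/TGA) wholly within the
#' sequence unless `require_stop = FALSE`. Candidate ORFs containing an
#' ambiguity code are rejected (translation undefined) and counted in the
#' `n_rejected` attribute. Ambiguity codes at -3 or +4 disqualify the ATG.
#'
#' Coordinates are always a plus-strand interval: `start < end` with
#' `end - start + 1 = 3 * (codon_count + 1)`; for `strand == "-"` the A of
#' the ATG sits at `end`.
#'
#' @param seq Nucleotide string.
#' @param parent_id Id recorded in the `parent_id` column.
#' @param min_codons Minimum sense-codon count (default 30).
#' @param mode `"maximal"` reports only the 5'-most qualifying ATG per
#'   (strand, frame, stop) segment; `"all_starts"` reports every qualifying
#'   ATG. Maximal-mode hits are a subset of all-starts hits.
#' @param require_stop Require the terminating stop codon inside the
#'   sequence (default TRUE; stop-less terminal ORFs are for sensitivity
#'   analyses only).
#' @return Data frame with columns parent_id, strand, start, end,
#'   codon_count, minus3_base, plus4_base, peptide; attribute `n_rejected`
#'   counts ambiguity-rejected candidates.
#' @export
find_kozak_orfs <- function(seq, parent_id = "seq", min_codons = 30L,
                            mode = c("maximal", "all_starts"),
                            require_stop = TRUE) {
  mode <- match.arg(mode)
  stopifnot(min_codons >= 1)
  seq <- toupper(seq)
  bad <- regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), seq)
  if (bad > 0)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(seq, bad, bad), bad))
  L <- nchar(seq)
  hits <- list()
  n_rejected <- 0L
  for (strand in c("+", "-")) {
    S <- if (strand == "+") seq else reverse_complement(seq)
    for (f in 0:2) {
      if (L - f < 3) next
      starts <- seq.int(f + 1L, L - 2L, by = 3L)
      codons <- substring(S, starts, starts + 2L)
      stop_idx <- which(codons %in% STOP_CODONS)
      atg_idx <- which(codons == "ATG")
      if (!length(atg_idx)) next
      # index (within stop_idx) of the first stop strictly after each ATG
      nxt <- findInterval(atg_idx, stop_idx) + 1L
      taken_segment <- integer(0)  # stop indices already claimed (maximal)
      for (k in seq_along(atg_idx)) {
        i <- atg_idx[k]
        has_stop <- nxt[k] <= length(stop_idx)
        if (!has_stop && require_stop) next
        sidx <- if (has_stop) stop_idx[nxt[k]] else length(codons) + 1L
        cc <- sidx - i
        if (cc < min_codons) next
        p <- starts[i]
        if (p < 4L) next  # fewer than 3 upstream bases: disqualified
        m3 <- substr(S, p - 3L, p - 3L)
        p4 <- substr(S, p + 3L, p + 3L)
        if (!(m3 %in% c("A", "G")) || p4 != "G") next
        if (mode == "maximal" && sidx %in% taken_segment) next
        orf_end <- if (has_stop) starts[i] + 3L * cc + 2L  # stop included
                   else starts[i] + 3L * cc - 1L
        region <- substr(S, p, orf_end)
        if (grepl("[^ACGT]", region)) {
          n_rejected <- n_rejected + 1L
          next
        }
        if (mode == "maximal")
          taken_segment <- c(taken_segment, sidx)
        pep <- translate(substr(S, p, p + 3L * cc - 1L),
                         check_internal_stop = FALSE)
        coords <- if (strand == "+") c(p, orf_end)
                  else c(L - orf_end + 1L, L - p + 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          parent_id = parent_id, strand = strand,
          start = coords[1], end = coords[2], codon_count = cc,
          minus3_base = m3, plus4_base = p4, peptide = pep)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(parent_id = character(), strand = character(),
                         start = integer(), end = integer(),
                         codon_count = integer(), minus3_base = character(),
                         plus4_base = character(), peptide = character())
  out <- out[order(out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_rejected = n_rejected)
}

#' Scan a set of sequences for Kozak-context ORFs
#'
#' @param seqs Named character vector of sequences (e.g. [read_fasta()]
#'   output or the `sequence` column of a simulated ERV set).
#' @param ... Passed to [find_kozak_orfs()].
#' @return Row-bound hit table over all parents; attribute `n_rejected`
#'   sums ambiguity rejections.
#' @export
scan_kozak_orfs <- function(seqs, ...) {
  stopifnot(!is.null(names(seqs)))
  per <- lapply(names(seqs), function(id)
    find_kozak_orfs(seqs[[id]], parent_id = id, ...))
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  structure(out, n_rejected = sum(vapply(per, attr, integer(1),
                                         "n_rejected")))
}

#' Translate a coding sequence with the standard genetic code
#'
#' One letter per codon. A terminal stop, when present, is excluded from
#' the reported polypeptide; with `check_internal_stop = TRUE` an internal
#' stop is an error naming the codon index.
#'
#' @param cds Nucleotide string, length divisible by 3, A/C/G/T only.
#' @param check_internal_stop Error on internal stops (default TRUE);
#'   when FALSE internal stops appear as `*`.
#' @return Amino-acid string.
#' @export
translate <- function(cds, check_internal_stop = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0)
    stop("CDS length ", n, " is not a positive multiple of 3")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    stop("untranslatable codon '", codons[which(is.na(aa))[1]],
         "' at codon index ", which(is.na(aa))[1])
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  internal <- which(aa == "*")
  if (length(internal) && check_internal_stop)
    stop("internal stop codon at codon index ", internal[1])
  paste(aa, collapse = "")
}

#' Summarize peptide lengths of a set of ORF hits
#'
#' @param hits Hit table from [find_kozak_orfs()]/[scan_kozak_orfs()].
#' @param parents Optional character vector of all scanned parent ids, used
#'   for the fraction of parents with at least one hit (defaults to the
#'   parents present in `hits`).
#' @return List: n, mean_aa, ci95 (t-interval on the mean), range_aa,
#'   per_parent (named counts), frac_parents_with_hit. All numeric fields
#'   are `NA` for an empty hit table.
#' @export
orf_length_summary <- function(hits, parents = NULL) {
  if (is.null(parents)) parents <- unique(hits$parent_id)
  if (nrow(hits) == 0)
    return(list(n = 0L, mean_aa = NA_real_, ci95 = c(NA_real_, NA_real_),
                range_aa = c(NA_real_, NA_real_),
                per_parent = stats::setNames(integer(length(parents)),
                                             parents),
                frac_parents_with_hit = if (length(parents)) 0 else
                  NA_real_))
  len <- hits$codon_count
  n <- length(len)
  ci <- if (n >= 2 && stats::sd(len) > 0) {
    se <- stats::sd(len) / sqrt(n)
    mean(len) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  } else c(mean(len), mean(len))
  per_parent <- table(factor(hits$parent_id, levels = parents))
  list(n = n, mean_aa = mean(len), ci95 = ci,
       range_aa = range(len),
       per_parent = stats::setNames(as.integer(per_parent),
                                    names(per_parent)),
       frac_parents_with_hit = mean(per_parent > 0))
}
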