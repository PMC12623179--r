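# Shared fixture builders and independent oracles. The oracles deliberately
# take the dumbest correct route (per-position enumeration, direct moment
# sums) so they share no code path with the implementation they check.

make_count_matrix <- function(counts, species = "Pleucopus") {
  n_s <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(n_s))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  meta <- data.frame(sample_id = colnames(counts),
                     species = species,
                     cell_line = paste0("L", seq_len(n_s)),
                     condition = "control", dose_ug_per_ml = 0, passage = 2L)
  count_matrix(counts, meta)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force Kozak ORF enumerator: tests the predicate at every (strand,
# position) pair by walking codons. all_starts semantics; maximal obtained
# by keeping the 5'-most start per (strand, frame, stop).
oracle_kozak <- function(seq, min_codons = 30L,
                         mode = c("all_starts", "maximal")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") seq else reverse_complement(seq)
    ch <- strsplit(S, "")[[1]]
    for (p in seq_len(L - 2)) {
      if (paste(ch[p:(p + 2)], collapse = "") != "ATG") next
      if (p < 4) next
      if (!(ch[p - 3] %in% c("A", "G"))) next
      if (ch[p + 3] != "G") next
      q <- p + 3
      stop_at <- NA
      while (q + 2 <= L) {
        codon <- paste(ch[q:(q + 2)], collapse = "")
        if (codon %in% c("TAA", "TAG", "TGA")) { stop_at <- q; break }
        q <- q + 3
      }
      if (is.na(stop_at)) next
      cc <- (stop_at - p) / 3
      if (cc < min_codons) next
      if (grepl("[^ACGT]", substr(S, p, stop_at + 2))) next
      coords <- if (strand == "+") c(p, stop_at + 2)
                else c(L - (stop_at + 2) + 1, L - p + 1)
      rows[[length(rows) + 1]] <- data.frame(
        strand = strand, start = coords[1], end = coords[2],
        codon_count = cc, frame = (p - 1) %% 3, stop_at = stop_at,
        p_scanned = p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(strand = character(), start = integer(),
                         end = integer(), codon_count = integer(),
                         frame = integer(), stop_at = integer(),
                         p_scanned = integer())
  if (mode == "maximal" && nrow(out)) {
    key <- paste(out$strand, out$frame, out$stop_at)
    keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(i)
      i[which.min(out$p_scanned[i])]))
    out <- out[sort(keep), , drop = FALSE]
  }
  out <- out[order(out$strand, out$start, out$end),
             c("strand", "start", "end", "codon_count")]
  rownames(out) <- NULL
  out
}

orf_key <- function(d) paste(d$strand, d$start, d$end, d$codon_count)

# Direct-definition Fisher oracle: enumerate every table with the observed
# margins, sum probabilities <= that of the observed table.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
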