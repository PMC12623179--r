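# Synthetic-data generators emulating the study design: a paired
# 2-species x {control, 1, 10 ug/mL} exposure with five cell lines per
# species and a stable housekeeping gene, and ERV/TE reference sets with
# right-skewed length distributions carrying planted Kozak-compliant ORFs.

#' Specification for the paired count simulator
#'
#' Defaults encode the study conditions: five cell lines per species, doses
#' {0, 1, 10} ug/mL (dose 0 = control), negative-binomial counts with a
#' per-line lognormal random effect shared between a line's control and
#' treated samples (so pairing is informative), and a designated
#' Gapdh-like housekeeping feature with treatment effect exactly zero.
#'
#' @param n_lines_per_species Cell lines (= animals) per species.
#' @param doses Dose levels in ug/mL; 0 is the untreated control.
#' @param n_features Number of coding features to simulate.
#' @param baseline_log_mean_range Range (natural log scale) from which
#'   per-feature baseline mean counts are drawn uniformly.
#' @param dispersion Negative-binomial size parameter; `1/sqrt(size)` is the
#'   biological coefficient of variation, so the default 100 encodes
#'   BCV 0.1, typical of replicate cultures of genetically homogeneous
#'   lines and the level at which a five-pair design detects a fourfold
#'   effect at p < 0.001.
#' @param frac_deg Fraction of features given a planted treatment effect,
#'   drawn independently per species.
#' @param treatment_ln_effect Planted effect on the natural-log scale applied
#'   to responsive features in treated samples (both doses).
#' @param species_ln_offset Global baseline offset (LN scale) added to the
#'   second species' features.
#' @param housekeeping_index Index of the feature designated as the Gapdh-like
#'   housekeeping gene; it receives a high stable baseline and zero effect.
#' @param line_sd Standard deviation of the per-feature, per-line lognormal
#'   random effect (LN scale).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_lines_per_species = 5L,
                           doses = c(0, 1, 10),
                           n_features = 2000L,
                           baseline_log_mean_range = c(log(50), log(2000)),
                           dispersion = 100,
                           frac_deg = 0.1,
                           treatment_ln_effect = log(4),
                           species_ln_offset = 0,
                           housekeeping_index = 1L,
                           line_sd = 0.3,
                           seed = 1L) {
  stopifnot(n_lines_per_species >= 1, n_features >= 2,
            0 %in% doses, any(doses > 0),
            dispersion > 0, frac_deg >= 0, frac_deg <= 1,
            housekeeping_index >= 1, housekeeping_index <= n_features,
            line_sd >= 0, length(baseline_log_mean_range) == 2,
            diff(baseline_log_mean_range) >= 0)
  if (frac_deg > 0 && treatment_ln_effect == 0)
    warning("frac_deg > 0 with treatment_ln_effect = 0: power is undefined")
  structure(list(n_lines_per_species = as.integer(n_lines_per_species),
                 doses = doses, n_features = as.integer(n_features),
                 baseline_log_mean_range = baseline_log_mean_range,
                 dispersion = dispersion, frac_deg = frac_deg,
                 treatment_ln_effect = treatment_ln_effect,
                 species_ln_offset = species_ln_offset,
                 housekeeping_index = as.integer(housekeeping_index),
                 line_sd = line_sd, seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate paired cross-species counts with planted effects
#'
#' Counts are negative binomial with mean
#' `exp(baseline + species offset + line effect + planted effect * treated)`.
#' The line effect is a per-feature random effect shared by all samples of a
#' cell line, which makes the within-line treated/control ratio more precise
#' than any between-line contrast; the housekeeping feature (named "Gapdh")
#' has planted effect exactly zero in both species and no line effect.
#'
#' @param spec A [count_sim_spec()].
#' @return List with elements `counts` (a [count_matrix()] over both
#'   species), `annotation` (feature_id, gene_symbol, cds_length_bp) and
#'   `truth` (feature_id, species, ln_effect).
#' @export
simulate_paired_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_features
  hk <- spec$housekeeping_index
  feature_id <- sprintf("gene%05d", seq_len(n))
  gene_symbol <- feature_id
  gene_symbol[hk] <- "Gapdh"
  feature_id[hk] <- "Gapdh"
  cds_length_bp <- 3L * sample(100:2000, n, replace = TRUE)

  baseline <- stats::runif(n, spec$baseline_log_mean_range[1],
                           spec$baseline_log_mean_range[2])
  baseline[hk] <- spec$baseline_log_mean_range[2]  # high, stable reference

  species <- c("Pleucopus", "Mmusculus")
  n_deg <- round(spec$frac_deg * n)
  candidates <- setdiff(seq_len(n), hk)
  effects <- matrix(0, n, 2, dimnames = list(feature_id, species))
  for (s in 1:2) {
    if (n_deg > 0) {
      idx <- sample(candidates, n_deg)
      effects[idx, s] <- spec$treatment_ln_effect
    }
  }

  n_samples <- 2L * spec$n_lines_per_species * length(spec$doses)
  counts <- matrix(0L, n, n_samples)
  meta <- vector("list", n_samples)
  col <- 0L
  for (s in 1:2) {
    sp_off <- if (s == 2) spec$species_ln_offset else 0
    for (l in seq_len(spec$n_lines_per_species)) {
      # per-feature line effect, shared by the line's control and treated
      # samples: cancels in within-line ratios (pairing is informative) but
      # inflates any between-line contrast
      line_eff <- stats::rnorm(n, 0, spec$line_sd)
      line_eff[hk] <- 0  # housekeeping gene is stable across lines too
      line_id <- sprintf("%s_L%d", substr(species[s], 1, 1), l)
      for (d in spec$doses) {
        col <- col + 1L
        mu <- exp(baseline + sp_off + line_eff + effects[, s] * (d > 0))
        counts[, col] <- stats::rnbinom(n, mu = mu, size = spec$dispersion)
        meta[[col]] <- data.frame(
          sample_id = sprintf("%s_d%g", line_id, d),
          species = species[s], cell_line = line_id,
          condition = if (d > 0) "agonist" else "control",
          dose_ug_per_ml = d, passage = 2L)
      }
    }
  }
  meta <- do.call(rbind, meta)
  dimnames(counts) <- list(feature_id, meta$sample_id)
  truth <- data.frame(
    feature_id = rep(feature_id, 2),
    species = rep(species, each = n),
    ln_effect = c(effects[, 1], effects[, 2]))
  list(counts = count_matrix(counts, meta),
       annotation = data.frame(feature_id = feature_id,
                               gene_symbol = gene_symbol,
                               cds_length_bp = cds_length_bp),
       truth = truth)
}

#' Specification for the ERV/TE sequence simulator
#'
#' Record lengths follow a log-normal law whose location parameter is solved
#' so that `P(length < 500) = frac_below_500`, mirroring reference sets in
#' which roughly 90 percent of raw repeat records are shorter than 500 bp;
#' lengths above `max_length_bp` are resampled. A chosen fraction of records
#' carries a planted open reading frame satisfying the Kozak-context
#' criteria (purine at -3, G at +4) by construction.
#'
#' @param n_records Number of ERV/TE records.
#' @param frac_below_500 Target fraction of raw lengths under 500 bp.
#' @param length_sdlog Log-scale standard deviation of the length law;
#'   the default 0.8326 gives a raw-law skewness near 4.
#' @param max_length_bp Upper bound on record length.
#' @param frac_with_planted_orf Fraction of records receiving a planted ORF
#'   (records must be at least `3 * planted_orf_codons + 7` bp to qualify).
#' @param planted_orf_codons Sense-codon count (ATG included, stop excluded)
#'   of planted ORFs; must be at least 30.
#' @param with_sequences Generate nucleotide sequences (disable for
#'   length-only analyses of large sets).
#' @param seed Integer seed.
#' @return A list of class `erv_sim_spec`.
#' @export
erv_sim_spec <- function(n_records = 10000L,
                         frac_below_500 = 0.90,
                         length_sdlog = 0.8326,
                         max_length_bp = 9600L,
                         frac_with_planted_orf = 0.05,
                         planted_orf_codons = 60L,
                         with_sequences = TRUE,
                         seed = 1L) {
  stopifnot(n_records >= 1, frac_below_500 > 0, frac_below_500 < 1,
            length_sdlog > 0, max_length_bp >= 500,
            frac_with_planted_orf >= 0, frac_with_planted_orf <= 1,
            planted_orf_codons >= 30)
  if (3 * planted_orf_codons + 7 > max_length_bp)
    stop("planted ORF needs ", 3 * planted_orf_codons + 7,
         " bp but max_length_bp is ", max_length_bp)
  structure(list(n_records = as.integer(n_records),
                 frac_below_500 = frac_below_500,
                 length_sdlog = length_sdlog,
                 max_length_bp = as.integer(max_length_bp),
                 frac_with_planted_orf = frac_with_planted_orf,
                 planted_orf_codons = as.integer(planted_orf_codons),
                 with_sequences = with_sequences,
                 seed = as.integer(seed)),
            class = "erv_sim_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate an ERV/TE record set with planted Kozak ORFs
#'
#' Background sequence is uniform random A/C/G/T. Planted ORFs are written
#' onto the plus or minus strand at a random admissible offset: a purine at
#' position -3, `ATG`, a `G` at +4, non-stop sense codons, then a stop codon,
#' so the scanner's predicate holds at the recorded coordinates by
#' construction. Minus-strand truth rows carry plus-strand-projected
#' start/end, matching [find_kozak_orfs()] output.
#'
#' @param spec An [erv_sim_spec()].
#' @return List with `records` (erv_id, chrom, start, end, strand, length_bp
#'   and, when sequences are generated, `sequence`) and `truth`
#'   (erv_id, strand, start, end, codon_count of each planted ORF).
#' @export
simulate_erv_set <- function(spec) {
  stopifnot(inherits(spec, "erv_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_records
  meanlog <- log(500) - stats::qnorm(spec$frac_below_500) * spec$length_sdlog
  len <- round(stats::rlnorm(n, meanlog, spec$length_sdlog))
  while (any(bad <- len > spec$max_length_bp | len < 1))
    len[bad] <- round(stats::rlnorm(sum(bad), meanlog, spec$length_sdlog))
  erv_id <- sprintf("erv%06d", seq_len(n))
  chrom <- sample(sprintf("chr%d", 1:20), n, replace = TRUE)
  start <- sample.int(1e8L, n, replace = TRUE)
  records <- data.frame(erv_id = erv_id, chrom = chrom, start = start,
                        end = start + len,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        length_bp = as.integer(len))

  truth <- data.frame(erv_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      codon_count = integer())
  if (spec$with_sequences) {
    seqs <- vapply(len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    n_plant <- round(spec$frac_with_planted_orf * n)
    if (n_plant > 0) {
      need <- 3L * spec$planted_orf_codons + 7L
      eligible <- which(len >= need)
      if (length(eligible) < n_plant)
        stop("only ", length(eligible), " records of >= ", need,
             " bp are eligible to host a planted ORF; ", n_plant, " requested")
      host <- sample(eligible, n_plant)
      truth <- vector("list", n_plant)
      for (k in seq_along(host)) {
        i <- host[k]
        planted <- plant_kozak_orf(seqs[i], spec$planted_orf_codons)
        seqs[i] <- planted$seq
        truth[[k]] <- data.frame(erv_id = erv_id[i], strand = planted$strand,
                                 start = planted$start, end = planted$end,
                                 codon_count = spec$planted_orf_codons)
      }
      truth <- do.call(rbind, truth)
      truth <- truth[order(truth$erv_id), , drop = FALSE]
      rownames(truth) <- NULL
    }
    records$sequence <- seqs
  }
  list(records = records, truth = truth)
}

# Write one Kozak-compliant ORF into `seq` on a random strand at a random
# admissible position. Returns the modified sequence plus the hit's
# plus-strand-projected coordinates (the convention of find_kozak_orfs).
plant_kozak_orf <- function(seq, codons) {
  L <- nchar(seq)
  strand <- sample(c("+", "-"), 1)
  S <- if (strand == "+") seq else reverse_complement(seq)
  # A of ATG at p; need 3 upstream bases and 3*(codons+1) bases from p on
  p <- sample(4:(L - 3 * (codons + 1) + 1), 1)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste,
                         collapse = ""), STOP_CODONS)
  codon2 <- paste0("G", paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                              collapse = ""))  # G at +4; G?? is never a stop
  body <- if (codons > 2)
    paste(sample(sense, codons - 2, replace = TRUE), collapse = "") else ""
  orf <- paste0("ATG", codon2, body, sample(STOP_CODONS, 1))
  upstream <- paste0(sample(c("A", "G"), 1),
                     paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                           collapse = ""))
  S <- paste0(substr(S, 1, p - 4), upstream, orf,
              substr(S, p + 3 * (codons + 1), L))
  stopifnot(nchar(S) == L)
  end_s <- p + 3 * (codons + 1) - 1  # last base of stop codon, scanned strand
  if (strand == "+") {
    list(seq = S, strand = strand, start = p, end = end_s)
  } else {
    list(seq = reverse_complement(S), strand = strand,
         start = L - end_s + 1, end = L - p + 1)
  }
}
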