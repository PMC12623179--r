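test_that("reverse complement maps IUPAC codes and is an involution", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement("AN"), "NT")
  expect_identical(reverse_complement("RYSWKM"), "KMWSRY")
  set.seed(1)
  s <- random_dna(500, c("A", "C", "G", "T", "N", "R", "Y"))
  expect_identical(reverse_complement(reverse_complement(s)), s)
  expect_error(reverse_complement("ACXT"), "position 3")
})

test_that("constructed Kozak examples hit or miss exactly as specified", {
  core <- paste(rep("GCT", 29), collapse = "")
  ok <- paste0("C", "AAA", "ATG", core, "TAA")
  h <- find_kozak_orfs(ok, min_codons = 30)
  expect_identical(nrow(h), 1L)
  expect_identical(h$codon_count, 30L)
  expect_identical(h$minus3_base, "A")
  expect_identical(h$plus4_base, "G")
  expect_identical(h$peptide, paste0("M", strrep("A", 29)))
  expect_identical(h$start, 5L)
  expect_identical(h$end - h$start + 1L, 3L * (h$codon_count + 1L))

  # pyrimidine at -3 disqualifies the start
  expect_identical(nrow(find_kozak_orfs(
    paste0("C", "CCT", "ATG", core, "TAA"), min_codons = 30)), 0L)
  # 29 codons miss the threshold
  expect_identical(nrow(find_kozak_orfs(
    paste0("C", "AAA", "ATG", paste(rep("GCT", 28), collapse = ""), "TAA"),
    min_codons = 30)), 0L)
  # fewer than 3 upstream bases disqualifies without erroring
  expect_identical(nrow(find_kozak_orfs(
    paste0("AA", "ATG", core, "TAA"), min_codons = 30)), 0L)
  # no in-frame stop: rejected unless stop-less ORFs are admitted
  stopless <- paste0("C", "AAA", "ATG", core)
  expect_identical(nrow(find_kozak_orfs(stopless, min_codons = 30)), 0L)
  expect_identical(find_kozak_orfs(stopless, min_codons = 30,
                                   require_stop = FALSE)$codon_count, 30L)
  # an N inside the candidate ORF rejects and counts it
  withN <- paste0("C", "AAA", "ATG", "GCN",
                  paste(rep("GCT", 28), collapse = ""), "TAA")
  hN <- find_kozak_orfs(withN, min_codons = 30)
  expect_identical(nrow(hN), 0L)
  expect_identical(attr(hN, "n_rejected"), 1L)
})

test_that("scanner equals the brute-force enumerator on random sequences", {
  set.seed(42)
  for (i in 1:12) {
    s <- random_dna(1200)
    for (mode in c("all_starts", "maximal")) {
      got <- find_kozak_orfs(s, min_codons = 10, mode = mode)
      want <- oracle_kozak(s, min_codons = 10, mode = mode)
      expect_identical(orf_key(got), orf_key(want))
    }
  }
})

test_that("strand symmetry: hits on revcomp are the strand-swapped hits", {
  set.seed(43)
  for (i in 1:6) {
    s <- random_dna(900)
    a <- find_kozak_orfs(s, min_codons = 8, mode = "all_starts")
    b <- find_kozak_orfs(reverse_complement(s), min_codons = 8,
                         mode = "all_starts")
    L <- nchar(s)
    flipped <- data.frame(strand = ifelse(b$strand == "+", "-", "+"),
                          start = L - b$end + 1L, end = L - b$start + 1L,
                          codon_count = b$codon_count)
    flipped <- flipped[order(flipped$strand, flipped$start, flipped$end), ]
    expect_identical(orf_key(a), orf_key(flipped))
  }
})

test_that("every reported hit re-validates against the raw sequence", {
  set.seed(44)
  s <- random_dna(3000)
  hits <- find_kozak_orfs(s, min_codons = 5, mode = "all_starts")
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$codon_count >= 5))
  expect_true(all(hits$minus3_base %in% c("A", "G")))
  expect_true(all(hits$plus4_base == "G"))
  expect_true(all(nchar(hits$peptide) == hits$codon_count))
  expect_true(all(hits$end - hits$start + 1 == 3 * (hits$codon_count + 1)))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    region <- substr(s, h$start, h$end)
    if (h$strand == "-") region <- reverse_complement(region)
    expect_identical(substr(region, 1, 3), "ATG")
    expect_true(substr(region, nchar(region) - 2, nchar(region)) %in%
                c("TAA", "TAG", "TGA"))
    expect_identical(translate(region), h$peptide)
  }
  # maximal-mode hits are a subset of all-starts hits
  mx <- find_kozak_orfs(s, min_codons = 5, mode = "maximal")
  expect_true(all(orf_key(mx) %in% orf_key(hits)))
})

test_that("translation follows the standard code and stop conventions", {
  expect_identical(translate("ATGGCTTAA"), "MA")
  expect_error(translate("ATGTAAGCT"), "codon index 2")
  expect_identical(translate("ATGTAAGCT", check_internal_stop = FALSE),
                   "M*A")
  expect_error(translate("ATGC"), "multiple of 3")
  expect_error(translate("ATGNNN"), "untranslatable")
  # a 1,983-nt CDS free of stops encodes a 661-aa polypeptide
  set.seed(45)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1,
                         paste, collapse = ""), c("TAA", "TAG", "TGA"))
  cds <- paste(c("ATG", sample(sense, 660, replace = TRUE)), collapse = "")
  cds <- substr(cds, 1, 1983)
  expect_identical(nchar(translate(cds)), 661L)
})

test_that("ORF length summaries match direct computation", {
  one <- data.frame(parent_id = "p1", codon_count = 30)
  s1 <- orf_length_summary(one)
  expect_equal(s1$mean_aa, 30)
  expect_equal(s1$range_aa, c(30, 30))

  two <- data.frame(parent_id = c("p1", "p2"), codon_count = c(30, 90))
  expect_equal(orf_length_summary(two)$mean_aa, 60)

  set.seed(46)
  lens <- sample(30:500, 40, replace = TRUE)
  hits <- data.frame(parent_id = sample(paste0("p", 1:10), 40,
                                        replace = TRUE),
                     codon_count = lens)
  s <- orf_length_summary(hits, parents = paste0("p", 1:12))
  expect_equal(s$mean_aa, mean(lens))
  se <- sd(lens) / sqrt(40)
  expect_equal(s$ci95, mean(lens) + c(-1, 1) * qt(0.975, 39) * se,
               tolerance = 1e-12)
  expect_equal(sum(s$per_parent), 40L)
  expect_equal(s$frac_parents_with_hit,
               length(unique(hits$parent_id)) / 12)

  s0 <- orf_length_summary(hits[0, ], parents = c("p1", "p2"))
  expect_true(is.na(s0$mean_aa))
  expect_equal(s0$frac_parents_with_hit, 0)
})
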