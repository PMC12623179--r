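#!/usr/bin/env Rscript
# Stage 5: the two stand-alone calculators. Doubling times from log-linear
# growth fits at the rates observed for early-passage mouse (~28 h),
# early-passage deermouse (~56 h) and transformed deermouse (~14 h)
# cultures; and peptide coverage of a protein by a set of identified
# tryptic peptides.

suppressMessages(library(crossfibro))
dir.create("results", showWarnings = FALSE)

set.seed(20260926)
rows <- list()
for (dt in c(mouse_P2 = 28, deermouse_P2 = 56, deermouse_P47 = 14)) {
  t_days <- c(0, 1, 2, 4, 6)
  density <- 1e4 * 2^(t_days * 24 / dt) * exp(rnorm(5, 0, 0.02))
  est <- doubling_time(t_days, density)
  rows[[length(rows) + 1]] <- data.frame(
    culture = names(which(c(mouse_P2 = 28, deermouse_P2 = 56,
                            deermouse_P47 = 14) == dt)),
    true_doubling_h = dt, estimated_doubling_h = est$doubling_time_h,
    r_squared = est$r_squared)
  cat(sprintf("%s: planted %d h, estimated %.1f h (R^2 %.4f)\n",
              rows[[length(rows)]]$culture, dt, est$doubling_time_h,
              est$r_squared))
}
utils::write.table(do.call(rbind, rows), "results/doubling_times.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# peptide coverage demo: three synthetic tryptic peptides of a 106-aa
# protein (a synthetic stand-in for a processed secreted protein)
set.seed(1)
protein <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 106,
                        replace = TRUE), collapse = "")
peptides <- c(substr(protein, 5, 20), substr(protein, 40, 53),
              substr(protein, 80, 99))
cov <- peptide_coverage(protein, peptides)
cat(sprintf("peptide coverage: %d peptides cover %.0f%% of %d aa\n",
            length(peptides), 100 * cov$coverage, nchar(protein)))
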