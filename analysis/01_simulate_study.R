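#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a paired 2-species x
# {control, 1, 10 ug/mL} fibroblast exposure with 5 cell lines per species
# and a stable Gapdh-like housekeeping gene, plus an ERV/TE reference set
# with a right-skewed length law and planted Kozak ORFs. Writes the count
# matrix, metadata, annotation and truth tables that later stages re-read.

suppressMessages(library(crossfibro))
dir.create("results/simdata", recursive = TRUE, showWarnings = FALSE)

seed <- 20260926

counts_spec <- count_sim_spec(n_features = 2000, frac_deg = 0.1,
                              treatment_ln_effect = log(4), seed = seed)
sim <- simulate_paired_counts(counts_spec)
write_counts(sim$counts, "results/simdata/counts.tsv",
             "results/simdata/sample_meta.tsv")
utils::write.table(sim$annotation, "results/simdata/annotation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth, "results/simdata/truth_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("counts: %d features x %d samples; %d planted effects/species\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            sum(sim$truth$ln_effect > 0) / 2))

erv_spec <- erv_sim_spec(n_records = 3000, frac_with_planted_orf = 0.02,
                         planted_orf_codons = 60, seed = seed)
erv <- simulate_erv_set(erv_spec)
write_erv_table(erv$records[, setdiff(names(erv$records), "sequence")],
                "results/simdata/erv_intervals.tsv")
write_fasta(setNames(erv$records$sequence, erv$records$erv_id),
            "results/simdata/erv_sequences.fa")
utils::write.table(erv$truth, "results/simdata/truth_orfs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ERV set: %d records, %.1f%% under 500 bp, %d planted ORFs\n",
            nrow(erv$records),
            100 * mean(erv$records$length_bp < 500), nrow(erv$truth)))
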