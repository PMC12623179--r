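#!/usr/bin/env Rscript
# Stage 2: within-species paired differential expression and the
# cross-species comparison. Counts are normalized by total reads and
# adjusted per kb for the paired fold-change/t-test analysis; the Gapdh
# ratio is applied on top for the cross-species table. DEGs are called at
# FC >= 2 or <= 0.5 with paired p < 0.001, and species specificity at a
# tenfold fold-change difference.

suppressMessages(library(crossfibro))
stopifnot(file.exists("results/simdata/counts.tsv"))  # run 01 first

cm <- read_counts("results/simdata/counts.tsv",
                  "results/simdata/sample_meta.tsv")
annot <- utils::read.delim("results/simdata/annotation.tsv")
truth <- utils::read.delim("results/simdata/truth_counts.tsv")

nm <- per_kb_adjust(total_count_normalize(cm), annot)
tpm_mat <- tpm(cm, annot)
expressed <- expression_filter(tpm_mat, threshold = 10, scope = "mean")
cat(sprintf("expressed universe (mean TPM >= 10): %d of %d features\n",
            length(expressed), nrow(cm$counts)))

deg_by_species <- list()
for (sp in c("Pleucopus", "Mmusculus")) {
  pm <- paired_design_matrices(nm, cm$meta, sp, dose = 1)
  deg <- suppressMessages(
    paired_deg(pm$treated[expressed, ], pm$control[expressed, ]))
  deg_by_species[[sp]] <- deg
  planted <- subset(truth, species == sp & ln_effect > 0)$feature_id
  cat(sprintf(
    "%s: %d up / %d down DEGs; %.1f%% of planted effects recovered\n",
    sp, attr(deg, "n_up"), attr(deg, "n_down"),
    100 * mean(intersect(planted, expressed) %in%
               deg$feature_id[deg$call == "up"])))
  utils::write.table(deg, sprintf("results/deg_%s.tsv", sp),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# cross-species table on the Gapdh-ratio scale, per condition
gr <- gapdh_ratio(nm)
meta <- cm$meta
xs <- list()
for (cond in c(0, 1)) {
  P <- unclass(gr)[, meta$species == "Pleucopus" &
                     meta$dose_ug_per_ml == cond, drop = FALSE]
  M <- unclass(gr)[, meta$species == "Mmusculus" &
                     meta$dose_ug_per_ml == cond, drop = FALSE]
  tab <- cross_species_ratio(P, M, pseudocount = 1e-6)
  names(tab)[2:3] <- paste0(c("ratio_PM_", "p_"),
                            if (cond == 0) "control" else "treated")
  xs[[length(xs) + 1]] <- tab
}
xspecies <- merge(xs[[1]], xs[[2]], by = "gene")
spec_call <- classify_specificity(deg_by_species$Pleucopus$fc,
                                  deg_by_species$Mmusculus$fc)
xspecies$specificity <-
  as.character(spec_call)[match(xspecies$gene,
                                deg_by_species$Pleucopus$feature_id)]
utils::write.table(xspecies, "results/cross_species_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cross-species table: %d genes, %d species-specific responses\n",
            nrow(xspecies),
            sum(xspecies$specificity != "shared", na.rm = TRUE)))

# housekeeping stability on the count scale
raw <- paired_design_matrices(cm$counts, cm$meta, "Pleucopus", dose = 1)
gfc <- paired_fold_change(raw$treated["Gapdh", , drop = FALSE],
                          raw$control["Gapdh", , drop = FALSE], 0.5)
cat(sprintf("Gapdh paired FC (deermouse, 1 ug/mL): %.3f\n", gfc$fc))
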