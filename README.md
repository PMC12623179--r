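# crossfibro

Cross-species comparison of dermal fibroblast transcriptome responses to a
Toll-like receptor agonist, for the paired design used in comparative
studies of the white-footed deermouse *Peromyscus leucopus* (an
infection-tolerant zoonosis reservoir) and the house mouse *Mus musculus*:
each animal contributes one cell line, split into untreated and
lipopeptide-treated cultures.

The package implements, with tests, every stage of that analysis:

* **Cross-species normalization chain** — counts normalized by total reads,
  adjusted for CDS length as reads per kb, then expressed as the ratio to
  the housekeeping gene Gapdh in the same sample, making values comparable
  across species and annotations. TPM and TMM (edgeR) factors for the
  within-species analyses.
* **Paired differential expression** — per-line treated/control ratios;
  FC = geometric mean of per-line ratios so that
  ln FC = mean per-line LN ratio; one-sample t of the LN ratios against 0;
  Benjamini–Hochberg FDR over defined p-values; DEG calls at FC ≥ 2 or
  ≤ 0.5 with p < 0.001; species-specific responses at a ≥ 10× fold-change
  difference between species.
* **ERV/TE analyses** — ≥ 500 bp length filter, length/TPM Z-scores
  against the complete reference set, adjusted Fisher–Pearson skewness,
  top-k expression subsets, passage contrasts, and OLS regression of mean
  TPM on length with 95% confidence (LCL/UCL) and prediction (LPL/UPL)
  bands.
* **Kozak-context ORF scanner** — six-frame scan for ORFs with an ATG
  start (A at +1), ≥ 30 codons, a purine at −3 and G at +4, verified
  against a brute-force enumerator and a strand-symmetry bijection.
* **Synthetic data generators** — negative-binomial paired counts with
  planted LN effects and a stable housekeeping gene; ERV record sets with
  a right-skewed (log-normal) length law and planted Kozak-compliant ORFs
  — so the whole pipeline runs and is tested without any external data.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 1 simulates
the study (2 species × 5 lines × {0, 1, 10} µg/mL, 2,000 features, 10%
planted fourfold effects; 3,000 ERV records with 60 planted ORFs); later
stages re-read its TSV output:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_species_deg.R
```

```
expressed universe (mean TPM >= 10): 2000 of 2000 features
Pleucopus: 192 up / 0 down DEGs; 96.0% of planted effects recovered
Mmusculus: 195 up / 0 down DEGs; 97.5% of planted effects recovered
cross-species table: 2000 genes, 0 species-specific responses
Gapdh paired FC (deermouse, 1 ug/mL): 1.095
```

About 96–98% of the 200 planted per-species effects are recalled at the
joint thresholds with no false calls (all planted effects are positive,
hence no down-DEGs); the housekeeping gene, planted with zero effect,
shows a paired fold change near 1; and no response differs ≥ 10× between
species because the generator plants the same effect size in both — the
specificity classifier correctly returns "shared" everywhere.

```sh
Rscript analysis/03_erv_lengths.R
Rscript analysis/04_orf_scan.R
```

```
length filter: 90.6% of 3000 records excluded under 500 bp
filtered lengths: median 673 bp (IQR 574-915), skewness 3.00
...
planted ORF recovery (all-starts mode): 100% of 60
peptides: mean 46 aa (95% CI 45-48), range 30-195; 14.3% of parents hit
```

The length law is calibrated so the ≥ 500 bp filter removes ~90% of
records and leaves a strongly right-skewed distribution; every planted ORF
is recovered at its exact coordinates, and the background hits are the
chance ORFs expected in random sequence.

In code, the core steps are:

```r
library(crossfibro)
sim <- simulate_paired_counts(count_sim_spec(seed = 1))
nm  <- per_kb_adjust(total_count_normalize(sim$counts), sim$annotation)
pm  <- paired_design_matrices(nm, sim$counts$meta, "Pleucopus", dose = 1)
deg <- paired_deg(pm$treated, pm$control)      # fc, ln_ratio, p, q, call
gr  <- gapdh_ratio(nm)                         # cross-species scale
hits <- find_kozak_orfs("CAAAATG...", min_codons = 30)
```

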