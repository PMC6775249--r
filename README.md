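# sncpipe

Analysis pipeline for small non-coding RNA sequencing studies of **5' tRNA
halves** and **5' YRNA fragments** — ~30-34 nt species cleaved from the 5'
end of tRNA and Y RNA genes that circulate in serum and shift in abundance
with disease, making them attractive minimally invasive biomarkers. The
package is aimed at researchers analyzing small RNA-seq from case/control
serum cohorts and matched tumor/normal tissue who want the complete path
from aligned reads to functional inference in one tested toolchain.

## What it computes

1. **Fragment profiling** — counts reads that are 30-34 nt long, on the
   locus strand, and anchored (within a configurable tolerance, default
   0 nt) at the gene's biological 5' terminus, per locus per sample. A read
   matching several identical paralogs counts toward each. Rejections are
   tallied by reason and conserved: assigned + rejected = input.
2. **Differential abundance** — negative binomial counts
   (Var = mu + phi mu^2, BCV = sqrt(phi)) with TMM normalization, Cox-Reid
   adjusted profile-likelihood dispersion estimation with empirical-Bayes
   tagwise shrinkage, the conditional **exact test** for unpaired (serum)
   designs, a patient-blocked NB **likelihood-ratio test** for paired
   (tumor/normal) designs, BH FDR (significant = FDR < 5%), and
   leading-log-fold-change MDS diagnostics.
3. **Coexpression modules** — over the pooled miRNA + fragment matrix:
   unsigned soft-threshold adjacency a_ij = |cor|^beta (beta = 6),
   topological overlap, average-linkage clustering with an adaptive branch
   cut (deepSplit 3, minimum module size 10, unassigned = grey), module
   eigengenes, module membership (kME), trait gene significance, and
   module-trait correlations.
4. **miRNA overtargeting** — for the top-10 module miRNAs, the upper-tail
   hypergeometric probability that each gene in a strong-evidence
   miRNA-target universe receives at least its observed number of
   interactions, BH over tested genes, a random-set empirical null for the
   module-level overtargeted-gene count, SIF/GraphML network export, and
   hypergeometric term enrichment.
5. **qPCR relative quantification** — 2^-ddCt fold changes against a
   housekeeping reference and control group, Student's t-test on log folds.
6. **Synthetic data** — generators for every input (reads, annotations,
   count matrices, pooled expression with planted modules, interaction
   universes with planted overtargeted genes, Ct tables) with truth tables,
   so the full pipeline runs and is validated offline.

## Worked example

```r
library(sncpipe)

cfg <- sim_config(seed = 1, n_features = 2000, de_fraction = 0.1, de_fold = 6)
sim <- simulate_counts(cfg)              # 5 vs 5 serum-style NB counts
de  <- run_exact_de(sim$counts, sim$groups)
sig <- significant_set(de$table, 0.05)
de$dispersion$bcv                        # 0.32  (true BCV sqrt(0.1) = 0.316)
nrow(sig)                                # 201 features at FDR < 5%
head(sig, 5)
#>     feature avg_cpm log2fc fc_display        p      fdr
#> 1 feat_0080     824   3.01       8.06 3.45e-31 6.89e-28
#> 2 feat_0039     789   3.31       9.95 6.15e-30 4.25e-27
#> 3 feat_1309     429   3.00       7.98 7.34e-30 4.25e-27
#> 4 feat_0915    5193   2.87       7.31 8.50e-30 4.25e-27
#> 5 feat_1713     855  -2.89      -7.43 2.87e-29 1.15e-26
```

The table mirrors the conventional report layout: average CPM over all
libraries, log2 fold change, the signed display fold change (a 7.4-fold
decrease prints as -7.43), p, and FDR. Against the generator's truth table
this run recovers 96.5% of the planted 6-fold features with an observed
FDR of 4%.

The whole pipeline (profile -> DE -> coexpression -> overtargeting ->
enrichment -> qPCR) runs from one config:

```r
report <- run_pipeline(default_pipeline_config(seed = 42), "out/")
```

or from a shell via the bundled front-end:

```sh
Rscript exec/sncpipe run --seed 42 --out out/
```

Every output table is TSV with a config-hash header; `report.json` records
seeds, parameters, per-stage counts. Identical configs reproduce all
stochastic stages bit-identically.

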