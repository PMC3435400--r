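# methsig

Discovery of cell-type-specific and disease-associated DNA methylation
signatures from two-colour CpG bead-array panels (GoldenGate-type arrays).

## The scientific problem

Matched-tissue methylation studies ask two questions at once: which CpG
sites distinguish one cell type from another regardless of disease (a
*cell-type signature*), and which sites differ between disease phenotypes
within a cell type.  The motivating design is a paediatric airway study:
airway epithelial cells (AECs, from bronchial brushings) and peripheral
blood mononuclear cells (PBMCs) from the same children, grouped as
healthy, atopic, atopic-asthmatic or non-atopic-asthmatic, assayed on a
1505-probe CpG cancer panel where each probe reports a methylated (Cy5)
and an unmethylated (Cy3) channel intensity plus a detection p-value.

`methsig` implements the complete analysis chain for such data:

1. **Probe filtering** — X-chromosome probes, SNP-containing probes, and
   probes with detection p > 0.05 in more than 10% of samples are removed
   sequentially with single counting.
2. **KNN imputation** — remaining detection-failed entries are completed
   by inverse-distance-weighted K-nearest-neighbour imputation (k = 10).
3. **Background and colour-bias correction** — per-sample 5th-percentile
   background subtraction (floored at 1) and a per-sample monotone
   quantile mapping of Cy5 onto Cy3.
4. **M-values** — M = log2((Cy5 + 1) / (Cy3 + 1)); positive M means more
   methylated.
5. **DWD batch adjustment** — distance-weighted discrimination
   (minimise Σᵢ 1/rᵢ + C Σᵢ ξᵢ subject to rᵢ = yᵢ(w·xᵢ + b) + ξᵢ > 0,
   ξᵢ ≥ 0, ‖w‖ ≤ 1) fits a direction between batches; each batch is
   rigidly translated along it so batch means coincide.
6. **z-scoring** — each sample column is standardised to mean 0, sd 1.
7. **Differential calling** — per-CpG Welch (or paired) t-tests, Storey
   q-values with smoother π₀ estimation, and the dual rule:
   a site is called iff **q ≤ 0.05 and |z-score difference| ≥ 2**
   (equivalently ≥ 1 on the signed log2 axis used in volcano plots).
8. **Signatures** — called sets per comparison with per-site methylation
   direction, three-way Venn decomposition into core/unique/pairwise
   regions, and right-tailed hypergeometric (Fisher) enrichment against a
   user-supplied gene → function annotation, with the analysed panel
   itself as the reference universe.

A synthetic-data generator (`simulate_dataset()`) emulates the full study
design — matched AEC/PBMC samples, the panel's probe categories, ~0.5%
detection failures, batch structure, and injected methylation-state
switches — and returns a ground-truth table, so every stage is verifiable
without any data download.

## Worked example

```r
library(methsig)
sim <- simulate_dataset(sim_config(seed = 11))   # full study-design emulation
run <- run_pipeline(sim$dataset)
print(run)
```

```
Methylation-signature pipeline run
Probe filter report
  input probes        : 1505
  removed X chromosome: 84
  removed SNP-in-probe: 272
  removed detection   : 0 (p > 0.05 in > 10% of samples)
  retained            : 1149
  asthma subgroups merged: TRUE
  comparisons run: 12 (skipped: 0)
    aec_asthma_subtypes             0 called
    pbmc_asthma_subtypes            0 called
    celltype_all                   80 called
    celltype_healthy               80 called
    celltype_atopic                80 called
    celltype_asthmatic             88 called
    aec_healthy_vs_atopic           0 called
    aec_healthy_vs_asthmatic        8 called
    aec_atopic_vs_asthmatic         8 called
    pbmc_healthy_vs_atopic          0 called
    pbmc_healthy_vs_asthmatic       0 called
    pbmc_atopic_vs_asthmatic        0 called
  Venn core: 80 CpGs; unique per set: 0/0/8
```

Reading the output: the generator planted 80 cell-type-differential
probes and 8 asthma-associated probes in AECs.  The pipeline recovers all
80 in every AEC-vs-PBMC comparison (the cell-type signature, shared
across phenotypes — the Venn core), finds no difference between the two
asthma subtypes (so they are merged into one asthmatic group before the
phenotype comparisons), recovers the 8 planted asthma sites in the AEC
phenotype comparisons, and calls nothing in PBMCs, where no effect was
planted.  Per-comparison detail:

```r
summary(run$results$aec_atopic_vs_asthmatic)
#> Comparison aec_atopic_vs_asthmatic: atopic vs asthmatic — 8/1149 probes called (pi0 = 0.836)
#>        probe_id        target_id    z_diff z_diff_log2      q_value
#> 426  probe00782 GENE0391_E1423_R -2.539841   -1.344738 7.072692e-11
#> 276  probe00632 GENE0316_E1495_R -2.575890   -1.365071 9.699571e-11
#> ...
```

Negative `z_diff` means less methylated in the first-named group (atopic)
than in the second (asthmatic); `z_diff_log2 = sign(z)·log2|z|` is the
volcano-plot x-axis, so the raw threshold 2 sits at ±1.

`run_pipeline(ds, out_dir = "run1")` additionally writes every
intermediate matrix, per-comparison TSVs, volcano/heatmap exports,
`venn_counts.tsv`, a plain-text log and a JSON run manifest with
provenance hashes; re-running is bit-identical.

Real array data enter through `read_dataset()` (tab-separated manifest,
long-form intensities, sample sheet; see `?read_dataset`).  The counts
published for the deposited study (GEO accession GSE37853) are available
via `reference_results_gse37853()` for validating a converted copy of the
accession; they are properties of the real arrays and are not expected
from synthetic data.

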