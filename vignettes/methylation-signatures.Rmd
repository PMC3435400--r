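---
title: "Methylation signature discovery from two-colour CpG panels: models and choices"
author: "methsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation signature discovery from two-colour CpG panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsig)
```

## The measurement model

A GoldenGate-type methylation panel interrogates a fixed set of CpG sites
(here, 1505 probes across ~800 genes).  Each probe on each sample yields
two intensities — Cy5 for the methylated allele, Cy3 for the unmethylated
allele — and a detection p-value, the probability that the signal is
indistinguishable from background.  Two derived scales are standard:

* the **beta-value** `beta = Cy5 / (Cy5 + Cy3)` in [0, 1], the
  methylated proportion, bimodal on real arrays (most promoter CpGs are
  either mostly unmethylated or mostly methylated);
* the **M-value** `M = log2((Cy5 + 1) / (Cy3 + 1))`, the symmetric
  log-ratio scale on which differences are approximately additive and
  variance is better behaved.  The +1 offsets keep M finite at zero
  intensity.

All testing in this package happens on per-sample z-scores of M-values,
so a group difference is expressed in units of the per-sample M-value
spread ("z-score difference").

## The analysis chain and its rationale

1. **Filtering.** X-chromosome probes are removed to avoid sex bias, then
   SNP-containing probes (a polymorphism under the probe confounds the
   methylation signal), then probes with detection p > `detection_alpha`
   (0.05) in strictly more than `max_fail_frac` (10%) of samples.  The
   categories are applied sequentially with single counting, so the
   report always partitions the input panel.  "More than 10%" is a strict
   inequality: a probe failing in exactly 10% of samples is kept.
2. **Imputation.** Surviving detection-failed entries are completed by
   KNN: neighbours are the k = 10 probes closest in Euclidean distance
   over co-observed samples, combined by inverse-distance weights; an
   exact duplicate row is copied outright.  By default imputation runs on
   the M-value scale *after* intensity corrections and batch adjustment
   (`impute_stage = "post"`), because Euclidean distances on a log-ratio
   scale are not dominated by overall intensity; the literal
   impute-first order is available as `impute_stage = "pre"` (on raw
   intensities).  Neither order is asserted as the historical
   computation; both are tested.
3. **Background.** Vendor negative-control probes are not part of the
   interchange format, so the background estimate is the per-sample,
   per-channel 5th percentile, subtracted and floored at 1 — a
   deterministic, documented surrogate that preserves probe order within
   a channel.
4. **Colour bias.** The two dyes differ systematically in brightness.
   Per sample, the Cy5 channel is monotonically rescaled so its empirical
   quantiles equal the Cy3 channel's (rank r of Cy5 receives the value at
   rank r of Cy3).  This is a strong form of dye correction: it equalises
   the whole marginal distribution, which compresses extreme M-values
   somewhat (see "What the generator shows" below) but requires no
   control probes and is exactly invertible in rank terms.
5. **Batch adjustment (DWD).** Distance-weighted discrimination fits a
   separating direction between two batches by minimising the sum of
   inverse margins plus a slack penalty over the unit ball.  Profiling
   out the slacks gives the convex, continuously differentiable loss
   `V(m) = 1/m` for `m >= 1/sqrt(C)`, else `2*sqrt(C) - C*m`, which a
   projected-gradient solver minimises to the global optimum (the
   `backend` field records `"gradient"`; an exact conic solve would be
   admissible where a second-order-cone solver is available).  Every
   sample keeps a nonzero pull on the direction — the property that makes
   DWD stable when samples are few and probes many.  Adjustment
   translates each batch rigidly along the fitted direction to the pooled
   mean projection, so within-batch geometry is untouched; with more
   than two batches, batches are merged sequentially in order of first
   appearance.  The default penalty is the scale-invariant heuristic
   `C = 100 / median²` of between-class pairwise distances.  Batch labels
   are caller-supplied (chip, plate, run date — whatever the design
   says); a batch perfectly confounded with the comparison of interest
   triggers a warning because adjustment would then remove signal.
6. **Standardisation.** Each sample column is z-scored (n−1 denominator;
   the convention is stated because nothing in the upstream definitions
   forces it).  A constant column is an error naming the sample.
7. **Testing and calling.** Per CpG, a two-sided Welch t-test (unpaired
   default) or a one-sample t on within-subject differences (`paired`);
   pairing is a flag because a matched design admits both analyses and
   the choice is not forced.  A probe with zero variance in both groups
   reports t = 0, p = 1 and a degeneracy flag rather than an error.
   Multiplicity is handled by Storey q-values: π₀ is estimated on the
   grid λ = 0, 0.05, …, 0.90 via `#{p > λ} / (m(1−λ))`, smoothed by a
   cubic spline (df = 3) and read off at the largest λ, clipped to
   (0, 1]; if the smoother leaves (0, 1] the estimate falls back to
   π₀ = 1, in which case q-values equal Benjamini–Hochberg exactly (a
   tested identity).  Each comparison's q-values are computed over
   exactly the probes tested in that comparison, never pooled.  A site is
   called iff `q <= 0.05` **and** `|z_diff| >= 2`.  The reporting axis is
   `z_diff_log2 = sign(z)·log2|z|`, on which the threshold is ±1.  The
   raw-scale reading of the threshold is the only one consistent with
   published tables whose log2 magnitudes are ~1.0–1.3 (raw 2.0–2.5).
   Note the signed-log2 map also exceeds 1 in magnitude for |z| ≤ 0.5;
   the faithful threshold equivalence is `|z| >= 2  <=>  sign(z)·z_diff_log2 >= 1`,
   and `z_diff = 0` is recorded as 0 with a degeneracy flag since
   `log2(0)` is undefined.
8. **Comparison plan.** The default plan first compares the two asthma
   subtypes within each cell type; iff *zero* sites are called in both,
   the subtypes are merged into one asthmatic group
   (`grouped_asthma_check()` — data-driven, not hard-coded).  Then: AEC
   vs PBMC over all subjects and within each phenotype; every phenotype
   pair within each cell type.  Comparisons with fewer than two samples
   per group are skipped and logged.
9. **Signatures and enrichment.** A comparison's called set, with
   per-site direction (`more_methylated` = positive z-difference in the
   first-named group), is a signature; the three per-phenotype cell-type
   signatures are Venn-decomposed into the disease-independent core, the
   per-phenotype unique sites, and pairwise regions.  Enrichment is the
   right tail of the hypergeometric distribution (Fisher's exact test)
   per function label, with genes deduplicated (a gene with several
   called CpGs counts once) and the analysed panel's own genes as the
   reference universe — using the panel as its own reference avoids
   enrichment being driven by the panel's gene composition (a cancer
   panel would otherwise "enrich" cancer pathways in any signature).
   Raw p-values are reported (as −log10 p), matching the way such
   analyses are usually published; a BH adjustment flag exists.

## The synthetic test bed

`simulate_dataset()` emulates the study design so every stage has ground
truth:

* **Cohort**: 25 subjects (7 healthy, 9 atopic, 4 atopic-asthmatic, 5
  non-atopic-asthmatic), each contributing one AEC and one PBMC sample;
  two processing batches assigned round-robin over subjects.
* **Panel**: 1505 probes, 84 on X, 272 SNP-flagged (disjoint), target
  IDs in the panel grammar.
* **Baselines**: per-probe M-values from a two-component mixture — 70%
  mostly-unmethylated around M = −2 (beta ≈ 0.2), 30% mostly-methylated
  around M = +2, component sd 0.5 — chosen to mimic the bimodal beta
  distributions of promoter panels; the real array's intensity
  distribution is not published, so these are free, documented
  parameters, not fitted values.
* **Effects**: 80 cell-type-differential probes and 8
  phenotype-differential probes (in AECs of asthmatic subjects), both as
  **methylation-state switches** of 6 M-units toward the opposite
  mixture component.  A switch, rather than a random-sign shift, is the
  biologically meaningful event: shifting an already-saturated probe
  further into its beta tail produces no observable intensity change, so
  random signs would plant effects that are undetectable by
  construction.  After preprocessing, a 6 M-unit switch lands at a raw
  z-score difference of about 2.2–3 (log2 ≈ 1.1–1.6) — the scale at
  which panel studies report differential methylation.
* **Noise and nuisances**: per-entry Gaussian M-noise (sd 0.5), a batch
  displacement of 2.5 M-units along a fixed random unit direction over
  probes (applied on the M scale, where the DWD correction operates),
  and a shared per-entry log2 brightness factor (sd 0.25) on both
  channels.  Detection failures hit 0.5% of entries independently of
  methylation state (no dependence structure is asserted anywhere for
  them).
* **Back-transform**: intensities are generated by inverting the M-value
  formula (`beta = 2^M/(2^M+1)`, `Cy5 = s·beta·2^a`,
  `Cy3 = s·(1−beta)·2^a`, s = 2000), so the generator and the pipeline's
  forward M-value computation share no code path and the generator is an
  independent oracle for it.
* **Determinism**: one derived RNG stream per logical component
  (manifest, cohort, baseline, effects, batch, noise, intensity,
  detection), all keyed by the master seed, so changing one configuration
  field perturbs only its own component.

**What passing tests do and do not show.**  The generator produces
Gaussian M-noise, independent probes, rigid batch displacements and
effects of a single magnitude.  Real arrays have correlated probes within
genes, heteroskedastic noise across the intensity range, bead-level
artefacts and dye chemistry the quantile map only approximates.  Recovery
of planted effects therefore validates the *machinery* (filters, solver,
calibration of q-values, threshold logic), not performance on any real
cohort; the published counts for the deposited accession (GEO GSE37853)
are kept in `reference_results_gse37853()` as accession-bound validation
targets and are not expected from synthetic runs.

## Verification experiments and problem sizes

The test suite and `scripts/acceptance.R` run these study-condition
experiments (sizes chosen to make each property measurable while keeping
a laptop-scale runtime; each is averaged over 20 seeds unless noted):

* **Null calibration**: 1000 probes, 10 + 10 subjects, no effects; the
  mean fraction of q ≤ 0.05 calls stays below 5%.
* **FDR control under weak effects**: 50 planted probes at 1.5 M-units
  (deliberately at the edge of detectability, recall ≈ 0.5); the
  empirical false-discovery proportion among q ≤ 0.05 calls stays within
  1.5× the nominal level.
* **Parameter recovery**: 50 planted state switches of 6 M-units
  (≈ 3 per-sample SDs) among 1000 probes, 10 + 10 subjects; pipeline
  recall ≥ 0.8 and FDP ≤ 0.15 under the full dual-threshold rule.  The
  switch magnitude is chosen to sit clearly inside the callable regime:
  an effect of exactly 2 per-sample SDs lands on the |z_diff| = 2 calling
  boundary, where any thresholding rule calls it with probability ~1/2
  and recall is uninformative about correctness.
* **Batch recovery**: a displacement of 5 noise-SDs along a random unit
  direction over 500 probes; DWD adjustment leaves < 10% of it (measured
  along the injected direction; typical residuals are 2–6%).
* **Solver validation**: the projected-gradient DWD direction agrees with
  direct BFGS minimisation of the same objective (cosine ≥ 0.99 on 20
  random instances, n ≤ 40, p ≤ 20) and with closed-form symmetric
  cases.

## Numerical choices, degeneracies, tie-breaks

* Quantiles use R's default type-7 interpolation.
* The colour-bias map breaks Cy5 ties by first occurrence
  (`ties.method = "first"`), making the output deterministic.
* KNN neighbours at distance zero share the weight equally (the
  inverse-distance weight would be infinite); a probe with no co-observed
  samples against any candidate falls back to its own observed mean; a
  fully-masked probe is an error.
* The Kruskal–Wallis companion (`kruskal_dunn()`, used for demographic
  checks such as sex and age across phenotype groups) applies the
  rank-sum H with tie correction and Dunn's pairwise z with a Bonferroni
  adjustment over all pairs — the classical form of Dunn's multiple
  comparison; all-tied data short-circuit to H = 0, p = 1.
* Missing detection p-values in input files are read as 1 (certain
  failure), the conservative direction for the > 0.05 rule.
* DWD re-adjustment of already-adjusted data is *not* a strict no-op:
  once the systematic displacement is removed, a refit on few samples in
  many dimensions can only chase sampling noise, and the second-pass
  translation is bounded by the null spread of mean projections (tested
  at < 10% of the first-pass translation).

## Known limitations

* No vendor control-probe normalisation, bead-level replicate handling,
  or dye-swap designs; IDAT and series-matrix parsing is out of scope (a
  converter to the three TSV formats is the user's responsibility).
* The t-tests use per-probe variances; moderated/shrinkage estimators
  and covariate-adjusted models are deliberately out of scope.
* Enrichment quality is bounded by the supplied annotation; the package
  ships none (the published analyses used a proprietary knowledge base,
  so enrichment is validated against synthetic annotations only).
* More than two batches are corrected by sequential pairwise merging;
  the merge order (first appearance in the sample sheet) is logged, and
  a different order can give slightly different adjustments.
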