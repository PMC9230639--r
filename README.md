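# concordia

Transcriptome–proteome concordance analysis for paired case–control
cohorts.

## What this is for

Studies that profile the same case and control cohorts with both bulk
RNA-seq and label-free proteomics often find the two omes *decoupled*: a
functional group — a respiratory-chain complex, the ribosome, a mitochondrial
transporter family — can be transcriptionally downregulated while its
proteins accumulate, pointing at translational or post-translational
regulation. `concordia` is for analysts of such paired datasets (the
motivating setting is Parkinson's-disease versus control lymphoblastoid
cell lines). It runs each ome's differential expression, over-representation
of the hit lists, and set-level concordance statistics, and classifies each
functional group's transcript–protein coupling.

## The statistics at the core

* **Transcripts** (integer counts): TMM scaling-factor normalization
  (reproduces `edgeR::calcNormFactors` to machine precision) and a
  common-dispersion negative-binomial exact test of each gene's normalized
  group sums conditional on their total; significant at BH *q* ≤ 0.05 with
  a symmetric 2-fold gate (FC ≥ 2 or ≤ 0.5).
* **Proteins** (intensities with explicit "not detected" cells): linear
  fold-change of detected-sample means; Welch *t*-test on log intensities;
  BH *q* ≤ 0.05.
* **Over-representation**: one-sided binomial tail of list hits *k* against
  expected *nK/N*, run against the reference of all detected features in
  that ome, with fold enrichment *k/(nK/N)* and single-linkage merging of
  redundant terms (Jaccard ≥ 0.5).
* **Concordance** (the core): after a ≥5-detections-per-cohort filter,
  members with FC > 1 / FC < 1 give the up/down counts; the continuity-
  corrected two-proportion test

  `z = (|x₁/n₁ − x₂/n₂| − (1/n₁ + 1/n₂)/2) / √(p̂(1−p̂)(1/n₁ + 1/n₂))`,
  `p = 2Φ(−z)`

  (identical to Yates' chi-square) tests direction; a one-sample *t* of
  member fold-changes against 1 tests magnitude; and per-ome calls combine
  into a coupling class: `concordant_up`, `concordant_down`,
  `discordant_t_down_p_up`, `discordant_t_up_p_down`, `undetermined`.

A seeded synthetic-cohort generator (negative-binomial counts, log-normal
intensities with logistic intensity-dependent missingness, planted per-set
fold-changes per ome) provides paper-shaped data for validation; the
methods vignette (`vignettes/concordance-methods.Rmd`) documents every
model, default and limitation.

## Worked example

```r
library(concordia)

cohort <- generate_cohort(default_paper_scenario(seed = 7))
de_t <- transcript_de(cohort$transcripts, cohort$design)
de_p <- protein_de(cohort$proteins, cohort$design)
conc_t <- concordance_table(de_t, cohort$sets, "transcript")
conc_p <- concordance_table(de_p, cohort$sets, "protein")
subset(conc_p, set_name %in% c("CI", "CV"))
#>   set_name     ome n_members_detected n_up n_down mean_fc_up mean_fc_down
#> 1       CI protein                 39   38      1       2.04        0.965
#> 5       CV protein                 16    1     15       1.18        0.792
#>     prop_p magnitude_p
#> 1 3.57e-16    4.28e-18
#> 5 4.30e-06    4.67e-05
```

Complex I proteins (planted 2-fold up) show 38 of 39 detected members
above unit fold-change with mean 2.04 and a proportion-test *p* of
3.6×10⁻¹⁶; Complex V (planted down in both omes) shows the mirror image.
Combining both omes:

```r
subset(coupling_table(conc_t, conc_p), set_name %in% c("CI", "CV", "RIBOSOME"))
#>   set_name transcript_call protein_call               coupling
#> 1       CI            down           up discordant_t_down_p_up
#> 5       CV            down         down        concordant_down
#> 9 RIBOSOME            down         down        concordant_down
```

The statistics also run directly on published up/down tallies — no
expression data needed:

```r
global_direction_test(1454, 1440, 35956)          # balanced transcriptome
#> [1] 0.8051648
set_direction_test(c(rep(2, 19), rep(0.5, 7)))$prop_p   # 19 up vs 7 down
#> [1] 0.002281937
```

## Analysis workflow

`analysis/` holds numbered drivers that chain the full study on a simulated
cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # paired cohort + GMT
Rscript analysis/02_differential_expression.R # per-ome DE tables
Rscript analysis/03_enrichment.R              # ORA + merged terms
Rscript analysis/04_concordance.R             # set tests + coupling calls
Rscript analysis/05_worked_examples.R         # printed-count reproductions
```

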