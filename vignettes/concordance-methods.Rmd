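---
title: "Methods: transcript-protein concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-protein concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordia)
```

# The problem

Bulk case-control studies that measure both the transcriptome (RNA-seq) and
the proteome (label-free mass spectrometry) of the same cohorts routinely
find that the two omes disagree: a functional group — a respiratory-chain
complex, the ribosome, a transporter family — can be transcriptionally
downregulated while its proteins accumulate. `concordia` implements the
statistical pipeline for detecting and classifying such
transcript-protein decoupling at the functional-group level: per-ome
differential expression, over-representation of hit lists against the
detected-feature reference, and set-level direction/magnitude tests that
culminate in a coupling call per group (concordant up/down, discordant in
either orientation, or undetermined).

The two omes are treated asymmetrically throughout, because the measurement
processes differ:

* **Transcripts** are nonnegative integer counts. A zero is a true zero.
  Depth and composition differences between libraries are removed with TMM
  scaling factors.
* **Proteins** are nonnegative intensities with explicit missingness: an
  absent intensity means *not detected*, not zero, and detection probability
  rises with abundance (missing-not-at-random). All protein statistics use
  detected values only.

# Differential expression

## Transcripts

Counts are normalized by trimmed-mean-of-M-values (TMM) scaling factors
computed against a reference sample (the one whose upper-quartile count
fraction is closest to the mean), with the canonical 30% trim on log-ratios
and 5% trim on average log-intensity, precision weighting, and pairwise
exclusion of zero-count genes; factors are rescaled to product 1 and the
effective library size is the raw size times the factor. The implementation
reproduces `edgeR::calcNormFactors` to machine precision on random count
matrices (this is asserted in the test suite); keeping the canonical
floating-point forms of the M and A expressions matters, because exact ties
at the trim boundaries otherwise resolve differently.

Testing uses a *common-dispersion exact test*. Counts are scaled to a common
effective library size (the geometric mean); a single negative-binomial
dispersion is estimated by method of moments on the scaled counts — per gene,
pooled within groups, `phi = (s^2 - mu) / mu^2` averaged over genes and
floored at 0 — and each gene's scaled group sums are compared conditionally
on their total. The two-sided p-value is the sum of conditional
probabilities not exceeding that of the observed split. At `phi = 0` the
conditional law is exactly binomial and the test coincides with
`binom.test` of the split (also asserted against that oracle). Group sums
are rounded to integers after scaling; at the count depths used here the
rounding is negligible next to sampling noise, and a null-scenario
calibration (50 seeds) keeps the raw false-positive rate at the nominal 5%.

A transcript is significant when its BH q-value is at most `alpha = 0.05`
**and** its linear fold-change passes the symmetric 2-fold gate
(`FC >= 2` or `FC <= 0.5`). Fold-changes are ratios of normalized group
means with a pseudocount of 0.5 added to each mean — the pseudocount
prevents infinite ratios but never enters the test. FPKM
(`count / (kb * millions of effective reads)`) is provided for reporting;
all testing happens on counts.

## Proteins

A protein enters the analysis only if detected at least once in each
cohort. The fold-change is the linear ratio of detected-sample means —
reported fold-changes in this field are linear, so the package keeps that
scale — while the t-test runs on natural-log intensities, where MS
intensity noise is closer to Gaussian. Welch's unequal-variance form is the
default because cohort sizes and variances are rarely matched; a pooled
option (`var_equal = TRUE`) and a raw-intensity option
(`log_transform = FALSE`) are exposed since either convention appears in
practice. Proteins with fewer than two detected values in a group cannot be
tested and are reported with `p = q = 1`, never significant; the BH family
is the set of actually tested proteins, and transcripts and proteins are
corrected as separate families.

# Over-representation

Hit lists (significantly up- or downregulated features) are tested against
the reference of *all detected features in that ome* — not the genome —
since detection itself is strongly abundance-biased. For a set with `K`
reference members, a list of `n` drawn from a reference of `N` yields
`expected = n K / N` and `fold_enrichment = k / expected`. The p-value is a
one-sided binomial tail in a *fixed* direction: the over-representation
analysis always uses `P(X >= k)` and the under-representation analysis
`P(X <= k)`. The direction is an argument, never inferred from the observed
count — switching tails after seeing the data would double the effective
type-I rate, and the calibration test (random lists drawn uniformly from
the reference) verifies the p-values are stochastically no smaller than
uniform. The binomial tail is the default to match standard ORA tools; an
exact hypergeometric option is available and is slightly more conservative
at these reference sizes.

Redundant terms (GO-style annotation yields many near-duplicate sets) are
merged by single-linkage clustering on the Jaccard similarity of
reference-restricted memberships, at a default threshold of 0.5. Judgment
calls in published merges are not reproducible; a fixed overlap criterion
is. The merged row is named after its most significant member and carries
the mean/min/max fold enrichment and mean significance of its members. Term
relationships enter only through membership overlap — no ontology traversal.
A pattern blocklist (`filter_relevance`) removes terms irrelevant to the
cell type, mirroring the manual curation such analyses apply.

# Functional-group concordance

This is the package's analytical core and uses deliberately permissive
thresholds, because set-level tests aggregate weak per-member signals:

* **Detection filter**: a feature joins set-level analysis only when
  detected in at least `min_detect = 5` samples per cohort (inclusive).
* **Direction classes**: fold-change strictly above 1.1 is a 10% increase
  (`up`), strictly below 0.9 a 10% decrease (`down`); boundary values are
  `unchanged` (the cuts are exclusive).
* **Set direction test**: members with FC strictly above 1 count as up,
  strictly below 1 as down (exactly 1 counts as neither); the up and down
  counts are compared with a continuity-corrected two-sample proportion
  test, *each arm out of `n_up + n_down`*.
* **Set magnitude test**: a two-sided one-sample t-test of all member
  fold-changes against 1, on the linear scale, because the reported
  group-average fold-changes are linear; a log-scale option tests log-FC
  against 0.
* **Global direction test**: the same proportion test, but with the total
  number of detected features as both denominators.

The proportion test is the pooled two-proportion z-test: with
`ph = (x1 + x2) / (n1 + n2)`,

```
z = (|x1/n1 - x2/n2| - c) / sqrt(ph (1 - ph) (1/n1 + 1/n2)),
c = (1/n1 + 1/n2) / 2,   numerator floored at 0,   p = 2 Phi(-z),
```

identical to the Yates-corrected chi-square on the equivalent 2x2 table
(asserted over a grid of counts in the tests). Degenerate pooled
proportions (0 or 1) return `p = 1`; all other undefined statistics
propagate as `NA` rather than silently becoming 0 or 1.

The two denominators — the moved members for set-level tests, the full
detected population for global tests — are both exposed because each
reproduces a distinct family of published worked examples; the set-level
form answers "do the moved members prefer one direction", the global form
"is either direction enriched relative to everything measured".

**Coupling calls**: per ome, a set is called `up` when its proportion test
is significant at `alpha = 0.05` with more up than down members, `down` in
the mirror case, `mixed` when not significant, and `none` when empty after
filtering. The transcript and protein calls map through a fixed lookup to
`concordant_up`, `concordant_down`, `discordant_t_down_p_up`,
`discordant_t_up_p_down`, or `undetermined`.

# The synthetic cohort generator

No raw data accompany the study design this package targets, so validation
rests on a generator that emulates the *statistical structure* the methods
assume:

* Two cohorts (default 20 vs 20, matching typical lymphoblast-cohort
  sizes), measured in both omes over a shared gene universe.
* Transcript counts: log-normal baseline abundance landscape
  (`meanlog = 3`, `sdlog = 1.2` — a realistic several-decade dynamic
  range), per-sample library sizes uniform on 50,000-80,000, negative
  binomial sampling with common dispersion 0.1 (biological-replicate
  variability for cell lines), case means multiplied by each set's planted
  transcript fold-change.
* Protein intensities: baseline log-intensities `N(20, 2)` in natural-log
  MS units, case samples shifted by `log(protein_fc)`, per-cell noise
  sd 0.5, then logistic intensity-dependent masking
  (`P(detect) = plogis((log I - 18) / 1)`), so low-abundance proteins go
  missing preferentially — at the defaults roughly a fifth of cells. This
  MNAR mechanism is what makes the detected proteome much smaller than the
  transcriptome in real studies; an MCAR model would not reproduce that.
* The default scenario plants the canonical decoupling pattern:
  Complexes I-IV transcripts 0.8 / proteins 2.0; Complex V and the
  ribosome 0.8 in both omes; TCA proteins up with unchanged transcripts;
  SLC25 and TIMM/TOMM transcripts down; immune and sphingolipid sets up in
  both omes. Set sizes follow the detected counts of published
  functional-group tables (44 Complex I transcripts, 52 SLC25 carriers,
  and so on), over a null background of 1,000 genes.

Problem sizes in the test suite are scaled for tightness of the check, not
realism of scale: calibration runs 50 seeds of a 500-gene null at 10 vs 10;
parameter recovery runs 50 seeds of the full default scenario and requires
the planted coupling classes (discordant for CI-like sets, concordant-down
for Complex V and the ribosome) in at least 90% of seeds.

What the generator does **not** emulate — and hence what passing tests do
not certify on real data: peptide-to-protein inference and shared-peptide
ambiguity, batch and run-order effects, gene-length and GC biases beyond a
static length column, correlated gene-gene expression within sets, and
cohort covariates (age, sex). Dispersion is common across genes by
construction, matching the test's model on purpose; a Poisson switch
(`nb_dispersion = 0`) exists for model-mismatch experiments.

# Numerical choices and edge cases

* Exact-test two-sided p-values use the "sum of probabilities not exceeding
  the observed" rule with a `1 + 1e-7` tolerance factor, as exact binomial
  implementations do.
* Constant-in-both-groups proteins with equal means get `p = 1` (no
  evidence) rather than an undefined t statistic.
* Zero-variance or n < 2 magnitude tests return `NA`.
* Sets with no detected members yield `NA` proportion tests and a `none`
  call; a missing ome row makes the coupling `undetermined`.
* TSV writers emit full-precision reals so write-read round trips are
  exact; identical inputs produce byte-identical outputs (no timestamps in
  tables; run parameters live in `summary.json`, schema
  `concordia_summary_v1`).

# Known limitations

* The set-level proportion test treats members as independent; co-regulated
  complexes violate this, so set-level p-values are anti-conservative to an
  unknown degree in real data. The coupling call, which only consumes the
  direction of imbalance, is more robust than the p-value itself.
* The common-dispersion exact test has no tagwise/trended dispersion, no
  GLM designs, and no covariates; it targets the one-factor two-group
  design only.
* ORA here does not reproduce any specific annotation database; gene sets
  are supplied as GMT files and results depend on them entirely.
* The magnitude test on linear fold-changes is sensitive to a single large
  ratio; the log option is preferable when sets contain extreme movers.
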