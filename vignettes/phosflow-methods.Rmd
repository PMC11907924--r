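---
title: "phosflow: models, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosflow: models, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
library(SummarizedExperiment)
```

phosflow models the analysis chain of a label-free phosphoproteomics
drug-response study: quantification post-processing, set-based activity
inference, dose--response summarization, and repeated-split
classification of ex vivo drug sensitivity. This vignette explains each
model, the parameters that matter, the numerical conventions, and --
because the package ships its own synthetic-data generators -- exactly
what the passing tests do and do not demonstrate about real data.

## Quantification model

Peptide-ion intensities arrive as a `PeptideQuant`, a
`SummarizedExperiment` whose rows are peptide ions annotated with a
protein and zero or more phosphosite ids (`PAK1(S144)` style), and whose
cells are non-negative intensities or `NA`. The processing order is fixed
and deliberate:

1. **`normalizeTotal()`** -- each quantified cell is divided by its
   sample's total quantified intensity. Missing cells are excluded from
   the totals, so each sample's quantified signal sums to exactly 1.
2. **`imputeMissing()`** -- each missing cell becomes the ion's minimum
   *observed* (normalized) intensity divided by 10. Imputation therefore
   operates on normalized values: the min/10 rule is a left-censored
   placeholder, and dividing a normalized minimum by 10 preserves that
   semantics regardless of each sample's loading. Ions observed nowhere
   cannot be imputed and are dropped with a warning.
3. **`averageTechnicalReplicates()`** -- arithmetic mean of
   post-imputation replicate columns.
4. **`rollupSites()` / `rollupProteins()`** -- the phosphorylation index
   (ppIndex) of a site is the *sum* of all ions carrying that site; an
   ion with $k$ sites contributes its full intensity to each of the $k$
   sites, so site totals are intentionally not conserved, while protein
   totals are exactly conserved.
5. **`differentialTest()`** -- statistics are computed on log2 values.
   The unpaired test is the equal-variance (Student) two-sample $t$, not
   Welch; the paired test is a one-sample $t$ on paired log2 differences.
   Benjamini--Hochberg q-values are emitted alongside raw p-values, but
   the package's own defaults filter on raw $p \le 0.05$.

Whether roll-up should precede or follow imputation is not decidable from
first principles; phosflow imputes at the ion level first, which keeps
the imputed placeholder tied to the detection limit of the individual
ion. The same holds for replicate averaging, which here follows
normalization so that replicates with different loadings are comparable
before averaging.

## Activity inference

`ksea()` scores a kinase by the distance between its substrates' mean
log2 fold change and the global mean,
$\delta = \bar f_S - \bar f$. Its null distribution is obtained by
drawing random feature sets of the same size from the contrast;
$p = (b+1)/(N+1)$ with $b$ the draws at least as extreme in absolute
value, so p-values live in $[1/(N+1), 1]$ and are never exactly zero.
Because sets of equal matched size have identical nulls, phosflow draws
one permutation null per distinct size per contrast, which is
statistically identical to per-set draws and considerably faster. A
normal approximation ($z = \delta\sqrt{m}/\hat\sigma_f$) is available as
`method = "ztest"` for large contrasts. The default
`minSubstrates = 3` reflects that enrichment over one or two matched
sites is not meaningfully testable. `ctamScore()` applies the same
statistic to compound-target signatures, optionally per sample, where the
input column is treated as that sample's log2-change profile.

`tfActivity()` z-scores each gene's (log2) protein intensity across
samples using the sample ($n-1$) standard deviation, and sums the
z-scores of a factor's target genes per sample. Rows of the resulting
activity matrix sum to zero by construction -- a useful invariant, and a
reminder that these scores are relative within the cohort, not absolute
activities. Activation/repression edge signs are ignored: the score is an
unsigned sum, and a signed variant would require edge-annotated input
sets.

## Drug-response summaries

`computeAac()` integrates $1 - \text{viability}$ (viability clipped to
$[0,1]$) over $\log_{10}$ dose by the trapezoid rule and divides by the
log-dose range, giving a unitless AAC in $[0,1]$ that is comparable
across dose ranges. Higher AAC means more sensitive.
`classifySensitivity()` thresholds at the cohort mean; a value exactly at
the mean is called resistant (documented tie rule), and a `direction`
argument accommodates metrics with the opposite polarity.
`correlateFeatures()` uses Spearman rank correlation with average-rank
ties and the $t$ approximation for p-values; `integrateDependency()`
applies fold-change, p-value and dependency-score cutoffs conjunctively
and deliberately ships **no default cutoffs** -- all three are required
arguments, since no principled defaults exist.

## The classifier

`repeatedSplitWorkflow()` follows a fixed recipe: label the full cohort
once at the mean sensitivity; per cycle, draw a uniform train/test
partition (27/9 proportions by default, 50 cycles), select features by
PLS importance, fit a random forest on the selected features, and record
each held-out sample's probability of resistance.

* **Labelling before splitting** leaks a small amount of information
  (each training label depends weakly on test-set values through the
  cohort mean). This mirrors the modelled workflow and is the default;
  `labelMode = "training"` recomputes the threshold per training set for
  a leakage-free variant.
* **PLS importance** is defined as
  $\sum_k |w_{jk} b_k|$ over components -- loading weight times inner
  regression weight -- min--max scaled to $[0,100]$, from a NIPALS PLS1
  fit on standardized training features against the centred 0/1 class
  indicator. Standardization before PLS is assumed; features without
  variance get importance 0. Two components is the default: the smallest
  non-trivial latent space for a training set of 27.
* **Selection threshold 75 vs frequency cutoff 70.** Selection into a
  cycle's model requires importance > 75; the cross-model frequency table
  counts exceedances of 70. These are two distinct, independently
  configurable thresholds and phosflow keeps them separate rather than
  reconciling them.
* **Random forest**: 500 trees, `mtry` $=\lfloor\sqrt p\rfloor$, no class
  weighting; per-cycle seeds are `masterSeed + cycle`, so a run is fully
  reproducible and cycles are independent of execution order. Cycles
  whose training draw is single-class are redrawn (counted); cycles where
  no feature passes selection are recorded as failed rather than silently
  skipped.
* **Pooled ROC.** All held-out (probability, label) pairs are pooled into
  one curve rather than averaging per-cycle AUCs, because each cycle
  holds out only 9 samples -- per-cycle ROC would be extremely coarse.
  A sample is called resistant at thresholds less than or equal to its
  probability (half-open convention); the trapezoidal AUC then equals the
  Mann--Whitney concordance with ties counted 1/2, which is how the test
  suite checks it. The per-sample mean probability across cycles is also
  reported.

## What the synthetic generators emulate

The generators reproduce the statistical shape of the modelled
experiments, with defaults chosen once to match those study conditions:

* `simulateTreatmentContrast()`: per-site log2 baselines
  $\sim N(20, 2)$ (a typical LC-MS dynamic range -- the scale is
  irrelevant downstream because normalization removes it), cell-level
  log2 noise (default sd 0.5), 4 control vs 4 treated replicates,
  kinase-level log2 shifts applied to substrate sites, per-cell
  missingness that is completely at random by default with an optional
  left-censored mode (low intensities preferentially missing, matching
  the assumption behind min/10 imputation), and a configurable fraction
  of sites carried by two peptide ions to exercise roll-up.
* `simulateCohort()`: 36 samples and 1000 sites by default, with 10
  informative sites that are *co-regulated* through a latent per-sample
  kinase activity $a_s \sim N(0,1)$: informative site values are
  $a_s + N(0, 0.5)$ around their baselines. The continuous sensitivity is
  the literal weighted sum
  $\text{sens}_s = \text{effect} \cdot \sum_{i} z_{is} + \varepsilon_s$,
  $\varepsilon \sim N(0,1)$, with the effect expressed in
  noise-standard-deviation units. Co-regulation is the realistic
  structure -- substrates of one kinase rise and fall together, and a
  response biomarker is informative precisely because it tracks the
  activity that drives response. With `effectSdUnits = 0` the
  sensitivity is pure noise and the classifier must collapse to chance.
* `simulateDoseResponse()`: a four-parameter-logistic-shaped viability
  curve over log-spaced doses, scaled by an `effect` in $[0,1]$, so
  `effect = 0` gives viability identically 1 and AAC exactly 0.

**What passing tests show -- and what they do not.** The simulation tests
demonstrate internal correctness: planted kinase shifts are recovered by
KSEA within tolerance, null kinases are rejected at the nominal 5% rate,
planted biomarkers dominate the selection-frequency table, pooled AUC is
high when signal exists and near 0.5 when labels are permuted, and every
closed-form quantity is exact. They do not demonstrate performance on
real cohorts: real phosphoproteomics data have correlated non-substrate
sites, batch structure, heavier-tailed noise, missingness that is only
partially intensity-driven, and annotation databases with errors --
none of which the generators emulate. The generators are a test harness,
not a simulator of biology.

## Numerical conventions and degenerate inputs

* Normalization totals exclude missing cells; a sample with no quantified
  intensity is an error naming the sample.
* Renormalizing a normalized table changes no cell by more than 1e-12;
  column sums are within 1e-9 of 1.
* Zero-variance features: $t = 0$, $p = 1$ when group means are equal
  (no evidence against the null); importance 0 in PLS; dropped with a
  note in TF z-scoring.
* Permutation p-values use add-one smoothing and are reproducible given
  a seed; seeds are plain integers kept below $2^{31}$.
* Ties: sensitivity values exactly at the mean threshold are resistant;
  equal probabilities at a ROC threshold are handled by the half-open
  convention, making trapezoidal AUC exactly the tie-aware concordance.
* Ledgers serialize to JSON lines at 17 significant digits, so a
  round-trip reproduces ROC output bitwise.

## Problem sizes used by the test suite

The package's own checks run at deliberately chosen sizes: quantification
oracles on 200-ion, 8-sample tables; differential-test calibration on
4000 null features; KSEA recovery at planted shifts of $-2$, $-1$ and
$-0.5$ on 20 substrates among 2000 sites over 50 simulations with 10,000
permutations; classifier recovery on 20 independent 36-sample cohorts of
1000 sites (10 informative, effect 2 sd) with 50 cycles each; and 5
label permutations for the null AUC. These sizes give the binomial
margins needed by the calibration checks while keeping a full test run
in the minutes range on a single CPU.

## Known limitations

* The KSEA delta weights all matched substrates equally; no site
  reliability weighting.
* PLS importance is one of several reasonable definitions; alternatives
  (VIP scores, filter coefficients) would rank features similarly but
  not identically.
* The repeated-split design estimates a single pooled ROC; it does not
  provide per-sample uncertainty beyond the mean probability, and no
  hyperparameter search or alternative learners are included by design.
* `integrateDependency()` assumes contrast features and dependency genes
  already share a namespace; no identifier mapping is performed.
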