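---
title: "Cumulative CNV risk scores: model, design choices, and what the synthetic cohort does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative CNV risk scores: model, design choices, and what the synthetic cohort does and does not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrisk)
library(dplyr)
```

## The scientific problem

Rare copy number variants (CNVs) carry substantial risk for cognitive and
psychiatric outcomes, but almost all of them are individually too rare to
test. The cumulative risk-score framework sidesteps this: instead of asking
"which CNV?", it asks "how much dosage-sensitive gene content does this
person's CNV burden delete or duplicate?". Each gene carries published
annotation scores — pHI and pTS (probabilities of haploinsufficiency and
triplosensitivity), pLI (loss-of-function intolerance), and LOEUF (the
loss-of-function observed/expected upper bound fraction, used here as its
reciprocal so larger means more constrained). A person's deletion score
under a scheme is the sum of that scheme's gene score over every gene fully
contained in any of their deletions; duplications are scored separately
with the duplication-matched annotation (pTS). The scores then enter
multivariable regression models of cognition, psychopathology, and brain
structure together with environmental stressors and polygenic scores
(PGSs).

## Scoring: conventions and why

**Coordinates.** All intervals are 0-based, half-open (BED dialect);
length is `end - start`. A call of exactly 50 000 bp passes the standard
"at least 50 kb" size filter.

**Gene overlap rule.** A gene contributes only when *fully encompassed* by
a CNV (`rule = "containment"`, the convention of the cumulative risk-score
literature: a partially overlapped gene's dosage change is ambiguous).
`rule = "any"` is available for sensitivity analyses. Under containment, a
gene can never be claimed twice by disjoint same-state calls of one
sample, so per-event and per-distinct-gene counting coincide; overlapping
same-state calls within a sample are unioned before scoring so a
double-reported segment is not double counted.

**Chromosome policy.** chrY and mitochondrial calls are always removed;
chrX is removed by default and restored with `include_chrX = TRUE`
(mirroring the usual X-inclusion sensitivity analysis).

**Transforms.** Cumulative sums are zero for most individuals and heavily
right-skewed, so `transform_scores()` adds `log(1 + S)` — zero maps to
zero and rank order is preserved, which an offset-free log cannot do for
zero-inflated sums — and the binary indicators `S > 0`.

**Pathogenic exclusion.** `exclude_pathogenic()` drops every call of any
sample whose CNV reciprocally overlaps a listed pathogenic region of the
same copy state at ≥ 50% of both lengths — 0.5 being the standard
CNV-matching threshold; the value is an argument because the convention is
not universal.

**Interval engine.** Containment queries run on
`GenomicRanges::findOverlaps(type = "within")`; the test suite holds the
engine to exact equality with an all-pairs brute-force oracle, so the
dependency is an implementation detail, not a trust assumption.

## Association models

All reported coefficients are standardized: continuous predictors are
z-scored with the sample SD (n − 1), and linear outcomes are z-scored as
well, so a linear β reads as SDs of outcome per SD of predictor. For
logistic models the outcome is untouched and β is the log-odds change per
SD of predictor — the standard choice, since "standardized outcome" has no
natural meaning for a binary diagnosis. Binary 0/1 predictors and
categorical covariates are left on their native scale; categoricals are
dummy-coded against the most frequent level. Standardization makes every
reported quantity invariant to positive affine rescaling of the raw
variables (a tested property).

The default covariate block is sex, self-identified race, and 10 ancestry
principal components. The stepwise ladder fits, on one identical
complete-case row set, the models: covariates only; + CNV scores;
+ environment; + environment + CNV; optionally + PGSs. Holding the row set
fixed is what makes AIC differences meaningful, and the ladder errors out
rather than compare AICs across differing rows. AIC follows the
`stats::AIC` Gaussian convention (`2k − 2 lnL` with the residual variance
counted in k); only ΔAIC between ladder steps is interpreted, so the
convention constant is irrelevant as long as it is consistent. Deletion
and duplication scores of one scheme always enter a model as a pair — a
scheme is compared as a whole, not one channel at a time.

**FDR.** `bh_adjust()` implements the Benjamini–Hochberg step-up against a
*declared* family size that may exceed the number of p values supplied.
Families are explicit (`fdr_families()`: 16 for the scheme comparison, 34
for the outcome-wide scan, 90 for the combined models) and never inferred
from the number of tests that happen to be reported, because family
construction is an analysis decision, not a property of a vector. Ties are
broken by stable order, which provably does not change adjusted values.

**Logistic numerics.** IRLS convergence is declared at a relative
log-likelihood change below 1e-10 with at most 100 iterations. Perfect or
quasi-perfect separation (fitted probabilities at the 0/1 boundary, or a
slope above 15 on the log-odds scale) is an error with a diagnostic rather
than a silently absurd estimate.

**Age normalization.** "Age-normalized" is implemented as residualization
on a natural cubic spline of age (4 df) followed by z-scoring; the exact
recipe used upstream of the factor scores is not restated in the source
literature, so a 2-year-bin z-score variant is available behind
`method = "bins"`. The spline residuals carry no linear or quadratic age
correlation beyond numerical tolerance (a tested property). An outcome
that is an exact function of age residualizes to the zero vector rather
than to amplified rounding noise.

**Missing data.** Every model is complete-case over its own columns, with
the per-model n recorded in `glance()`; the ladder takes complete cases
over the union of all its terms first.

## Brain deviation

The normative reference is a table of age- and sex-specific median and
scale curves per phenotype (GMV, sGMV, WMV; mm³) on a 0.1-year grid over
ages 8–21, plus a scalar study offset read from the file header. A centile
is the Gaussian CDF of `(volume − offset − median) / scale` with linear
interpolation between grid points. Treating the reference as Gaussian
around tabulated curves is a deliberate simplification of the
GAMLSS-class growth models normative references are actually fitted with;
the file format keeps phenotype/sex/age/median/scale columns precisely so
skew or kurtosis curves could be added later without breaking readers.
Fitting the reference itself, and estimating the study offset, are out of
scope — both arrive as inputs.

An individual is *high deviation* when any centile is strictly below 0.10
or strictly above 0.90 ("first or tenth decile in at least one
phenotype"). Boundary values count as low deviation — a measure-zero event
under any continuous reference, so the choice is documented rather than
consequential. CNV-risk categories use the cumulative dosage-sensitivity
sums: high if deletion-pHI > 1 or duplication-pTS > 1 (strict), and, when
the three-category variant is requested, medium for any nonzero sum not
exceeding 1. The (0, 1] medium band is our choice — the source analysis
used a medium category but did not print its cutoffs — and the LOEUF-based
variant reuses the same threshold on the 1/LOEUF sums for want of a
published one.

## The synthetic cohort: what it emulates

The generator exists so the full pipeline is testable without the
restricted cohort data. Its defaults are fixed to the study conditions:
7101 individuals aged 8–21 (uniform), balanced sex, race proportions
63/26/11 (European American / African American / other), 18 000 genes,
2.56 CNV calls per person (Poisson) of which 57.8% are deletions, call
lengths lognormal (median ≈ 120 kb) truncated below at 50 kb so every
generated call survives the size filter, and an imaged subcohort of 920.

Gene-level pHI/pTS/pLI are Beta(0.3, 2) — right-skewed on [0, 1] so most
genes score near zero and cumulative scores inherit a point mass at zero
with a long right tail, the shape that motivates the transforms. LOEUF is
Gamma(4, 4) (mass near 1). CNVs are placed uniformly and independently;
there is deliberately no recurrent-hotspot model, because hotspots matter
for discovery but not for verifying scoring and regression machinery.

Outcomes are built as `Σ β_j · z(predictor_j) + Gaussian noise`, with the
noise scaled so each outcome has unit variance — the generating βs are
therefore standardized by construction, and an unbiased pipeline should
recover them on average. The headline generating effects are the published
ones (deletion-pHI on overall accuracy −0.121, duplication-pTS −0.054,
deletion-pHI on psychosis-spectrum 0.05, intelligence-PGS on accuracy
0.27, trauma on overall psychopathology 0.35, and the secondary PGS and
environment effects); the remaining cognitive-domain effects are
interpolated to mirror the reported pattern of strong, unspecific
cognitive associations and weaker psychopathology ones. PGSs are
multivariate normal with modest cross-disorder correlation (0.2 among the
five psychiatric scores, −0.1 with intelligence) — a stylized stand-in,
configurable via `pgs_correlation`. Trauma is a Binomial(8, 0.15) count
and neighborhood SES a standard normal factor score; the source describes
both only as quantitative predictors, so any monotone choice serves, and
both are configurable. Generated outcomes carry no age trend: age effects
are injected by tests when the age-normalization step itself is under
test, so the generator and the phenotype module stay independently
checkable.

Brain volumes are generated by inverting the reference: a deviation
indicator is drawn from a logistic model (baseline probability 0.395 for
low-risk individuals — the published low-risk rate, which embodies the
correlation among the three volume phenotypes — plus a 0.56 log-odds
increment for high CNV risk), centiles are drawn uniformly conditional on
the indicator, and volumes come from the centile via the reference curves.
Setting the baseline to 1 − 0.8³ = 0.488 with zero coupling makes the
three centiles exactly independent uniforms, the closed-form null used in
the calibration tests.

What passing tests therefore show: the scoring engine is exact, the
estimators are unbiased and calibrated, FDR control holds, and the
pipeline recovers known standardized effects at the study's sample sizes.
What they do not show: robustness to recurrent hotspots, array batch
structure, genotyping error, non-Gaussian outcome distributions,
population stratification beyond independent PCs, or real linkage between
PGSs and CNV burden — none of which the generator emulates.

## Determinism and seeds

Every generator takes one master seed and derives a fixed child seed per
component stream (genes, calls, cohort, outcomes, brain), so regenerating
one component never perturbs another and identical configurations are
byte-identical end to end (manifest checksums are compared in the tests).
Replicate r of a simulation study uses `seed * 1000 + r`, kept within
32-bit integer range.

## Problem sizes used by the simulation studies

The parameter-recovery study runs 200 replicates at the full cohort size
(n = 7101; the combined PGS models on the ~63% European-ancestry
subcohort, n ≈ 4470) and 500 replicates of the n = 920 imaged cohort;
recovery is judged within 3 Monte-Carlo standard errors of the mean. The
model-ladder behaviour study uses 200 replicates at n = 2000 and the
global-null FDR study 100 replicates at n = 1000 — sizes chosen so the
relevant effects are comfortably powered (a −0.121 standardized effect has
|t| ≈ 5.4 at n = 2000) while the studies stay quick to rerun.

```{r recovery-demo}
rec <- recovery_study(n_reps = 5, seed = 1, n_samples = 1200)
round(colMeans(rec), 3)
```

(Five small replicates for illustration; `scripts/acceptance.R` runs the
full-size study.)

## Known limitations

* The Gaussian normative reference ignores the skew/kurtosis of real
  growth curves; centiles from real GAMLSS references will not be exactly
  Gaussian quantiles.
* PGSs are generated for all individuals but, as in real practice, are
  only interpretable in the ancestry subcohort the models restrict to;
  the generator does not emulate ancestry-specific LD structure.
* The interaction scan tests one product term per model; it is an
  exploratory screen, not an optimized interaction detector.
* Array-heterogeneity random effects and trio-based analyses are out of
  scope; the cohort is treated as unrelated individuals on one platform.
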