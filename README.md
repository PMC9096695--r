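# cnvrisk

Copy number variants (CNVs) — deleted or duplicated genomic segments — are
major contributors to liability for neurodevelopmental and psychiatric
conditions, but most clinically relevant CNVs are far too rare for
variant-by-variant association testing. `cnvrisk` implements the cumulative
**CNV risk-score** framework for community-scale cohorts: every deletion
(duplication) an individual carries is annotated with the dosage
sensitivity of the genes it fully encompasses, the per-gene scores are
summed into a per-individual burden, and that burden is related to
cognitive, psychopathological, and neuroimaging outcomes alongside
environmental stressors and polygenic scores (PGSs).

The package is aimed at statistical geneticists and neuropsychiatric
epidemiologists who want the whole pipeline — scoring, model ladder,
multiple-testing control, normative brain-deviation classification — as
tested, composable, pipe-friendly functions, plus a synthetic-cohort
generator that reproduces the statistical structure of a large restricted
developmental cohort so everything can be exercised without access to the
original data.

## The model

For individual *i* with deletion calls *D<sub>i</sub>* (duplications
*U<sub>i</sub>* analogously), the deletion risk score under gene-level
annotation *w* is the cumulative burden over fully encompassed genes:

```
S_i(w) = Σ_{d ∈ D_i} Σ_{g ⊆ d} w(g)
```

Annotation schemes compared head-to-head: total size, gene count, pLI,
1/LOEUF, and the dosage-sensitivity probabilities pHI (deletions) / pTS
(duplications), with log(1 + S) and S > 0 transforms for the zero-inflated,
right-skewed sums. Outcomes are age-normalized and modelled by a stepwise
ladder of multivariable regressions,

```
outcome ~ covariates  →  + CNV scores  →  + environment  →  + environment + CNV  →  + PGSs
```

with standardized β per term (SDs of outcome per SD of predictor), AIC and
adjusted r² per model, and Benjamini–Hochberg FDR within declared
comparison families. The imaging arm locates each global brain volume
(GMV, sGMV, WMV) on an age- and sex-specific normative reference curve,
classifies individuals in the first or tenth centile decile of any
phenotype as *high deviation*, and tests the association with high CNV
risk (cumulative pHI > 1 or pTS > 1) by logistic regression.

## Worked example

```r
library(cnvrisk)
library(dplyr)

cfg    <- sim_config(seed = 42)                 # 7101 youths, 18k genes
genes  <- sim_gene_table(cfg)
calls  <- sim_cnv_calls(cfg, genes)
scored <- run_score(calls, genes, samples = sprintf("S%05d", 1:cfg$n_samples))
#> Scored 7101 samples (5638 with genic CNV content).

cohort <- sim_cohort(cfg, scored$profile)
dat    <- left_join(cohort, scored$profile, by = "sample_id")

fit_linear(dat, "overall_accuracy", c("del_sum_pHI", "dup_sum_pTS"))
#> <cnv_fit> linear model of overall_accuracy (n = 7101, AIC = 20060.1)
#>   term        estimate std.error statistic  p.value conf.low conf.high
#> 1 del_sum_pHI  -0.119     0.0118    -10.1  1.22e-23  -0.142    -0.0955
#> 2 dup_sum_pTS  -0.0368    0.0118     -3.12 1.80e- 3  -0.0599   -0.0137
```

Each row is a standardized effect: one SD more cumulative deletion-pHI
burden predicts 0.119 SD lower overall cognitive accuracy, adjusted for
sex, self-identified race, and 10 ancestry principal components (the
generating truth in this synthetic cohort is −0.121). The model ladder
shows how CNV scores and environmental stressors each improve fit:

```r
model_ladder(dat, "overall_accuracy", c("del_sum_pHI", "dup_sum_pTS"))
#> <cnv_ladder> outcome: overall_accuracy
#>   model               n     k    AIC adj.r.squared delta_AIC
#> 1 covariates       7101    14 20166.      0.000270      NA
#> 2 cnv              7101    16 20060.      0.0153      -106.
#> 3 environment      7101    16 20144.      0.00357       84.3
#> 4 environment_cnv  7101    18 20038.      0.0187      -107.
```

The imaging arm, end to end:

```r
ref   <- make_normative_reference()
risk  <- assign_risk_category(scored$profile)   # pHI > 1 or pTS > 1
brain <- sim_brain(cfg, cohort, risk, ref)
dev   <- run_deviation(brain, scored$profile, ref)
dev$crosstab
#>   risk_category     n n_deviant pct_deviant
#> 1 high             79        45        57
#> 2 low             841       308        36.6
```

High-CNV-risk individuals deviate from the normative brain-volume range
more often than low-risk individuals; `dev$fit` carries the logistic
log-odds estimate with its CI. `autoplot()` methods exist for fits and
ladders, and `plot_score_distribution()` shows the zero-inflated burden
distribution that motivates the log/indicator transforms.

A thin command-line wrapper over the same functions ships at
`inst/cli/cnvrisk` (subcommands `simulate`, `score`, `analyze`,
`deviation`).

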