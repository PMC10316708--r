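# dldscreen

Screening utility of a parental questionnaire for developmental
language disorder (DLD).

Developmental language disorder affects roughly one child in ten and is
chronically underdiagnosed where standardized language assessment is
unavailable. A short parental questionnaire is often the only signal a
clinic gets. `dldscreen` answers the practical question behind such a
questionnaire: *given a parent's answers, how much should the estimated
probability that this child has DLD change?*

The package is aimed at clinical researchers validating screening
questionnaires and at methodologists studying likelihood-ratio-based
test evaluation.

## What it computes

* **Risk-perception coding** of the eight-item parental linguistic
  concern questionnaire (PLCQ), with a schema-pinned coding direction
  per question, and cumulative 0–8 / reduced 0–4 concern scores.
* **Stratum-specific likelihood ratios.** For score stratum *s* with
  condition counts *d_s* (DLD) and *t_s* (TLD),

  SSLR_s = (d_s / d_tot) / (t_s / t_tot),

  with log-method 95% intervals, interpretation bands, and
  sparse-stratum collapsing.
* **Bayes pretest→posttest updating** on the odds scale:
  odds_post = p/(1−p) × Π LR_j, optionally chaining the score SSLR
  with the likelihood ratio of a dichotomized biological/environmental
  covariate (e.g. preschool years split at the within-age median).
* **Question screening**: phi / Cohen's d with interpretation bands,
  uncorrected Pearson χ² (so χ² = nφ² exactly), Woolf odds-ratio CIs,
  logistic regression by IRLS with AIC stepwise selection, and
  ROC/AUC with DeLong confidence intervals.
* **Synthetic cohorts**: a one-factor latent-severity generator
  calibrated exactly to per-condition marginal risk rates, so the whole
  pipeline is testable without child-level clinical data.

## Worked example

The published overall count table (185 DLD / 495 TLD children scored
0–4 on the reduced questionnaire) ships with the package:

```r
library(dldscreen)
tab <- read_stratum_table(system.file("extdata",
        "plcq4_strata_overall.csv", package = "dldscreen"))
utility_report(tab, pretest = 0.12)
#>  stratum dld tld  sslr     band pretest_prob pretest_odds posttest_odds posttest_prob
#>        4  46  14 8.792 moderate         0.12        0.136         1.199          0.55
#>        3  57  38 4.014    small         0.12        0.136         0.547          0.35
#>        2  28  71 1.055     none         0.12        0.136         0.144          0.13
#>        1  27 104 0.695     none         0.12        0.136         0.095          0.09
#>        0  27 268 0.270    small         0.12        0.136         0.037          0.04
```

Reading: a child whose parent reports all four concerns moves from the
12% background DLD probability to 55% (pretest odds 0.136 × SSLR 8.792
= posttest odds 1.199); a child with no concerns drops to 4%. Scores of
1–2 barely move the needle. The raw 0–4 score discriminates well on its
own:

```r
ex <- expand_strata(tab)
roc_auc(ex$score, ex$condition)
#> ROC: AUC = 0.7912 (95% CI 0.7523, 0.8301; DeLong), 185 vs 495
```

Chaining a second test — the preschool-attendance indicator with
likelihood ratio 1.829 below the within-age median — with the top
stratum of the complete-responder subgroup:

```r
update_probability(0.12, c(4.367, 1.829))
#> pretest 0.12 (odds 0.136) x LR 4.367 x 1.829 -> odds 1.089, posttest 0.52
```

A full synthetic run (simulate → code → compare → select → utility):

```r
cfg <- pipeline_config(simulate = cohort_params(), seed = 7)
res <- run_pipeline(cfg)
res$manifest$selected_terms   # questions kept by stepwise AIC
res$utility                   # SSLR + probability-update table
```

## Command-line use

A thin wrapper over the package functions lives at
`inst/cli/dldscreen.R`:

```sh
Rscript inst/cli/dldscreen.R run-all --seed 7 --out out/
Rscript inst/cli/dldscreen.R utility --counts inst/extdata/plcq4_strata_overall.csv --out out/
```

See `vignettes/screening-utility.Rmd` for the model, its assumptions,
the generator's design and the package's numerical conventions.
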