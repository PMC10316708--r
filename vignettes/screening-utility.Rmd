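---
title: "Quantifying the screening utility of parental language concerns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the screening utility of parental language concerns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dldscreen)
```

## The problem

Developmental language disorder (DLD) is widely underdiagnosed where
standardized language assessment is scarce. Parents, however, observe
their children daily, and a handful of well-chosen questions about
parental linguistic concern carries real diagnostic information. This
package quantifies exactly how much: given a child's answers to a short
parental questionnaire, how should a clinician's estimate of the
probability of DLD change?

The package works with two questionnaire parts. The PLCQ (parental
linguistic concern questionnaire) holds eight yes/no questions about the
child's language; the BECQ (biological and environmental conditions
questionnaire) holds eleven variables — sex, three early problem flags,
age of first words, parental education, family history, preschool
attendance, and daily interaction and screen time.

## Risk-perception coding and the concern score

Each PLCQ answer is coded as a *risk perception* when it signals
concern: a "yes" on questions 1, 2, 4, 5, 7 and 8, or a "no" on the
positively phrased questions 3 and 6 ("Does your child talk as well as
other children of the same age?", "Does your child understand most of
what is said to him/her?"). The coding directions live in a shipped
schema file (`plcq_schema()`), so a permuted CSV can never silently
flip a question's direction. Risk perceptions are summed into a 0–8
score, and — after question screening reduced the instrument — into the
0–4 score over questions 1, 2, 5 and 8 that the utility analysis uses.

Missing answers propagate: they never count as risk, and a child with a
missing answer among the four reduced items is excluded listwise from
score-based strata (`score4 = NA`). Reports carry exclusion counts.

## Stratum-specific likelihood ratios and Bayes updating

The core statistic is the stratum-specific likelihood ratio. For score
stratum $s$,

$$\mathrm{SSLR}_s \;=\;
  \frac{P(\text{score}=s \mid \mathrm{DLD})}
       {P(\text{score}=s \mid \mathrm{TLD})}
  \;=\; \frac{d_s/d_\bullet}{t_s/t_\bullet},$$

estimated from a condition-by-score count table. Unlike a single
positive/negative likelihood ratio pair, SSLRs keep the ordinal
resolution of the score: a score of 4 and a score of 3 shift the
probability by different amounts.

A pretest probability $p$ (default 0.12, an external prevalence
estimate for DLD among Mexican 4–6-year-olds) is updated on the odds
scale,

$$\mathrm{odds}_{\text{post}} = \frac{p}{1-p} \times
  \prod_j \mathrm{LR}_j, \qquad
  p_{\text{post}} = \frac{\mathrm{odds}_{\text{post}}}
                         {1+\mathrm{odds}_{\text{post}}},$$

where the product may chain the score's SSLR with the likelihood ratio
of a second, dichotomized variable (e.g. preschool-attendance years
split at the within-age median). Chaining assumes the two tests are
conditionally independent given condition status; that assumption is
stated, not validated, and is the main caveat on chained posttests.
LR interpretation uses the standard bands (≥10 or ≤0.1 large, 5–10 or
0.1–0.2 moderate, 2–5 or 0.2–0.5 small, otherwise none); a ratio and
its reciprocal always land in the same band.

`sslr()` also attaches a 95% interval from the log-method standard
error $\sqrt{1/d_s - 1/d_\bullet + 1/t_s - 1/t_\bullet}$. This is a
package extension — published SSLR tables of this kind typically print
none — and is labelled as such.

### Sparse strata

Score strata with fewer than `min_count` children in either group
(default 5, the situation that arises when very few children reach the
top score in a subgroup) are merged by `collapse_sparse()` into the
adjacent stratum closer to the count-weighted center of the
distribution, so sparse tails fold inward. Merged labels become ranges
("3-4"); totals are conserved exactly. The default of 5 reflects the
usual small-expected-count rule of thumb for ratio estimates.

### Numerical conventions

Probabilities, odds and SSLRs are kept at full precision internally;
print methods round SSLRs and odds to 3 decimals and probabilities to
2, matching the conventions of published utility tables. Zero-cell
strata produce infinite or zero sentinels by default; a flagged
Haldane-style +0.5 correction is available (`correction = TRUE`) but
off by default, since well-formed stratum tables rarely need it.
A boundary value exactly at a dichotomization median goes to the
"≤ median" class.

## Question screening

Two complementary routes identify which questions matter.

*Effect sizes.* `compare_questions()` tabulates each question's risk
rate by condition and reports the phi coefficient with the categorical
interpretation bands (null < 0.1 ≤ small < 0.3 ≤ medium < 0.5 ≤ large),
an uncorrected Pearson chi-square p-value, and an odds ratio with a
Woolf 95% CI. The chi-square is deliberately uncorrected so the
identity $\chi^2 = n\varphi^2$ holds exactly; continuous variables use
Welch's t and Cohen's d (pooled-SD form by default, the classical
pairing even alongside Welch testing; a Welch-style denominator is
available via `pooled = FALSE`). No multiplicity adjustment is applied
across the eight questions — the screening is descriptive — but reports
annotate the number of tests performed.

*Model selection.* `fit_logistic()` implements the binomial-logit fit
by iteratively reweighted least squares: convergence when the
log-likelihood moves by less than 1e-10 (at most 50 iterations, both
configurable), Wald standard errors from the final information matrix,
and explicit errors for separation (diverging linear predictor) and
singular designs (naming the collinear columns). `stepwise_aic()`
searches bidirectionally from the full eight-question model, applying
at each step the single-term addition or deletion with the lowest AIC
($2k - 2\ell$) and stopping when no move improves it; ties break
deterministically by term order, and the move sequence is returned.
Bidirectional-from-full is the convention of R's `step()`, the most
plausible default for this kind of analysis; pure forward and backward
searches are options. Note one property of pure-AIC selection worth
knowing: an uninformative question still enters with probability
$\approx P(\chi^2_1 > 2) \approx 0.16$, so selected sets can carry a
stray near-null term; its odds ratio will sit indistinguishably close
to 1.

*Discrimination.* `roc_auc()` builds the empirical ROC over all
distinct thresholds; the trapezoidal AUC equals the tie-corrected
Mann–Whitney probability that a child with DLD outscores one with
typical development (ties count half). The 95% CI uses DeLong's
placement-value variance — deterministic, unlike a bootstrap, which is
why it is the default. Coordinates export via `roc_coordinates()` for
plotting; the package draws no figures itself.

## The synthetic cohort generator

No child-level data accompany the published analysis, so the package
ships a generator (`generate_cohort()`) that emulates the cohort
structure every stage assumes:

* three age groups (default 240/225/215 children) with age-specific
  DLD prevalences (defaults 0.35/0.26/0.19, the observed group
  composition);
* per-question marginal risk-perception rates by condition (defaults
  are the observed group percentages, e.g. 75% vs 37% for question 1);
* inter-question dependence through a single latent severity factor:
  question $q$ is perceived as a risk when
  $\rho z + \sqrt{1-\rho^2}\,\varepsilon_q > \tau_q$ with $z$ shared
  within child. Because the mixture is standard normal for any
  $\rho$, calibration is exact: $\tau_q = \Phi^{-1}(1 - p_q)$
  (`calibrate_threshold()`), so marginal rates are honored at every
  dependence level. The default $\rho = 0.5$ is a modeling choice —
  nothing in the published tables identifies the dependence — and the
  one-factor form is the simplest structure consistent with parents
  attending to a child's overall severity;
* BECQ variables from per-condition distributions
  (`default_becq_params()`): Bernoulli flags and lower-truncated
  normals with plausible cohort-level settings. Preschool years get
  age-specific means of 1.5/2.5/3.5 years so within-age medians land
  near the published dichotomization cut points, with the DLD mean
  shifted down by 0.2 pooled SDs by default — deliberately
  conservative, since the subgroup-level effect estimates are
  unstable.

A single integer seed drives everything through one substream per age
group, so regenerating one age group is stable under changes to the
others, and equal seeds give byte-identical cohorts.

What the generator does *not* emulate: age-dependence of risk rates
within condition, item-wording effects, informative missingness, and
any dependence structure beyond one factor. Tests passing on synthetic
cohorts therefore validate the *estimators* — calibration, recovery of
planted effects, conservation identities — not the clinical claims
about real children.

## Problem sizes used by the test suite

Property-style checks use cohorts of $n = 10^5$ (marginal calibration
within 3 binomial SEs; end-to-end SSLR recovery against an exhaustive
$2^4$-pattern oracle within 3 log-scale SEs; planted-model stepwise
recovery), 1,000 random stratum tables for the SSLR conservation
identity $\sum_s \mathrm{SSLR}_s\,P(s\mid\mathrm{TLD}) = 1$, and 20
seeds at $n = 5{,}000$ for the no-signal selection rate. These sizes
make sampling error a small fraction of the tested tolerances while
keeping the default suite quick.

## Known limitations

* SSLR confidence intervals and the DeLong AUC interval are asymptotic;
  both degrade in strata of a handful of children (which
  `collapse_sparse()` exists to prevent).
* Chained posttest probabilities inherit the conditional-independence
  assumption discussed above.
* The generator's BECQ distributions are plausible defaults, not fits;
  conclusions about BECQ variables on synthetic data reflect those
  defaults.
* Stepwise AIC inherits the usual caveats of stepwise selection;
  selected-model standard errors do not account for the selection step.
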