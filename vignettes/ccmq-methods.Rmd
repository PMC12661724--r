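---
title: "Methods: CCMQ scoring, classification and prevalence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCMQ scoring, classification and prevalence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmq)
library(dplyr)
```

## The instrument and its scoring model

The Constitution in Chinese Medicine Questionnaire (CCMQ, 2016 revision)
classifies adults into nine Traditional Chinese Medicine body
constitutions: one balanced constitution and eight unbalanced ones (Qi
Deficiency, Yin Deficiency, Yang Deficiency, Phlegm Dampness, Damp Heat,
Blood Stasis, Qi Stagnation, Inherited Special). The instrument has 54
items administered as 57 five-point Likert questions ("never" = 1 to
"always" = 5, "sometimes" = 3 in the middle), because the allergy-related
item of the Inherited Special scale is asked as four separate questions.
Each question belongs to exactly one constitution; the per-constitution
question counts are 7, 6, 6, 7, 5, 6, 7, 7 and 6 (in the order Balanced,
Qi Deficiency, Yin Deficiency, Yang Deficiency, Phlegm Dampness, Damp
Heat, Blood Stasis, Qi Stagnation, Inherited Special).

For a constitution with $N$ questions, the raw score is the sum of the
$N$ (polarity-adjusted) responses, so it ranges over $[N, 5N]$, and the
converted score rescales it to a dimensionless 0–100:

$$\text{converted} = \frac{\text{raw} - N}{4N} \times 100.$$

Converted scores therefore live on the lattice $\{100k/(4N)\}$,
$k = 0, \dots, 4N$: steps of 5 for a 5-question scale, about 4.17 for 6
questions, about 3.57 for 7. We never round before thresholding —
rounding first would flip classifications at lattice points such as
29.17 vs 30 — and round to one decimal only in presentation tables.

**Polarity.** Published CCMQ scoring reverse-codes some questions
(notably in the Balanced scale). The exact reverse-coded set is part of
the instrument's item table, which this package deliberately does not
reproduce; the schema carries a per-question `polarity` flag
(`direct`/`reverse`, effective response $6 - v$ when reversed),
defaulting to all-direct. Analysts whose raw data follow the original
coding should set the flags via `ccmq_schema(reverse = ...)` or a schema
JSON file; all downstream code is polarity-agnostic.

**Allergy item.** Because the scoring rule is stated at question level,
the default sums all four allergy questions into the Inherited Special
raw score with $N = 6$. An item-level alternative — collapse the four
questions to their maximum as one item value, giving $N = 3$ — is
available as `score_respondents(..., allergy = "max_item")`. The two
conventions are both defensible readings of the question/item
distinction; the question-level default follows the literal rule and is
used everywhere unless overridden.

## Decision rules and grouping

The ZZYXH/T157-2009 standard assigns per-constitution statuses from the
converted scores:

* **unbalanced constitution**: score $\ge 40$;
* **unbalanced tendency**: score in $[30, 40)$ — the printed "30–39
  range" is read as the half-open interval on the continuous scale so it
  meets "40 or higher" with no gap; 39.58 (a lattice point for $N = 6$)
  is a tendency;
* **balanced constitution**: Balanced score $\ge 60$ *and* all eight
  unbalanced scores $< 30$;
* **no classification**: Balanced $< 60$ and all unbalanced $< 30$.

Respondents are then partitioned into four groups: `balanced`,
`unbalanced_constitution` (at least one score $\ge 40$; also the group a
Balanced-scoring respondent lands in if any unbalanced score reaches
40), `tendency_only`, and `no_classification`. The primary
classification is the highest-scoring member of the relevant candidate
set. The standard is silent on ties; we break them by a fixed priority
order — descending overall prevalence in large community cohorts
(Qi Deficiency, Phlegm Dampness, Yang Deficiency, Yin Deficiency, Damp
Heat, Qi Stagnation, Inherited Special, Blood Stasis) — and always raise
a `tie` flag so the (rare) arbitrary choices are auditable. By
construction a balanced-group respondent has no tendencies: the rules as
written forbid the combination, and we follow the rules.

`classify_constitutions()` is validated against an independent
brute-force interpreter of the four rule statements on profiles drawn
from a boundary-spanning grid ({0, 29, 29.9, 30, 39, 39.9, 40, 59, 60,
100} per score), with dedicated tests at each threshold.

## Quality control

`qc_cascade()` applies the exclusions in a fixed order, so every
respondent receives exactly one disposition:

1. **missing responses** — any of the 57 responses absent; the
   classification requires complete responses and the package performs
   no imputation;
2. **middle-response contamination** — "sometimes" chosen for at least
   `middle_threshold` questions (default 50, i.e. 88% of 57). A
   mostly-3 responder scores near 50 on every scale and thus spuriously
   reaches all eight unbalanced constitutions, a biologically
   implausible pattern interpreted as low engagement. The threshold is a
   parameter: 29 ($\ge$ 50%) is the stringent sensitivity setting and
   `Inf` disables the rule, reproducing the standard sensitivity
   analyses; exclusions are monotone in the threshold by construction;
3. **no classification** — scored but no rule fires; excluded from the
   analytic cohort.

The included cohort carries scores, classification and derived
covariates; the ledger accounts for every input row.

## Covariates

BMI groups follow the Working Group on Obesity in China cutoffs:
underweight $< 18.5$, normal $[18.5, 24)$, overweight $[24, 28)$, obese
$\ge 28$ kg/m². The printed one-decimal ranges ("18.5–23.9",
"24–27.9") are read as half-open intervals so the binning is exhaustive
(a BMI of 23.95 is normal, not unassigned). Age groups are 18–29,
30–49, 50–59, 60–69, 70+, plus the two-level 18–39 / 40+ split used in
the age-stratified composite analysis. Ages outside 18–80 are kept with
a warning rather than silently dropped, since cohort-entry criteria are
the caller's decision. Missing demographics propagate as missing strata;
models are complete-case with the n used reported.

## Prevalence, tests and models

Prevalence of a classification is its count over the full analytic
sample (or the subgroup size when stratified); tendency-only respondents
always stay in denominators. Crude prevalences carry Wilson 95%
intervals — an addition of this package, labelled as such, since
reference tables typically print none. Composite and tendency
proportions by primary constitution use the within-primary denominator;
the test suite constructs cohorts where the two denominators differ to
guard against mixing them.

Group differences use Pearson chi-squared tests (no continuity
correction) and linear trends across ordered groups use the 1-df
Cochran–Armitage-style statistic with integer scores (delegated to
`stats::prop.trend.test`, cross-checked against a score-regression
oracle). Nine constitution-wise tests are a family: the significance
flag applies $\alpha = 0.05/9 \approx 0.006$ (Bonferroni).

Associations are estimated by **modified Poisson regression**: a
log-link Poisson GLM on the binary outcome, so exponentiated
coefficients are prevalence ratios, with HC0 sandwich standard errors
(the Poisson variance is misspecified for binary data) and robust Wald
95% intervals. On a 2×2 design with no covariates the fitted PR equals
the ratio of proportions to machine precision, which the suite asserts.
Separation (an exposure level with all or no events) is rejected with
the level named rather than silently producing infinite estimates.
Adjustment covariates default to age group and sex; age can equally be
supplied as a continuous column — the choice between categorical and
continuous age is genuinely open in this design, and we default to the
5-level category that matches the reporting tables.

**Marginal standardization** (estimated marginal means): for each
exposure level, every cohort member's exposure is set to that level, the
model's predicted probabilities are averaged, and the mean is reported
as the adjusted prevalence. The log link can predict probabilities
above 1 for extreme covariate patterns; predictions are truncated at 1
and the truncation count is reported and warned about — the standard
remedy, made visible.

## The synthetic cohort generator

No respondent-level data ship with the package, so
`simulate_respondents()` generates cohorts with known ground truth. The
generator works top-down:

1. **Demographics** are drawn from marginals typical of a large urban
   community cohort (about 61% female, 80% aged 30–70, half normal-BMI;
   education, income, work, marital, smoking and drinking categories
   with realistic mass). Demographic variables are mutually independent
   given the class structure — a simplification; real cohorts correlate
   age with work status, smoking with sex, and so on.
2. **Latent class**: each respondent is assigned balanced, one of eight
   primary unbalanced constitutions, tendency-only, or
   no-classification. The default class mix is the headline
   classification distribution of such cohorts (balanced 22.3%, Qi
   Deficiency 16.4%, Phlegm Dampness 11.0%, Yang Deficiency 9.4%, Yin
   Deficiency 6.1%, Damp Heat 4.6%, Qi Stagnation 2.5%, Inherited
   Special 1.1%, Blood Stasis 0.8%, tendency-only 25.8% of classifiable
   profiles) plus 5% unclassifiable. Covariate effects enter as logit
   shifts with the directions reported in the field — obesity raises
   Phlegm Dampness and lowers Balanced, Yang and Yin Deficiency; age
   raises Balanced and Yang Deficiency and lowers Qi Stagnation and
   Inherited Special; male sex raises Phlegm Dampness and Damp Heat —
   and the class intercepts are re-calibrated by fixed-point iteration
   so the population marginals match the target mix whatever the
   effects. Magnitudes (0.1–1.5 on the logit scale) were chosen once as
   plausibly strong epidemiological effects.
3. **Target scores**: the class implies a target converted score per
   constitution, drawn uniformly from lattice values inside bands
   (primary 52–71, secondary constitutions 41 up to 8 points below the
   primary so the primary identity is noise-stable, tendencies 30–37,
   background 3–23, balanced 66–93 for balanced profiles). Composite
   membership uses per-primary probabilities (43.6%–72.2%, higher for
   the rarer constitutions, shifted up by 0.45 logits under age 40), and
   partner constitutions are drawn with co-occurrence boosts; the boost
   magnitudes were set once so that the strongest published pairings
   (Qi Stagnation with Qi Deficiency near 56%, Damp Heat with Phlegm
   Dampness near 40%) emerge at large n. The intended group and primary
   are obtained by running the package's own classifier on the target
   scores, which makes the zero-noise round trip exact by construction.
4. **Responses**: each target raw score is split across its
   constitution's questions as evenly as possible (the inverse of the
   conversion formula), then each response is perturbed by ±1 with
   probability `response_noise` (default 0.02) and clipped to 1–5. The
   even-split-plus-jitter scheme is one discretization among many; we
   chose it over rounding a continuous draw because it keeps the
   zero-noise case exact and makes the noise scale interpretable (one
   jitter moves a score by one lattice step). The default rate keeps
   latent profiles identifiable; real Likert data are noisier, and the
   suite verifies separately that under heavy noise (0.25)
   misclassification concentrates on respondents whose targets sit near
   the 30/40/60 thresholds.
5. **Contamination** (default 0.175%, matching careful field work)
   replaces a respondent's answers with "3" on 52 questions and random
   values elsewhere; missingness (default 0.1%) blanks 1–3 random
   responses. Both are injected last, so contaminated respondents'
   intended labels describe what they would have been.

Everything is deterministic under `seed`; identical spec and seed give
byte-identical files.

What passing tests on this generator show — and do not show: they
validate the arithmetic, the rule engine, the estimators' calibration
(CI coverage, type-I error) and the pipeline's ability to recover a
known population structure. They do not validate the CCMQ as an
instrument, nor do they show that real populations follow the
generator's independence and band assumptions; the joint distribution
of the nine scores in real data (in particular the correlation structure
among unbalanced scales) is unpublished, and the pairwise-boost model is
a stated modelling choice, not an estimate.

## Problem sizes and runtime choices

The validation suite uses cohorts of 150–20,000 respondents: boundary
grids of 2,000–12,000 profiles for rule-engine agreement, 200
replicates of n = 10,000 for PR interval coverage, 1,000 replicates of
n = 2,000 for chi-squared type-I error, and a single n = 20,000 cohort
for full-pipeline prevalence recovery (within three binomial standard
errors of the target mix). These sizes keep Monte Carlo error well below
the assertion tolerances while the whole suite runs in a few minutes on
one core.

## Known limitations

* The schema ships structure only (counts, item grouping, polarity
  slots), not item text or the published reverse-coded set; users must
  supply polarity flags to match their data coding.
* Exact threshold values 30, 40 and 60 are not attainable on every
  scale's score lattice (e.g. 60 is not a multiple of 100/28), so some
  boundary cases exist only as synthetic score profiles, which is how
  the tests exercise them.
* No survey weights: analyses treat the cohort as a simple sample, as
  the reference analyses do despite quota sampling.
* Marginal standardization truncates out-of-range log-link predictions;
  with strong continuous covariates the truncation count should be
  inspected.
* The generator's demographic independence and its tie between class
  and scores are simplifications; it is a test harness with known
  truth, not a population model.
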