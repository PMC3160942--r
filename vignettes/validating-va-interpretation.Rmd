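---
title: "Validating verbal-autopsy interpretation against a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating verbal-autopsy interpretation against a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vaval)
library(dplyr)
```

## The problem

Where deaths are not medically certified, verbal autopsy (VA) — a
structured interview with the household of the deceased — is the main
source of cause-of-death information. Two interpretation routes are in wide
use: physician-certified VA (PCVA), where a trained physician reads the
questionnaire and assigns a cause, and probabilistic interpretation, where
a Bayes model converts the questionnaire's binary sign/symptom indicators
into likely causes. Neither is a gold standard, so validation studies
compare both against the best available reference — usually the hospital
cause of death (HCOD) for deaths that occurred in a facility with
laboratory support — and ask two questions:

1. **Population level**: do the cause-specific mortality fractions (CSMF)
   match? Public-health planning needs the distribution of causes, not
   individual diagnoses, so CSMF agreement within a few percentage points
   is the headline criterion.
2. **Individual level**: do the methods agree death by death? This is
   measured by chance-corrected agreement (Cohen's and Fleiss' kappa),
   per-cause diagnostic validity (sensitivity, specificity, PPV, NPV) and
   an overall ROC/AUC summary.

`vaval` implements the full comparison pipeline, and — because case-level
validation datasets are rarely publishable — a synthetic-cohort generator
with a known ground truth, so every stage of the pipeline can be tested
quantitatively.

## The assignment engine

For a death with indicator values $s_i \in \{\text{present}, \text{absent},
\text{unknown}\}$ and a cause list $c = 1, \dots, K$, the engine scores

$$
P(c \mid s) \;\propto\; \pi(c) \prod_{i} L_i(c), \qquad
L_i(c) =
\begin{cases}
p_{ic} & s_i = \text{present} \\
1 - p_{ic} & s_i = \text{absent} \\
1 & s_i = \text{unknown},
\end{cases}
$$

with $p_{ic} = P(s_i = \text{present} \mid c)$ the emission matrix and
$\pi$ the cause priors. Three choices deserve comment:

- **Unknown indicators contribute nothing.** VA questionnaires rarely
  cover every indicator an interpretation model expects; treating a null
  item as "no evidence" (likelihood 1) rather than "absent" keeps
  incomplete questionnaires from biasing the posterior. Absent indicators
  do carry evidence, via $1 - p_{ic}$ — the standard naive-Bayes treatment.
- **Log-space accumulation.** Products of hundreds of probabilities
  underflow; scores are accumulated as sums of logs and normalized with
  the log-sum-exp trick. The test suite verifies agreement with a direct
  product implementation to $10^{-9}$.
- **Conditional independence given cause** is assumed, as in all engines
  of this family. Real symptoms are correlated (e.g. fever and chills);
  the synthetic generator makes the same assumption, so parameter-recovery
  results quantify estimation error under the model, not model
  misspecification.

Priors can be adjusted for the local prevalence of designated causes with
`apply_prevalence()`: a "high" flag multiplies the cause's prior by 5, a
"low" flag by 0.2 (defaults; reciprocal so a high-then-low round trip is
the identity), followed by renormalization. The order-of-magnitude spread
reflects how strongly the population prevalence of causes like HIV and
malaria varies between settings; the multipliers are configurable because
no canonical value exists.

### Reporting policy

Engines of this type report up to three likely causes. The thresholds real
implementations use are not public, so the policy is explicit and
configurable (`reporting_policy()`): the top cause is reported only if its
normalized posterior reaches `top_min` (default 0.4, otherwise the death
is *indeterminate*), and a second or third cause only if it reaches
`extra_frac` (default 0.5) times the top posterior. The defaults were
chosen so that, on informative indicator sets, output is dominated by
single-cause assignments with a small indeterminate remainder — the
qualitative pattern VA studies report (roughly 80% single-cause, a few
percent indeterminate). Ties are broken by cause-list order, so batch runs
are reproducible.

Percentages in all summaries use round-half-up at the printed precision
(`round_half_up()`), the convention of mortality tabulations; note that
published tables do not always follow a single convention, so small
one-unit discrepancies against printed percentages in the literature are
possible for borderline fractions.

## The synthetic cohort

`simulate_cohort()` draws each death's true cause from a specified CSMF,
then draws each indicator Bernoulli from the emission matrix, flips it
with probability `flip_noise` (reporting error by the respondent), and
blanks it with probability `missing_rate` (items absent from the
questionnaire). `build_probability_matrix()` constructs a signature-block
emission matrix: each cause owns a random block of indicators that fire
with probability $0.5 + 0.5\,\iota$ while background indicators fire with
$0.5(1 - \iota)$. The single parameter $\iota$ (`informativeness`) is then
a monotone difficulty dial: $\iota = 1$ makes indicators a deterministic
function of cause, $\iota = 0$ makes them pure noise.

Raters (the hospital diagnosis and the physician coder) are modelled by
row-stochastic confusion matrices plus an indeterminate rate
(`rater_model()`, `simulate_rater()`). One study seed drives everything;
per-stage substreams (matrix, cohort, each rater, bootstrap) are derived
from it, so re-running one stage never disturbs another.

What the generator *does not* emulate — and what green tests therefore do
not establish about field data: symptom correlations beyond cause
membership, cause-dependent missingness, age/sex-dependent symptom
profiles (age and sex are generated only as stratifiers), interviewer
effects, and systematic (non-random) rater biases such as a physician's
tendency to over-diagnose a familiar disease. Confusion matrices can
encode such biases if supplied explicitly.

## The study design

`run_validation()` executes the complete design on a `study_config()`:
simulate → rate → assign → recode → resolve → compare. Its defaults
emulate a small adult hospital-based validation study:

- **145 deaths** over an **11-category** condensed cause list, with five
  major causes (HIV/AIDS-related, cardiovascular, tuberculosis, diabetes,
  meningitis) carrying roughly 60% of deaths — the scale and shape typical
  of single-site VA validation cohorts.
- **40 indicators**, informativeness 0.8, flip noise 0.05, missingness
  0.10: an informative but imperfect questionnaire.
- **Hospital rater** accuracy 0.95 (laboratory-supported diagnosis is good
  but not infallible), no indeterminates; **physician coder** accuracy
  0.60 with a 1.4% indeterminate rate — chosen to land the PCVA-vs-gold
  kappa in the "moderate" band where field studies typically find it.
- HIV and malaria priors flagged **high**.

Comparisons use only the primary cause of each method. One asymmetry of
the design is deliberate: when the engine's top cause disagrees with the
gold standard but its second or third listed cause matches, the matching
cause is carried into the cross-tabulation
(`resolve_comparison_cause()`) — the resolution rule validation studies
describe. Resolution happens *before* dichotomization into one-vs-rest
2×2 tables, and before kappa; the reported output mix is unaffected.

```{r run}
report <- run_validation(study_config(seed = 1))
report
```

All tables are plain tibbles:

```{r tables}
report$kappa_table |> filter(stratum == "total")
report$validity$interva |> select(cause, sensitivity, specificity, ppv, npv)
head(report$tolerance$interva)
```

## Statistical choices

**Cohen's kappa.** $\kappa = (P_A - P_E)/(1 - P_E)$ from the K×K
cross-classification; the confidence interval uses the
Fleiss–Cohen–Everitt large-sample standard error. When both raters are
constant and identical ($P_E = 1$), kappa is undefined and reported as
`NA` with a warning, never silently as 1 or 0.

**Indeterminate convention.** An indeterminate call carries no diagnostic
content, so by default it matches nothing — including another
indeterminate. Internally each rater's indeterminates become
rater-specific categories before the kappa computation (marginals are
preserved; shared indeterminates simply never land on the diagonal). The
alternative conventions (`"drop"` the cases, or `"agree"` on shared
indeterminates) are available because published studies rarely state
theirs. The same convention drives `agreement_indicator()`, the per-death
"at least two methods agree" flag.

**Multirater kappa** is Fleiss' kappa over subjects × raters ×
categories. Its sampling distribution is awkward in closed form under
category sparsity, so the CI is a seeded subject-level bootstrap
(percentile, default 2000 resamples; 500 in the pipeline default to keep
routine runs fast — configurable).

**Validity metrics** are one-vs-rest: sensitivity $= 100\,TP/(TP+FN)$,
specificity $= 100\,TN/(TN+FP)$, PPV $= 100\,TP/(TP+FP)$, NPV
$= 100\,TN/(TN+FN)$, with exact binomial (Clopper–Pearson) 95% intervals —
appropriate at the small denominators a 145-death study produces. A zero
denominator leaves the metric undefined (`NA`), not zero. The five causes
in `validity_table()` are the most frequent in the gold standard, ties
broken by cause-list order.

**ROC for hard classifiers.** A method that emits one cause per death has
no score to threshold. The curve is therefore built from per-cause
operating points — each cause's (1 − specificity, sensitivity) from its
one-vs-rest table — anchored at (0,0) and (1,1), sorted by FPR, and
integrated by trapezoid. This is a documented construction choice, not a
claim about how any particular published curve was drawn; it is the only
construction that yields a curve for a score-free method like physician
coding. For the engine, a genuine score-threshold ROC over pooled
(death, cause) posterior pairs is also provided (`roc_scores()`), whose
trapezoidal area equals the Mann–Whitney concordance probability.
Adequacy is `auc > 0.75`, strict. No binormal smoothing is applied —
smoothing would invent information the data do not contain.

**Strength scale** for kappa: < 0.21 poor, 0.21–0.40 fair, 0.41–0.60
moderate, 0.61–0.80 good, > 0.80 very good, upper boundaries inclusive.

## Numerical and degenerate-input behaviour

- Posterior normalization happens in log space with max-subtraction; an
  indicator profile impossible under the matrix (score 0 for every cause)
  yields a degenerate posterior, which `batch_assign()` converts to an
  indeterminate assignment with a flag rather than an error.
- CSMF over zero deaths is an error; an empty cohort through
  `batch_assign()`/`output_mix()` yields a structurally valid all-zero
  summary.
- Cause-map recoding is total: mapped labels recode, already-condensed
  labels pass through (making recoding idempotent), anything else falls
  to the configurable default category with a warning naming the label.
  Matching is case-insensitive on trimmed strings; deliberately no fuzzy
  matching, so every recode is auditable.
- All tie-breaks (assignment order, top-cause ranking, validity-table
  selection) follow cause-list order, making every pipeline product a
  deterministic function of the seed; the determinism test compares
  artifacts byte for byte.

## Problem sizes used in the test suite

The suite validates formulas against brute-force oracles on dozens of
randomized tables of up to 50 cases; distributional limits (chance-level
kappa, null AUC) use 5,000–10,000 draws, where binomial noise is a few
hundredths; CSMF parameter recovery uses 1,000 deaths over five causes at
informativeness 0.8 and 5% flip noise, where the engine recovers each
cause fraction to well within five percentage points; and full-pipeline
properties run at the default 145-death scale. These sizes were chosen so
each check's sampling noise is small relative to the tolerance it asserts.

## Known limitations

- The engine accepts any user-supplied probability matrix but ships none:
  published engines' internal probability tables are proprietary expert
  elicitations, and the built-in generator exists precisely so the
  pipeline can be validated without them.
- The condensed cause list shipped for demonstrations has 11 categories;
  real condensed lists run to ~35 categories and are supplied by the user
  together with their cause map.
- Fleiss' kappa assumes every subject is rated by the same number of
  raters; deaths missing one method's assignment must be filtered first.
- CSMF tolerance checks compare point estimates only; no sampling
  uncertainty is attached to CSMF differences at n = 145.
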