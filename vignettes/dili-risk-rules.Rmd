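---
title: "Methods: DILI risk rules, ATC scans and docking-score statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DILI risk rules, ATC scans and docking-score statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilirules)
```

## The problem

Drug-induced liver injury (DILI) is idiosyncratic, rare per patient, and
responsible for a large share of post-marketing warnings and withdrawals.
Because prospective detection is hard, a productive line of work asks which
properties a drug carries *before* it reaches patients — daily dose,
lipophilicity, extent of hepatic metabolism, molecular weight — predict a
DILI signal on its label. `dilirules` packages that analysis: grade each
drug's liver-injury severity from its label, scan drug classes for
association, test conjunctions of property thresholds, and relate predicted
protein-binding strength (docking scores) to the same outcome.

## Severity grading

Each drug carries a set of label endpoints from a fixed seven-token
vocabulary plus three regulatory flags. The grade is

- **severe** — any of fatality, liver failure, liver transplantation, or any
  of the Hy's-law, black-box or withdrawal flags;
- **less_severe** — otherwise, any of hepatitis, hepatomegaly, jaundice,
  abnormal biomarkers;
- **none** — otherwise.

Two modelling choices are worth making explicit. First, the regulatory
criteria are kept as flags separate from the seven endpoint tokens, so the
endpoint vocabulary stays exactly the label vocabulary; the flags still
force the severe grade. Second, dominance (severe > less-severe > none) is
explicit: a drug with both jaundice and liver failure grades severe. Group
definitions are only self-consistent under this dominance, and it gives the
useful invariant that adding endpoints never lowers a grade — which is
property-tested.

## Association statistics

All associations reduce to a 2×2 exposure-by-outcome table (a, b, c, d).

- **Odds ratio.** The default estimator is the cross-product ad/bc. It is
  the default because it exactly reproduces the reference rule tables this
  package ships (e.g. (22·612)/(3·542) = 8.28). The conditional maximum
  likelihood estimate under the noncentral hypergeometric model is exposed
  as an alternative (`estimator = "conditional_mle"`, delegated to
  `stats::fisher.test()`); for extreme tables such as a 43/1 exposed split
  the two differ by a few percent, and published class-level odds ratios in
  this literature are sometimes consistent only with the conditional
  estimate. Reports carry an `estimator` column so the choice is visible.
- **Confidence interval.** Woolf's log-normal interval
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d)). It reproduces every reference interval
  we check to the printed 2 d.p.; exact conditional intervals are not
  provided.
- **Fisher exact p.** Implemented directly as the two-sided tail sum: over
  the hypergeometric support with the observed margins, sum the point
  probabilities not exceeding the observed one. Floating-point ties use a
  relative tolerance of 1e-7, the usual convention for this test. Degenerate
  margins (an empty row or column) return p = 1. The implementation is
  verified exhaustively against an independent log-binomial-coefficient
  enumeration on every table with total at most 30, and spot-checked against
  `stats::fisher.test`.
- **Zero cells.** The default policy is the Haldane–Anscombe correction
  (+0.5 to all four cells) with a warning, because ATC scans over sparse
  categories hit zero cells routinely; a strict `"error"` policy is
  available.
- **Rounding.** Statistics are computed and stored at full precision;
  `format_associations()` applies report-layer rounding only (2 d.p. for
  OR/CI/PPV, 3 significant digits for p).

## Outcome modes

`"dili"` contrasts any DILI (severe or less-severe) against none over all
graded drugs. `"severe"` contrasts severe against none and **excludes**
less-severe drugs from both arms. The exclusion is an inference from the
reference severe-mode tables, whose no-outcome arms match the no-DILI group
size rather than the full non-severe complement; it is applied uniformly.

## The rule engine

The canonical predicate library is 400 ≤ MW < 600 Da (half-open, as
printed in the source tables), LogP ≥ 3, DDD ≥ 100 mg/day and LM ≥ 50%
(LM is stored in percent, not as a fraction). `enumerate_rules()` builds all
2^k − 1 conjunctions in a deterministic order (size, then label); labels use
the fixed property order MW, LogP, DDD, LM so they are canonical.

Two evaluation-cohort choices are configurable because the underlying
design is genuinely ambiguous:

- **Missing values** default to `"negative"`: a drug with a missing property
  stays in the cohort and fails the predicate. This is what makes every
  rule's four cells sum to one common denominator, which is how the
  reference tables behave; `"exclude"` drops such drugs instead.
- **Kinase inhibitors** (ATC `L01XE`) are excluded from the evaluation
  cohort by default (`include_kis = FALSE`), reflecting a derive-on-KIs /
  validate-on-the-rest design in which the reference denominators equal the
  cohort minus the KI class; `include_kis = TRUE` evaluates on everyone, and
  the synthetic-recovery checks use it because the generator plants its
  effect on the full cohort.

## ATC scans

At level k the scan forms one 2×2 table per distinct code prefix (lengths
1/3/4/5 for levels 1–4). A drug with several codes in one category counts
once; drugs without codes are unexposed everywhere. Categories covering all
or none of the eligible drugs are skipped (no second arm), and
`min_exposed` (default 1, matching the reference behaviour) can suppress
unstable sparse categories. The default multiplicity correction is `"none"`
because the reference analysis reports raw Fisher p-values;
Benjamini–Hochberg is available and tested against a hand-coded step-up.

## Docking-score statistics

The input is a drugs × proteins matrix of best docking scores in kcal/mol
(more negative = stronger predicted binding), one score per pair; selecting
the best pose per pair is upstream of this package.

- **Normalization.** Z_ij = (X_ij − X̄_j)/SD(X_j) per protein column, with
  the sample SD (divisor N_j − 1, exactly as the defining formula states).
  Missing entries stay missing and are excluded from the column statistics;
  columns with fewer than two scores or zero variance raise errors naming
  the protein. The often-quoted "normalized to a range between −4 and 4" is
  interpreted as winsorization after z-scoring: `clip_bound` defaults to 4,
  and `NULL` gives unbounded z-scores (on which normalization is
  idempotent — the invariant the tests check).
- **Severity comparison.** Per-drug mean z-scores are compared with the
  Kruskal–Wallis rank test (tie-corrected; the all-tied degenerate case is
  defined as H = 0, p = 1), plus one-sided Wilcoxon comparisons of each DILI
  group — and the pooled all-DILI group — against no-DILI, directional
  because the scientific hypothesis is *lower* (stronger-binding) scores in
  DILI drugs. Groups under two drugs are dropped with a warning.
- **Class scans.** Each ATC category is compared one-vs-rest with a
  two-group equal-variance ANOVA (F = t² for two groups, which is tested as
  an identity), sorted by p.
- **Protein ranking.** `top_proteins()` ranks by ascending mean score over a
  drug subset, ties by ascending SD then protein id. The raw kcal/mol matrix
  is the default ranking basis — subset means with SDs are conventionally
  reported on that scale — and passing a normalized matrix switches basis,
  since which basis underlies published per-protein tables is ambiguous.

## The synthetic generator

The generator exists so that every stage has a ground truth. Its defaults
are fixed to emulate a 1,223-drug oral-drug cohort and are not tuning
knobs:

- properties: MW log-normal (median 350 Da, σ_log 0.35), LogP normal
  (2.5 ± 1.8), DDD categorical on {5, 20, 50, 100, 200, 400} mg/day, LM a
  Beta(1.2, 1) scaled to [0, 100]. Jointly these put about 3–4% of drugs
  inside all four rule thresholds, a realistic prevalence for a conjunction
  of this kind;
- outcome: DILI odds are p₀/(1−p₀)·ω^I with baseline p₀ = 0.45,
  severe-given-DILI 283/605 (the severity split of the emulated cohort),
  and I the rule-of-four indicator computed on the *complete* property
  values. Because the rule indicator is the only covariate, the population
  odds ratio equals ω exactly (`expected_rule_or()`), making parameter
  recovery a clean calibration check; the default ω is 8;
- endpoints: each drug receives one guaranteed class-consistent token plus
  Bernoulli extras (severe drugs may also carry less-severe tokens and
  flags), so re-grading recovers the planted class deterministically —
  grading error is thereby isolated from rule-engine error in tests;
- missingness: applied after outcome assignment, default rates 0. A nonzero
  default would misclassify some truly rule-positive drugs as negative and
  attenuate the recovered odds ratio, confounding the calibration check;
  missingness is instead exercised explicitly where the missing-value
  policies are under test;
- ATC codes: one (occasionally two) 7-character codes drawn from a 12-prefix
  mixture including a kinase-inhibitor-like `L01XE` class at weight 0.036
  (≈ 44/1223), independent of properties and outcome;
- docking: score(i, j) = baseline_j + shift·1[class] + noise, with
  per-protein baselines around −7 kcal/mol, unit noise SD and a default
  class shift of −0.8 kcal/mol (i.e. −0.8 noise SDs).

What the generator deliberately does **not** emulate: correlations between
MW, LogP, DDD and LM across chemical space, per-predicate (rather than
whole-rule) outcome effects, class-outcome confounding (real KIs are both a
class and DILI-enriched), and heavy-tailed docking-score distributions.
Passing the planted-recovery and power checks therefore demonstrates that
the machinery is correct and calibrated under the stated model, not that
the rule of four generalises to any particular real cohort.

## Problem sizes and determinism

The calibration checks run at the sizes the contracts state: odds-ratio
recovery at n = 20,000 drugs × 100 seeds per planted ω ∈ {1, 2, 4, 8}
(coverage of the Woolf 95% interval ≥ 90%), grading round-trip at
n = 10,000, docking power and null at 1,000 drugs × 20 proteins over
100–200 seeds. All sampling is driven by explicit integer seeds;
regenerating with the same configuration is byte-identical, which the CLI
manifest (command, options, versions, input checksums, no timestamps)
relies on.

## Limitations

- The severity grade is only as good as the label tokens; the package
  grades strictly from tokens and does not attempt causality assessment
  (e.g. RUCAM scoring).
- Associations are crude 2×2 analyses; there is no stratified or
  regression-adjusted estimation, by design.
- Threshold values are fixed, literature-derived inputs; the package does
  not search for new cut-points, and nothing here validates thresholds on
  data they were derived from.
- Docking scores are predictions, not measurements; their statistics
  inherit every bias of the upstream docking protocol.
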