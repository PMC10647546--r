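---
title: "Methods: screening rules, penalty-weighted subset selection, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening rules, penalty-weighted subset selection, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscreen)
```

## The screening tool

The Children's Wisconsin Nutrition Screening Tool (CWNST) is a daily,
EMR-embedded nutrition risk screen for hospitalized children. A nurse
administers the Pediatric Nutrition Screening Tool (PNST) at admission; the
EMR then generates seven daily binary elements every morning at 06:00:

* active enteral nutrition (EN),
* active parenteral nutrition (PN),
* presence of intubation,
* two or more food allergies,
* a merged anthropometric flag — BMI-for-age z-score below −1 at two years
  corrected age and above, weight-for-length z-score below −1 below two
  years (the two are mutually exclusive by age, so the package treats them
  as one element),
* a subjective RD-identified-risk flag set by a dietitian's clinical
  judgment (never inferred by the engine), and
* the admission PNST result carried forward.

A patient screens positive when **any** element fires (`screen_positive()`).
Three status-change elements — intake below 50% of estimated needs, NPO
status, and unintentional weight loss of at least 5%, each sustained over
three or more consecutive days — are assessed on hospital day 4 and every
Monday, Wednesday and Friday thereafter (`status_change_days()`,
`evaluate_status_change()`).

### Threshold conventions

Published summaries of the tool are internally inconsistent about three
thresholds; the package follows the tool's stated definitions and treats
the table labels as rendering shorthand:

* food allergies: **two or more** (not strictly more than two),
* weight loss: **at least** 5% (inclusive),
* NPO / low intake / weight loss duration: **three or more** consecutive
  days.

The anthropometric threshold is strictly below −1 on both sides of the
age-two dispatch boundary, so the flag is branch-independent for a fixed
z-score. The weight-loss baseline is not defined by the tool's public
description; the package uses the **highest weight recorded in the current
admission, recomputed daily** — conservative (a transient gain raises the
baseline) and exactly reproducible from the record. Missing anthropometry
yields a negative flag plus a warning rather than an error, because a daily
automated screen cannot halt on a missing vital sign.

Z-scores are computed from caller-supplied Box-Cox growth-reference rows by
the LMS method (`lms_z()`): `((value/M)^L − 1)/(L·S)`, with the log-normal
limit `log(value/M)/S` used when `|L| ≤ 1e-12`. No growth reference is
bundled.

## Diagnostic accuracy

`severity_confusion()` cross-classifies predictions by the four-level
severity scale (none/mild/moderate/severe) without dichotomising; the
positive class — *any malnutrition*, or *moderate/severe only* with none
and mild grouped as negative — is applied downstream. Metrics follow the
standard ratio definitions; a metric with a zero denominator is reported
as `NA` ("undefined"), never coerced to 0 or 1.

Per-element association uses the two-sided Fisher exact test under the
probability-mass convention (sum of hypergeometric probabilities of tables,
at fixed margins, no more probable than the observed one) — the convention
of mainstream statistical software, cross-checked in the test suite against
exhaustive enumeration over every 2×2 table with total at most 30. A table
with a zero margin admits only itself, so its p-value is 1. Percentages are
rendered at one decimal, with a zero count rendered `0 (0%)`.

## Penalty-weighted best-subset selection

The selection statistic is a cost-sensitive misclassification penalty.
With default weights $(w_1, w_2, w_3, w_{fp}) = (1, 3, 5, 0.2)$:

$$
\mathrm{score} = w_1\,\mathrm{FN}_{mild} + w_2\,\mathrm{FN}_{moderate}
  + w_3\,\mathrm{FN}_{severe} + w_{fp}\,\mathrm{FP}_{none}
$$

under the all-levels definition. Under the moderate/severe-only
definition, missed moderate and severe cases keep their weights and every
flagged none-or-mild patient is charged $w_{fp}$ — the minimal extension
consistent with grouping none and mild as the negative class; the weights
remain configurable. With unit weights the score degenerates to the raw
misclassification count.

`enumerate_models()` scores **every** nonempty subset of the element
vocabulary (capped at 20 elements, i.e. $2^K - 1$ subsets) using the
screen's own any-positive rule as the subset's prediction rule — the
natural choice for an any-positive screen, made explicit here because the
selection procedure itself does not prescribe one. Status-change elements
are excluded from the default vocabulary because they fire too rarely to
inform selection (about 1–4% positivity); passing them in `elements`
re-includes them. Ties are never broken silently: all minimum-score subsets
per size are reported, ordered lexicographically by element name, which
also makes the output invariant to the order the vocabulary is supplied in.
OR-rule monotonicity guarantees that growing a subset never lowers
sensitivity and never raises specificity, so the FN-driven part of the
penalty is non-increasing and the FP-driven part non-decreasing in subset
growth — the property the tests verify on every nested chain.

## The synthetic cohort generator

Patient-level data from the evaluation study cannot be shared, so
`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes. The defaults are the study conditions: 250 RD-assessed
patients with severity multinomial 181/27/24/18
(none/mild/moderate/severe), per-element positivity conditional on the
no-vs-any malnutrition dichotomy equal to the published conditional
proportions (e.g. PN 29/181 vs 27/69, PNST 13/181 vs 24/69, anthropometric
flag 32/181 vs 40/69), and 918 never-assessed patients (severity sentinel
`"unknown"`) with the published marginal rates, including the structural
zeros for PN and RD-identified risk — both imply RD involvement, which
never happened for that stratum.

Severity is drawn first; elements are drawn conditional on the dichotomy
only, because the published conditional proportions condition on that
dichotomy, not on the severity grade. Ages are lognormal, truncated to
[0.01, 17] years by resampling, with parameters matched to each stratum's
published median and mean (assessed: median 2.0, mean 4.7; unassessed:
median 4.0, mean 6.4); about 10% of infants get a prematurity correction of
up to 0.25 years, so corrected age never exceeds chronological age. Ages
are plumbing for the anthropometric dispatch and carry no role in element
generation.

**Dependence.** The study reports only marginal rates, so any joint
structure is a modelling choice. The generator's default is conditional
independence (`dependence = 0`). To let downstream code be exercised
against correlated elements, `dependence` $d \in [0, 1)$ adds one shared
standard-logistic latent factor per patient to every element's log-odds
with loading $\lambda = \sqrt{d/(1-d)}$ (so $d$ is the shared fraction of
latent-scale variance); each element's intercept is then recalibrated by
numerically solving $E_z[\operatorname{logit}^{-1}(a + \lambda z)] = p$, so
the configured marginal rates are preserved at any dependence level.

**Determinism.** One master seed; each consumer (severity, ages, latent
factors, elements; separately per stratum) is seeded with
`(seed + stream × 1000003) mod (2^31 − 1)` (`child_seed()`), so resizing
one stratum never perturbs draws in another. Identical config and seed give
bitwise-identical cohorts.

**What passing tests do and do not show.** The generator reproduces the
study's margins and severity mix; it does not model within-stay severity
dynamics, admission/discharge processes, real element co-occurrence (e.g.
EN and NPO are drawn independently although they are clinically coupled),
or informative selection into RD assessment. Results on synthetic cohorts
therefore validate the *machinery* — rule engine, statistics, search — not
clinical conclusions about any real population.

## Reproducing the published numbers — and the ones that cannot be

The bundled fixtures carry the published per-element counts verbatim;
`expand_contingency_fixture()` turns them into per-element pseudo-cohorts
whose 2×2 tables reproduce every published count, percentage and Fisher
p-value exactly (e.g. PNST positivity 34.8% among malnourished patients,
EN p > 0.999, any-positive-screen p = 0.677). Only per-element margins are
identified by those counts: the joint element structure, and hence the
numeric score/sensitivity/specificity columns of the published selection
tables, depend on the unavailable patient-level data — and contain internal
inconsistencies (the published PNST-row accuracy figures cannot be derived
from the published contingency counts under the standard definitions; the
published full-model penalty of 97.6 cannot be reconciled with the stated
weights and stratum sizes). The package computes all metrics from counts by
the standard definitions, reproduces the *structure* and *procedure* of the
selection tables, and verifies the search itself against a brute-force
oracle on seeded synthetic cohorts (n = 250, all 127 subsets of the 7
daily elements) instead of value-matching those columns.

## Problem sizes and numerical choices

The test suite checks marginal calibration at n = 100,000 per stratum
within three binomial standard errors, sweeps all 46,375 2×2 tables with
total ≤ 30 against the enumeration oracle, and compares 1,000 random
confusion vectors against an independently coded penalty sum at 1e-12.
Intercept calibration uses `integrate()` at relative tolerance 1e-10 and
`uniroot()` on [−60, 60] at tolerance 1e-10; rates of exactly 0 or 1 map to
infinite intercepts and are honoured exactly. Fisher p-values are clamped
to 1 from above (floating-point sums can exceed 1 by one ulp).

## Limitations

* Severity is fixed per patient; no longitudinal dynamics.
* The selection is in-sample, as in the original analysis: no
  cross-validation, confidence intervals, or multiple-testing correction.
* The PNST is an opaque admission-time boolean; its five questions are not
  re-implemented.
* No growth-reference data ship with the package; LMS rows are
  caller-supplied.
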