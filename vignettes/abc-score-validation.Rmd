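---
title: "Validating the ABC score: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the ABC score: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcscore)
```

## The scientific setting

Out-of-hospital cardiac arrest (OHCA) patients who reach hospital
without return of spontaneous circulation (ROSC) have a very poor
neurological prognosis; under 1% recover with good cerebral function.
The ABC score condenses three scene-available predictors into a 0–3
integer: **A**ge ≤ 70 years, **B**ystander factor (witnessed arrest
with no-flow time — collapse to first chest compression — of ≤ 5 min),
and **C**ardiogram (first monitored rhythm VT/VF, or public-access
defibrillation (PAD) performed). The intended uses sit at the two ends
of the scale: a score of 3 flags candidates for aggressive therapy such
as extracorporeal CPR; a score of 0 supports considering termination of
resuscitation at hospital.

This package implements the score and the machinery of its external
validation on nationwide Utstein-style registry data across three
resuscitation-guideline eras (arrest years 2007–2009, 2012–2014,
2017–2019; revision years and the years after them are transition
periods, excluded). The outcome is the 1-month cerebral performance
category (CPC), dichotomized 1–2 (favourable) versus 3–5.

## Scoring rule: edge cases fixed here

Both numeric thresholds are **inclusive** (age ≤ 70; no-flow ≤ 5 min),
following the rule's definition. A no-flow time of 0 is a real value
(immediate bystander compressions) and scores B = 1. No-flow times are
compared as non-negative reals — a recorded 5.4 min scores 0; we do not
floor to whole minutes, since the registry convention is not public.
PAD grants the C point as an *or*: a patient defibrillated by a
bystander scores C = 1 even if the first rhythm the ambulance crew
monitors is non-shockable, and even if no rhythm was recorded at all. A
first rhythm of "spontaneous circulation" without PAD scores C = 0:
such records exist (circulation can resume transiently before EMS
monitoring) and remain in the cohort as long as the prehospital-ROSC
flag is not set. Unwitnessed arrests score B = 0 regardless of any
recorded no-flow time, which is only defined for witnessed arrests.

## The selection funnel

Eligibility requires: a resuscitation attempt and age ≥ 18 (inclusive);
an internal (medical) cause of arrest; a computable ABC score; a known
CPC; no prehospital ROSC; a region outside Kanto (the derivation
region of the score, removed so the validation is fully external); and
an arrest year inside one of the three guideline periods.

Filters are applied in a fixed order and each record is tallied at the
*first* criterion it fails, making the exclusion log deterministic and
exactly additive (`n_input = n_retained + Σ tallies`) and invariant to
row order. "Score not computable" is defined operationally as any
component input unresolvable: age missing, witnessed status missing,
no-flow time missing for a witnessed arrest, or first rhythm missing
without PAD. Two decisions the source material leaves open are fixed
as follows, on the conservative side:

* a record with PAD but *missing witnessed status* is excluded — C is
  known but B is not computable;
* records with missing cause or missing region are excluded at the
  cause and region steps respectively, since eligibility cannot be
  confirmed.

## Reconstruction of the published tables

The published validation reports, per guideline group, the totals
(`N`, favourable `P`) and — at thresholds score ≥ 1, ≥ 2, = 3 — the
patient and favourable counts. Successive differences of these
cumulative counts recover the full 4 × 2 score-by-outcome table; the
differenced stratum sizes agree *exactly* with the independently
printed per-score distribution in all three groups (nine equalities),
which is the package's cross-check that the transcribed aggregates are
self-consistent. `strata_from_cumulative()` performs the inversion
(validating monotonicity first) and `cumulative_from_strata()` the
forward direction; they are exact inverses, property-tested on random
tables.

## Test characteristics and intervals

At threshold t, "score ≥ t" is the positive prediction for a
favourable outcome. Sensitivity and specificity are exact binomial
point estimates; reported percentages are rounded half-up at two
decimals while internal values keep full precision. The interval
method used in the original analysis is not identifiable from the
published bounds, so intervals are pluggable: Clopper–Pearson exact by
default (beta-quantile form, boundary-exact), Wilson score and Wald as
alternatives. Likelihood-ratio intervals use the delta method on the
log scale (Simel): `exp(log LR ± z·SE)` with
`SE² = 1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)` for LR+ and the
complementary form for LR−. Degenerate cells are signalled, not left
to overflow: `fp = 0` yields an explicit infinite LR+ with an undefined
lower bound, `fn = 0` a zero LR− with an undefined upper bound.

## ROC, ties, and the Youden cutoff

A four-level score yields three non-trivial operating points; the ROC
curve joins them with the (0,0) and (1,1) corners. The AUROC uses the
tie-corrected rank form (half-credit for tied pairs), which for an
ordinal predictor is algebraically identical to the trapezoidal area;
the implementation computes both and requires agreement to 1e-12.
Whether the published analysis scored the raw 0–3 values or a
probability transform of them is immaterial: any strictly monotone
transform preserves the ranking, hence the AUROC, so the question is
documented rather than resolved. The Youden index
J(t) = sensitivity + specificity − 1 is evaluated at the three
thresholds; ties (unspecified in the source) break toward the *larger*
threshold, preferring fewer false positives in a triage reading. A
Hanley–McNeil interval for the AUROC is attached as a descriptive
extra, clearly outside the reproduced surface.

## Calibration

Calibration pairs an externally supplied predicted probability per
score with the observed proportion and its interval. The predicted
values used in the original plots are not recoverable from the text
(plausibly the derivation-cohort rates), so they are a required input;
the shipped group configurations carry example values equal to the
validation cohorts' own observed rates, which makes the example plots
self-calibrated by construction. Observed proportions share the
`observed_proportions_by_score()` code path exactly, so the two views
cannot drift apart.

## The synthetic registry generator

No record-level national registry data are public, so simulation
studies run on a seeded synthetic cohort. Generation is
**stratum-first**: each eligible record draws its score from the
configured score distribution, then component fields consistent with
that score, then its CPC from the per-score outcome probabilities.
This guarantees the two marginals the validation pipeline actually
consumes — the score distribution and the per-score outcome gradient —
match the configuration in expectation; generating components
independently would require a dependence structure the published
marginals do not determine.

The shipped configurations are calibrated once to the published
cohorts: exact per-score shares and favourable rates from the
reconstructed strata; within-stratum component-pattern weights solved
(one linear system per group) so the component prevalences (A
23.7–28.7%, B 21.9–22.4%, C 6.0–7.6%) are matched; the witnessed rate
among bystander-negative records set so the overall witnessed fraction
lands near the published 37–39%; the PAD share of C-positive records
at the published 7–18%. Ages are truncated normals (18–70 mean 56 sd
12 when A = 1; 71–110 mean 84 sd 8 otherwise), reproducing a cohort
median near 80 with IQR roughly 70–88; witnessed no-flow times use
decaying weights on 0–5 min (B = 1) and a geometric tail on 6–30 min
(witnessed B = 0), giving a median near 3 with IQR 0–10 among
witnessed. The CPC 3–4 gradient above score 0 is unpublished; shipped
values reproduce the published score-0 rate and the overall CPC 3–4
total approximately and sit outside every acceptance check. These
choices were fixed when the configurations were written and are not
tuned.

What the generator does *not* emulate: within-stratum correlations
(e.g. age–witness), regional and temporal heterogeneity, and any
registry coding quirks. Simulation results therefore demonstrate the
pipeline's statistical correctness under the configured model, not
properties of real registry exports.

Contamination — deliberately ineligible records exercising each
selection filter — is drawn per record from configured rates, in a
random substream separate from the eligible-field draws (a single root
seed derives per-purpose substreams, so enabling contamination does not
perturb eligible records). Each contaminated record is built eligible
and then broken in exactly one field, so it fails precisely its
intended filter; the generator records each record's intended fate,
and the funnel's tallies must match that bookkeeping exactly — an
integer identity, tested.

## Numerical and scale choices

Problem sizes in the test suite were chosen to keep the full run under
a minute while leaving the statistical assertions well-powered:
parameter recovery at 10⁵ records against 99% binomial bounds;
score-distribution convergence at 10³/10⁴/10⁵ against the 99%
Kolmogorov band with decay across two decades; Monte-Carlo agreement of
the closed-form AUROC oracle at 10⁶ records within ±0.005; coverage of
the observed-proportion intervals over 100 replicates of 2,000 records
(≥ 93% per score, consistent with Clopper–Pearson's conservatism); and
a 160,000-record simulated validation reproducing the 2005-group AUROC
within ±0.01. Published interval *bounds* are checked only to ±0.5
percentage points, since the original interval method is unstated;
point estimates are checked exactly at their printed precision.

## Known limitations

The package validates; it does not re-derive or re-weight the score,
fit multivariable models, or implement comparator rules (termination
rules, SWAP). Real registry export formats are not public, so the
default CSV dialect is this package's own, with every code and column
remappable. The synthetic generator's within-stratum distributions are
plausible but unverifiable against unpublished data; conclusions about
real cohorts require real records.
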