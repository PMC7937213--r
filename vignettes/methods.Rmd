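---
title: "Anchor-based MID and PASS estimation: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based MID and PASS estimation: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prothresh)
```

## The estimation problem

A continuous outcome score is only interpretable once two thresholds are
known: the **minimal important difference** (MID) — the smallest change a
patient experiences as a real improvement — and the **patient acceptable
symptom state** (PASS) — the symptom level at which a patient considers
themselves well. Both are estimated *anchor-based*: each patient also
answers a 5-level global rating of change (GRC), from 1 ("very satisfied —
healed") to 5 ("worse"), and the thresholds are chosen so that the
continuous score best reproduces the anchor's verdict.

The package works on a long-format table of patient × timepoint ×
instrument records (`as_outcome_table()`), with change scores oriented as
positive improvement magnitudes (`compute_changes()`) so pain instruments
(lower = better) and function instruments (higher = better) share one code
path. Follow-up timepoints are pooled as rows (`pool_timepoints()`): the
analysis unit is the GRC–outcome *pair*, not the patient, and no
clustering adjustment is applied to point estimates — a deliberate match
to pooled primary analyses of this design. Missing items are handled by
pairwise deletion only; each estimator uses the rows where its required
fields are present, which is why pair counts differ across instruments and
timepoints. No imputation is offered.

## Estimators

**MID.** The anchor is dichotomized improved (GRC 1–3) vs not improved
(GRC 4); worseners (GRC 5) are excluded so the threshold is one of
improvement (too few worseners exist in cohorts like this to estimate a
deterioration MID, which is out of scope). Three estimators:

* `estimate_mid_roc()` sweeps candidate cutoffs placed at **midpoints
  between consecutive distinct observed values**, plus a sentinel on each
  side, and picks the point closest (unweighted Euclidean distance) to the
  ROC corner (sensitivity 1, specificity 1). Midpoint placement is why
  thresholds like 1.5 appear on an integer 0–12 scale; a reporting option
  rounds for presentation, the engine never does. Whether to place
  cutoffs at observed values or between them is genuinely open in this
  literature; midpoints were chosen because they are invariant to which
  side of a tie a scan starts on and reproduce half-point thresholds.
  Ties in corner distance are broken by higher sensitivity, then higher
  specificity, then smaller cutoff — a convention, stated so results are
  reproducible.
* `estimate_mid_mdoc()`: mean improvement of the GRC 3 group minus that
  of the GRC 4 group ("mean difference of change").
* `estimate_mid_mc()`: mean improvement of the GRC 3 group ("mean
  change"). By construction `MDoC = MC − mean(improvement | GRC 4)`, an
  identity the test-suite asserts on every generated cohort.

Discrimination is summarized by the Mann–Whitney AUC (ties ½), computed
from mid-ranks. Its variance uses DeLong's structural components: the
placement value of each positive observation (fraction of negatives it
beats) and vice versa; `var(AUC) = var(V10)/m + var(V01)/n`. The interval
is **Wald on the AUC scale, clipped to [0, 1]** — no logit transform,
since the method cited for this design is DeLong's alone; perfectly
separated data legitimately give variance 0 and the degenerate interval
[1, 1]. A logit-scale variant would behave better near 1 with small
samples; it is intentionally not the default and noted here as a known
trade-off.

**PASS.** Estimated on follow-up (post) scores, under two anchor
definitions (satisfied = GRC {1}, or {1, 2}; both are defensible and both
are always reported). `estimate_pass_roc()` uses the same corner rule with
direction lower-predicts-satisfied for pain and higher for function;
`estimate_pass_percentile()` takes the 75th percentile of the satisfied
group's post scores for pain, the 25th for function. Worseners stay in the
"rest" class here — exclusion applies only to the MID ROC.

**Quantiles, everywhere:** linear interpolation between order statistics
(type 7). One definition is used for the percentile PASS and the bootstrap
interval bounds alike, so printed values are mutually consistent. On
integer instruments this rule still reaches integer thresholds when the
satisfied group's quartile lands on an observation.

**Bootstrap.** `percentile_ci()` implements the percentile bootstrap
(default 1000 resamples): simplest interval consistent with "bootstrapped
CIs" in this design; BCa or studentized intervals are out of scope.
Resampling defaults to the row level (the pooled pair is the analysis
unit); `unit = "patient"` resamples whole patients as a sensitivity
option, because whether pooled resampling should respect clustering is
genuinely undecidable from the design alone. Replicates where the
statistic is undefined (an anchor group empty in the resample) are
dropped and counted; more than half undefined aborts with a diagnostic
rather than returning a quietly unstable interval.

**Anchor adequacy.** `validate_anchor()` computes Spearman correlations
(average ranks on ties, pairwise deletion) of the GRC with baseline, post
and change scores, per timepoint and pooled, with bootstrap CIs. The GRC
is reversed (6 − GRC) so larger = more satisfied; in the default
`"aligned"` mode scores are improvement-oriented so an informative anchor
correlates positively everywhere, while `sign = "paper"` correlates
against raw scores, reproducing the sign conventions of published reports
(negative against pain change, positive against function change). Flags:
`adequate_change_correlation` (|rho with change| ≥ 0.3 by default — the
field says "adequate" without a number, so the threshold is configurable
and stated), `near_zero_baseline` (< 0.1), and `change_exceeds_post`,
whose absence is the recall-bias signature.

## The synthetic cohort generator

Real anchor-study datasets of this kind are typically not public, so the
generator is a first-class module: it must be able to produce every
qualitative regime the estimators are meant to distinguish, with known
ground truth.

Per patient × timepoint a latent improvement `L ~ N(2, 1)` is drawn (half
the variance from a per-patient random effect, so a patient's follow-ups
are correlated). Each instrument observes `effect_scale · L` plus noise as
its change; post = baseline ± change, clipped to the scale and rounded to
integer scores. Baselines share a per-patient severity factor across
instruments (`baseline_share = 0.5`), signed by direction — severe
patients are severe on every measure — which is what allows a
recall-biased anchor to track every instrument's post score. The GRC is an
ordinal cut of `U = (1−w)·L + w·P + noise` at thresholds
`tau = (2.5, 1.9, 0.8, 0.04)`, where `P` is the standardized post-score
composite mapped to the latent scale and `w` the recall-bias weight.

Consequences used by the tests: a patient is improved (GRC ≤ 3) exactly
when `U ≥ tau[3]`, so with a noise-free anchor the planted MID on an
instrument's scale is `effect_scale · tau[3]`; the effect scales
(16.25, 25, 12.5, 1.875) were chosen so these planted thresholds are
13 mm, 20 mm, 10 points and 1.5 points — magnitudes typical for these
four instruments. The default `tau` makes roughly 31% of ratings "very
satisfied", 11% "dissatisfied" and 2–3% worse, matching the strongly
right-shifted anchor distributions such trials see. Change-noise SDs
(38, 10, 7, 0.8) put activity pain, Constant–Murley and SST in the
good-to-excellent discrimination range and leave rest pain a weak anchor
whose pooled |rho with change| sits near 0.25 — the classic failure mode
— at the price of a rest-pain AUC (~0.64) somewhat below what a real
cohort with that correlation might show: with a single dependence
parameter per instrument, the correlation and the AUC cannot be set
independently, and the correlation-based failure mode was prioritized.
Missingness (7% of post scores per row, 2% of GRC per patient-visit) is
missing-completely-at-random, which reproduces unequal pair counts but
none of the informative-missingness patterns of real trials.

`scenario_library()` ships the regimes: `"fimpact-like"` (the default
above), `"perfect-anchor"` (all noise off, fixed baselines, no rounding —
planted thresholds recoverable exactly up to midpoint resolution, and the
implied post-score PASS threshold is exact because baselines are
constant), `"worthless-anchor"` (anchor noise SD 10 swamps the signal;
AUC ≈ 0.5), and `"recall-biased"` (`w = 0.7`; the anchor correlates more
with post than with change scores).

What passing tests on these cohorts does **not** show: robustness to
informative missingness, to floor/ceiling-dominated instruments, to
anchors administered with different wording at different visits, or to
treatment-arm effect heterogeneity (arms are labels only; emulating
differential efficacy is a non-goal).

## Numerical and testing choices

Degenerate inputs are errors, not silent values: single-class labels,
empty anchor groups, fewer than 2 observations per class for DeLong,
fewer than 3 pairs for a correlation. All-tied score vectors make the ROC
curve collapse to its two sentinel points (every nontrivial operating
point has sens + spec = 1) and make Spearman's rho undefined (`NA` with a
warning).

The test-suite checks the AUC against an O(n²) brute-force pair-counting
oracle and the corner selection against exhaustive minimization (200
random datasets of up to 30 observations each), the DeLong variance
against a hand-computed 4-observation placement-value fixture and against
an independent reference implementation, and recovery of planted
thresholds over 200 generated cohorts per scenario (medians compared to
ground truth; under noise, to a tolerance frozen from an independent
oracle simulation, because the corner cutoff under class overlap sits
between the class score distributions rather than at the category
boundary — a known property of this estimator worth remembering when
comparing ROC MIDs to mean-based MIDs). Bootstrap coverage is verified by
500 Monte-Carlo simulations of a known mean at n = 200. These problem
sizes keep the full suite to a few minutes while leaving every assertion
at cohort-realistic n.

## Limitations

* The ROC MID depends on the anchor category distribution, not only on
  the boundary; with strongly improved cohorts it exceeds the planted
  category boundary. Report it together with MDoC/MC and the AUC, never
  alone.
* Percentile bootstrap intervals are first-order accurate only; for
  statistics with skewed resampling distributions (extreme quantiles,
  small anchor groups) they can undercover.
* Pooling visits treats repeated measures as independent pairs; point
  estimates are unaffected but pooled CIs are anti-conservative when
  within-patient correlation is high. Use `unit = "patient"` as the
  sensitivity check.
* The generator is a stand-in calibrated to qualitative regimes; its
  defaults are synthetic and are not estimates of any real cohort's
  parameters.
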