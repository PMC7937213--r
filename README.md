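# prothresh

Anchor-based interpretability thresholds for patient-reported outcome
measures: the **minimal important difference** (MID, "how much change does
it take to feel better") and the **patient acceptable symptom state**
(PASS, "how little symptom does it take to feel well"), estimated against
a 5-level global-rating-of-change (GRC) transition anchor.

The package targets the analysis design of a shoulder trial measuring pain
at rest and on arm activity (VAS 0–100 mm, lower is better), the
Constant–Murley score (0–100, higher is better) and the Simple Shoulder
Test (0–12, higher is better) at several follow-ups, but every instrument
is configurable through `instrument_spec()`.

## Methods

Let `x` be a patient's improvement magnitude (change score oriented so
positive = better) and `y` the GRC answer (1 = very satisfied … 5 = worse).

**MID.** The anchor is dichotomized as improved (GRC 1–3) vs not improved
(GRC 4); worseners (GRC 5) are excluded. Three estimators:

- *ROC*: candidate cutoffs are midpoints between consecutive distinct
  improvement values; the MID is the cutoff minimizing the distance
  `sqrt((1 − sens)² + (1 − spec)²)` to the top-left ROC corner.
  Discrimination is summarised by the Mann–Whitney AUC
  `P(X_improved > X_not) + ½·P(=)`, with a DeLong
  (structural-components) variance and Wald 95% CI clipped to [0, 1].
- *MDoC* (mean difference of change): `mean(x | GRC = 3) − mean(x | GRC = 4)`.
- *MC* (mean change): `mean(x | GRC = 3)`.

MDoC and MC carry percentile-bootstrap 95% CIs (1000 resamples of the
pooled GRC–outcome pairs by default; patient-level resampling available).

**PASS.** Estimated on follow-up (post) scores under two anchor
definitions — satisfied = GRC {1} or GRC {1, 2}:

- *ROC*: same corner rule, direction lower-predicts-satisfied for pain,
  higher for function scores;
- *percentile*: the 75th percentile of the satisfied group's post scores
  for pain (25th for function scores), with linear interpolation between
  order statistics.

**Anchor adequacy.** Spearman correlations of the GRC with baseline, post
and change scores (bootstrap CIs); an anchor whose |rho with change| falls
below 0.3 (configurable) flags that instrument's MID as unreliable, and
`rho_post > rho_change` signals recall bias.

A latent-variable generator (`generate_trial()`, `scenario_library()`)
produces synthetic cohorts with known planted thresholds, so every
estimator is testable without access to trial data.

## Worked example

```r
library(prothresh)

cohort <- generate_trial(scenario_library("fimpact-like", seed = 42))
tab <- compute_changes(cohort$table)

estimate_mid_roc(tab, "pain_activity")
#> <mid_estimate> pain_activity, ROC method: MID = 31.5
#>   sens 0.88, spec 0.84, AUC 0.93 (0.90 to 0.96); 435 improved, 64 not improved, 26 worse excluded

estimate_mid_mc(tab, "pain_activity", n_boot = 1000, seed = 42)
#> <mid_estimate> pain_activity, MC method: MID = 38.43 (95% CI 36.38 to 40.51)

estimate_pass_percentile(tab, "sst", pass_anchor(1))
#> <pass_estimate> sst, percentile method, anchor GRC 1: well if post >= 9.25

validate_anchor(tab, "pain_rest", n_boot = 1000, seed = 42)
#> <anchor_validation_report> pain_rest (sign mode: aligned)
#>   grc_vs_baseline  rho +0.08 (-0.01 to 0.16), n = 561
#>   grc_vs_post      rho +0.30 (0.22 to 0.38), n = 521
#>   grc_vs_change    rho +0.33 (0.25 to 0.41), n = 521
#>   adequate (|rho_change| >= 0.30): TRUE; change > post: TRUE; baseline ~ 0: TRUE
```

Reading the output: a patient on this cohort needed a ~31 mm drop in
activity pain before rating themselves at least "somewhat satisfied"
(the anchor discriminates well, AUC 0.93), the mean-change method puts
the MID higher (38 mm — it averages the whole "somewhat satisfied" group
rather than finding the discrimination boundary), and an SST post score
of about 9–10 of 12 marks the "feeling well" state. The rest-pain anchor
check illustrates the diagnostic layout; on weak anchors the adequacy
flag turns off and downstream reports mark that MID unreliable.

`run_full_analysis()` composes all of the above (pooled, per timepoint,
and surgery-vs-exercise subgroups) into a `report_bundle`;
`write_report_bundle()` emits CSVs, JSON and a text summary. A thin CLI
over the same functions ships in `inst/scripts/clinthresh.R`
(subcommands `simulate`, `mid`, `pass`, `validate-anchor`, `report`).

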