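---
title: "The Triple Variable Index: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Triple Variable Index: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During general anesthesia three monitoring variables are recorded
continuously but at different rates and by different devices: mean arterial
pressure (MAP, mmHg, ~every 3 minutes), the bispectral index (BIS, a
processed-EEG depth-of-anesthesia score on 0–100, ~every 5 minutes), and
the end-tidal concentrations of inhaled anesthetic agents (~every 5
minutes). Individually each has known links to adverse outcomes; jointly
low values of all three — the *triple low state* (MAP < 75 mmHg, BIS < 45,
MAC < 0.8) — mark patients at elevated risk of postoperative death. The
triple low state, however, is a threshold rule: it discards the continuous
information in the three signals and has no time axis.

The Triple Variable Index (TVI) addresses both limitations. Each variable
is normalized to a population z-score, the z-scores are averaged within
short windows of intraoperative time, and the three window averages are
summed into a single composite value. The sequence of window values — the
*TVI profile* — maps a surgery's joint MAP/BIS/MAC behaviour across the
whole case, and profiles can then be compared, clustered into expression
patterns, and used as risk predictors.

## Index construction

1. **MAC summation.** At every timepoint with any inhaled-agent record, the
   agent concentrations are divided by their standard 1-MAC equivalents
   (isoflurane 1.17%, desflurane 6.6%, sevoflurane 1.8%, nitrous oxide
   105%) and summed into one total MAC value. Sums of 0.001 or less are
   treated as "no anesthetic in use" rather than as measurements. MAC is
   deliberately not age-adjusted: the index is meant to reflect the values
   as delivered and measured.

2. **Artifact removal.** Strictly out-of-range values are monitoring
   artifacts and are dropped with an audit trail: MAP above 250 or below 10
   mmHg, BIS above 100 or below 1 (a BIS of exactly 0 is a
   connect/disconnect artifact), total MAC above 3. Boundary values are
   retained, since only values *beyond* the limits are physiologically
   impossible. When arterial-line and cuff MAP coexist at one timestamp,
   the arterial value is used.

3. **Z-scoring.** Each retained value is normalized against the pooled mean
   and sample standard deviation (divisor *n − 1*) of *all* retained values
   of that variable across the entire cohort — not per case. A TVI of zero
   therefore means "population-average physiology", and TVI units are
   comparable across surgeries.

4. **Windowing.** A window spans five consecutive *distinct measurement
   timepoints* — a timepoint being a unique time at which at least one of
   MAP, BIS, or MAC exists; simultaneous recordings count once. Windows are
   non-overlapping and chronological; the final window keeps the 1–4
   remaining timepoints. Within a window, each variable's z-scores are
   averaged (all values at the window's timepoints, including duplicates).
   No interpolation or carry-forward is ever performed: a variable absent
   from a window is simply missing there.

5. **TVI.** A window's TVI is the sum of its three mean z-scores, defined
   only when all three variables are present. During cardiopulmonary
   bypass, for example, agent delivery is charted by the perfusionist and
   MAC data are absent, so bypass-spanning windows have no TVI. Cases in
   which no window ever attains a TVI are not analyzable and are excluded
   with a logged reason. Because the population mean and SD are fitted on
   the same pooled data that are z-scored, averaging z-scores within a
   window is algebraically identical to z-scoring the raw window mean; the
   test suite asserts this identity to 1e-9 as an implementation oracle.

## Pattern discovery

Profiles differ in length, so they are embedded on a fixed grid before
clustering: window *i* of a *W*-window profile has proportion
*i/(W − 1)* (0 for a single-window profile), and each present TVI value is
placed at grid position `round(proportion * (L - 1))` with `L = 20`
positions; collisions are averaged. Grid positions that receive no value
are filled with the profile's own mean TVI (`fill = "profile_mean"`). The
alternative `fill = "zero"` (missing ≙ population average) is available but
not the default: half the profiles have fewer windows than grid positions,
and zero-fill drags every short profile toward a neutral pattern regardless
of its actual expression level, which systematically confuses short
elevated or depressed cases with mixed ones. Mean-fill preserves the
level — the quantity the patterns are defined by — while the filled
positions carry no spurious shape information.

Embedded profiles are clustered with standard Lloyd k-means (Euclidean
distance, 10 random starts, 100 iteration cap, seeded and deterministic;
`stats::kmeans` under the hood). `k = 3` is the canonical analysis; the
cluster with the highest mean TVI over its member profiles is labelled
*elevated*, the lowest *depressed*, the middle *mixed*. Other `k` values
get rank labels. Exact ties in mean TVI are broken by cluster size, with a
message.

## Events, outcomes, and comparisons

* **Intraoperative hypotension (IOH):** any recorded MAP below 55 mmHg —
  evaluated on raw measurements, because the defining criterion concerns
  recorded levels, not window summaries.
* **Triple low state (TLS):** a profile window whose raw-scale MAP, BIS,
  and MAC means are all strictly below 75 / 45 / 0.8. The raw-scale means
  are carried through windowing alongside the z-means so no
  back-transformation is needed. Cumulative exposure is the count of
  qualifying windows.
* **Mortality windows:** death on day *d* after surgery is classed as
  ≤ 30, 31–365, or 366–730 days; absent death dates default to survival
  beyond 730 days (the bundled generator provides complete follow-up; an
  optional follow-up argument yields "unknown" instead when follow-up is
  shorter).
* **Characterization:** per-cluster summaries use Wilson score intervals
  for proportions, normal-theory t intervals for means, and seeded
  percentile-bootstrap intervals for medians. The bootstrap median
  interval resamples `sample_size` draws with replacement `n_boot` times
  and takes the 2.5/97.5 percentiles of the resampled medians; its
  reference defaults (10,000 resamples of 1,000,000 draws) are preserved on
  `bootstrap_median_ci()` itself, while the summary table uses a scaled
  1,000 resamples of the data's own size — the estimator is unchanged, only
  Monte-Carlo precision differs.
* **Prediction contest:** ROC AUC is the Mann–Whitney statistic with
  midrank ties. Per-case median TVI (sign-flipped so that depressed
  profiles score as higher risk) is compared with the cumulative TLS window
  count as predictors of 30-day mortality; the AUC difference is assessed
  by a paired case-resampling bootstrap (2000 replicates), standardizing
  the observed difference by the bootstrap SD and reading a two-sided
  normal p-value. Cases are canonically sorted before resampling so the
  result does not depend on input order; single-class resamples are
  redrawn with a capped retry count.

## The synthetic cohort generator

No intraoperative records can be shipped, so `generate_cohort()` emits
cohorts with the statistical structure the pipeline assumes, under a single
seed. Each surgery draws one of three latent regimes — elevated / mixed /
depressed, prevalences 891/2931/1474 out of 5296 — whose MAP/BIS/MAC means
(86.5/82.3/76.6 mmHg, 45.3/41.8/38.0, 0.980/0.817/0.666) and mortality
(30-day 0.8/2.7/5.6%; 31–365 day 4.9/6.7/7.4%; 366–730 day 3.3/3.8/4.3%)
follow published cluster-level summaries of a large single-center cohort.
Durations are lognormal (median 1.8 h, sdlog 0.9, floor 15 min, matching a
median of 1.8 h with quartiles 1.0–3.4 h); MAP is emitted about every 3
minutes and BIS/agents about every 5, with ±20% uniform timestamp jitter so
streams rarely coincide and the distinct-timepoint windowing rule is
exercised. Agent concentrations are back-solved from the target MAC
through a single sevoflurane channel so the agent→MAC round trip is exact.
Artifacts are injected at rate 0.005 per measurement (out-of-limit MAP or
MAC, BIS 0). About 4% of cases are bypass cases whose agent stream is
blanked over the middle third of the case. Arterial-line cases emit
occasional concurrent cuff readings to exercise source precedence.
Medication tables mimic the usual drug mix with regime-dependent
administration probabilities.

Within-case variation is decomposed as

> value(t) = regime mean + case effect + SD × (ρ·depth(t) + δ·drift(t) + w·ε)

where `depth(t)` is a smooth latent anesthetic-depth process shared by the
three variables (loadings −0.25 MAP, −0.55 BIS, +0.55 MAC — opposite signs
for BIS and MAC reproduce the negative within-pattern BIS–MAC correlations
seen in practice), `drift(t)` is an independent smooth per-variable
process (loadings 0.80/0.76/0.76), and ε is white noise; ρ² + δ² + w² = 1
so the marginal SDs equal the configured totals. Both processes are
case-centered random walks on 5-minute nodes, so they average out over a
profile and leave case-level means stable.

Two calibration choices deserve emphasis:

* **Within-case SDs** default to magnitudes typical of stable anesthesia
  (MAP 6 mmHg, BIS 3.5, MAC 0.10) with small case effects (2 / 1.2 /
  0.035). The generator's purpose is to exercise the pipeline against a
  known truth, which requires the planted regimes to be statistically
  recoverable from windowed profiles: with much wider within-case noise the
  minimum-WCSS three-way partition of the embedded profiles is provably a
  mass-balanced split rather than the planted one, and no clustering method
  could grade the pipeline. The price is that the pooled SDs of a
  synthetic cohort are narrower than a real cohort's, whose spread is
  dominated by continuous case-mix heterogeneity that a three-regime model
  intentionally collapses. Consequently synthetic z-scores and TVI gaps are
  larger in magnitude than their real-data counterparts, and events tied to
  absolute thresholds (IOH, TLS) reproduce orderings across regimes rather
  than exact real-cohort rates.
* **The logistic mortality mode** (`mortality_link = "logistic"`) makes
  30-day death probability a logistic function of the case's true mean TVI
  level, with intercept −3.55 and slope −0.38 chosen analytically so the
  implied regime-level probabilities match the tabulated 0.8/2.7/5.6%. It
  exists to test the prediction contest under a generative model where
  median TVI is, by construction, the better-specified predictor.

What the generator does **not** emulate: pharmacokinetics or drug-effect
dynamics, blood-pressure autoregulation, electrosurgical interference
patterns, age-adjustment of MAC, incomplete follow-up, or continuous
between-patient heterogeneity. Passing tests therefore demonstrate that
the pipeline's algorithms behave as specified on data with the assumed
moment structure — not that the clinical findings would replicate in any
particular hospital's records.

## Numerical and policy choices

* Sample SD (divisor *n − 1*) everywhere; numerically immaterial at cohort
  sizes but fixed for reproducibility.
* Timestamps are minutes from each case's first recorded measurement,
  rounded to 1 second (1/60 min, configurable) so "simultaneous" readings
  from different devices compare equal; arterial/cuff precedence is
  resolved per exact rounded timestamp, as no matching tolerance is
  defined by the method.
* Grid placement uses R's `round()` (half-to-even) — a deterministic
  tie-break for proportions landing exactly between positions.
* Duplicate (case, time, variable, source) rows are all retained and enter
  window means; no deduplication rule is part of the method.
* Degenerate inputs fail fast with informative errors: empty cases, fewer
  than two values or zero variance when fitting population statistics,
  fewer than `k` distinct feature vectors, single-class outcome vectors,
  negative concentrations or death days.
* The test suite runs the pipeline at reduced problem sizes chosen as
  study conditions: cluster recovery on one 2000-case cohort; the
  prediction-contest direction on 50 seeded cohorts of 1500 cases;
  bootstrap-median coverage on 100 seeded standard-normal samples of 5000
  values with 1000 resamples of 5000 draws. These sizes keep each
  experiment's Monte-Carlo error well inside the margins being asserted.

## Known limitations

* Equal weighting of MAP, BIS, and MAC is a modelling choice, not an
  optimized predictor; the contest uses the median profile TVI as-is.
* The fixed-grid embedding is one reasonable answer to comparing
  variable-length profiles; methods that align on absolute time or use
  distribution-based dissimilarities would weight long cases differently.
* k-means with `k = 3` is the canonical analysis because it separates
  expression levels cleanly; other `k` are supported but only ranked, not
  named.
* The bootstrap AUC comparison uses a normal approximation on the
  standardized difference; with very few events its p-values are
  approximate.
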