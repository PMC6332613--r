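# tviprofiles

Tools for the **Triple Variable Index (TVI)**: a composite, time-resolved
summary of intraoperative physiology for anesthesiologists and
perioperative-outcomes researchers working with electronic anesthesia
records.

During surgery, mean arterial pressure (MAP, ~q3 min), the bispectral index
(BIS, ~q5 min), and end-tidal inhaled-anesthetic concentrations (~q5 min)
are recorded at different rates. The *triple low state* (concurrent
MAP < 75 mmHg, BIS < 45, MAC < 0.8) flags risky combinations of the three
but discards their continuous information and has no time axis. The TVI
keeps both:

- every inhaled agent is converted to MAC fractions via its 1-MAC
  equivalent (isoflurane 1.17%, desflurane 6.6%, sevoflurane 1.8%, nitrous
  oxide 105%) and summed to a total MAC per timepoint;
- artifacts are removed (MAP outside (10, 250) mmHg, BIS outside (1, 100) or
  exactly 0, summed MAC > 3 — strict bounds, boundary values retained);
- each value is z-scored against the pooled population distribution of its
  variable;
- z-scores are averaged within non-overlapping windows of **five distinct
  measurement timepoints** (last window keeps the remainder), and

  **TVI(window) = mean z(MAP) + mean z(BIS) + mean z(MAC)**,

  defined only when all three variables have data in the window — nothing
  is interpolated or carried forward.

The sequence of window TVI values is a surgery's **TVI profile**. Profiles
are embedded on a fixed proportion grid and clustered with k-means
(`k = 3`, 10 random starts, 100 iterations) into **elevated / mixed /
depressed** expression patterns, which are then characterized against
patient, procedure, event (intraoperative hypotension: any MAP < 55 mmHg;
triple-low exposure per window) and mortality outcomes (≤30, 31–365,
366–730 days). Median profile TVI and cumulative triple-low exposure are
compared as 30-day mortality predictors via Mann–Whitney ROC AUCs and a
paired case-resampling bootstrap (2000 replicates).

Because anesthesia records cannot be shipped, the package includes a seeded
synthetic cohort generator (`generate_cohort()`) reproducing the assumed
statistical structure — three latent regimes with published cluster-level
means and mortality, multi-rate jittered sampling, artifacts, bypass gaps in
the MAC stream, and a latent depth process that couples BIS negatively to
MAC. Every stage of the pipeline is testable against its planted truth.

## Worked example

```r
library(tviprofiles)

cohort <- generate_cohort(cohort_spec(n_cases = 300, seed = 42))
fit <- tvi_fit(cohort, seed = 1)
print(fit)
#> Triple Variable Index fit
#>   profiles: 300 | windows: 6716 | TVI values: 6434
#>   excluded cases (no TVI window): 0 | artifact rows removed: 178
#> TVI k-means pattern model: k = 3 | inertia = 6056.96 | seed = 1
#>  cluster size mean_tvi     label
#>        1  168    0.221     mixed
#>        2   50    2.808  elevated
#>        3   82   -2.281 depressed
```

300 synthetic surgeries yield 6716 windows, 6434 of which have concurrent
MAP/BIS/MAC data and hence a TVI value; 178 artifact rows were filtered.
The three patterns separate by mean TVI (z-sum units; 0 = population-average
physiology). `summary(fit)` produces the per-cluster characterization table
(Wilson intervals for proportions, t intervals for means, bootstrap
intervals for medians); `plot(fit)` draws the profile heatmap (red =
elevated, blue = depressed, white = no TVI); `predict(fit, new_cohort)`
assigns new surgeries to the fitted patterns.

On a larger cohort whose 30-day mortality is generated as a logistic
function of the case's TVI level:

```r
co <- generate_cohort(cohort_spec(n_cases = 1500, seed = 42,
                                  mortality_link = "logistic"))
fit <- tvi_fit(co, seed = 1)
mortality_prediction_contest(fit, seed = 1)
#> 30-day mortality prediction: median TVI vs cumulative TLS
#>   n = 1500 cases, 47 deaths
#>   AUC (median TVI) = 0.6225 | AUC (TLS count) = 0.5854
#>   delta = 0.0371, bootstrap p = 0.3032 (2000 resamples)
```

Median TVI discriminates 30-day deaths better than cumulative triple-low
exposure (higher AUC), the qualitative ordering the index is designed to
show; with 47 events a single cohort of this size does not make the
difference significant. The per-cluster 30-day mortality in the same fit is
0.8% (elevated), 2.8% (mixed), and 5.4% (depressed).

An end-to-end run with file outputs (profiles, assignments, model JSON,
flags, characterization, contest JSON, artifact audit, run manifest):

```r
run_pipeline(list(synth = list(n_cases = 500, seed = 7), seed = 7),
             out_dir = "tvi_out")
```

or from a shell: `Rscript inst/cli/tvi.R --n 500 --seed 7 --out tvi_out`.

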