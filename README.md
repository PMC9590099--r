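# sozspatial

Spatial-bias-aware analysis of intracranial EEG functional networks.

## The problem

In patients with drug-resistant focal epilepsy, intracranial EEG electrodes
are placed where clinicians already suspect the seizure onset zone (SOZ).
This hypothesis-driven sampling contaminates every downstream network
analysis: electrodes are denser near the suspected SOZ, coverage is
asymmetric across hemispheres, and a classifier that "localizes" the SOZ may
merely be reading out where the electrodes were put. `sozspatial` implements
an analysis pipeline that measures and controls for this spatial bias:

- **Functional networks.** Signed Pearson correlation over non-overlapping
  2-s windows averaged within 1-min segments, and Welch magnitude-squared
  coherence (2-s window, 1-s overlap) in the canonical delta/theta/alpha/
  beta/gamma bands.
- **Symmetric-coverage atlas contrasts.** Electrodes are assigned to the
  nearest atlas region; region networks keep only inter-regional edges
  (diagonal unknown); regions without bilateral coverage are removed, so SOZ
  connectivity can be compared to the homotopic contralateral region within
  patient. Three contrasts (regional, intra-hemispheric, intrinsic) are
  tested with exact Wilcoxon signed-rank tests reporting the positive-rank
  sum T+. An electrode-subsampling control (100 resamples) balances
  electrode counts across homotopic pairs.
- **SOZ lateralization.** Leave-one-patient-out logistic classification of
  left vs right onset from intra-hemispheric connectivity and/or hemispheric
  spike rates, threshold 0.5.
- **Spatial null model.** The kernel density at electrode *i*,

  density_i = (1 / radius^2) * sum_j (3/pi) * (1 - (d_ij / radius)^2)^2,

  with patient-specific radius (the largest inter-electrode distance) and
  zero contribution beyond it, quantifies local sampling density. A logistic
  model on coarse anatomy + density — *no EEG data at all* — is the
  benchmark that any EEG-informed SOZ-electrode classifier must beat.
  Models adding normalized connectivity and/or spike rates are compared over
  repeated 2/3 / 1/3 patient-level train/test splits (1000 by default) with
  the counting p-value
  p = 2 (min[N(diff <= 0), N(diff >= 0)] + 1) / (N + 1),
  plus a stereo vs grid/strip/depth stratification and a random-intercept
  mixed-effects model with patient-level bootstrap.
- **Synthetic cohorts.** A seeded generator reproduces the statistical
  structure this analysis assumes — asymmetric coverage, density-biased
  stereo sampling around the SOZ, correlated Gaussian signals whose
  SOZ-involving edges are scaled by `1 - soz_conn_reduction`, and
  lateralized spike rates — so the full pipeline is testable end to end
  without patient data.

## Worked example

```r
library(sozspatial)

spec <- cohort_spec(n_patients = 40, duration_s = 30,
                    soz_conn_reduction = 0.5, spike_rate_ratio = 2, seed = 11)
cohort <- generate_cohort(spec)
analyses <- analyze_cohort(cohort)

# Homotopic contrast: is SOZ-region connectivity lower than contralateral?
ct <- cohort_contrast(analyses, cohort$patients, cohort$atlas, "regional")
ct$test$T_plus
#> [1] 0
ct$test$p
#> [1] 8.057245e-08
```

Every included patient's SOZ-region connectivity fell below its homotopic
control (T+ = 0: no positive ranks), so the injected 50% connectivity
reduction is detected essentially with certainty.

```r
feats <- cohort_electrode_features(cohort, analyses)
ev <- evaluate_splits(feats, n_splits = 200, seed = 5)
round(ev$mean_auc, 3)
#>        null   null+conn null+spikes         all
#>       0.755       0.914       0.986       0.992
```

The spatial null model — anatomy and sampling density only — already
classifies SOZ electrodes well above chance (AUC 0.76), because stereo
implants in this cohort sample the SOZ more densely. EEG-derived features
add performance on top, and the ordering null < null+conn < null+spikes <
all mirrors how much electrode-level information each feature carries.

```r
me <- mixed_effects_association(feats, n_boot = 200, seed = 3)
round(c(OR = me$or, me$ci), 3)
#>    OR  2.5% 97.5%
#> 0.102 0.033 0.173
```

Controlling for anatomy, sampling density and spike rate, each additional
normalized connectivity unit multiplies the odds of an electrode being in
the SOZ by about 0.10 — lower connectivity marks the SOZ.

`run_pipeline()` orchestrates all stages and writes seed-stamped,
reproducible TSV reports; see `vignettes/spatial-bias-analysis.Rmd` for the
methods account.

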