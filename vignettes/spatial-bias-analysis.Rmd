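---
title: "Controlling spatial sampling bias in intracranial EEG network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling spatial sampling bias in intracranial EEG network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sozspatial)
```

## Why a spatial null model

Intracranial EEG electrodes are implanted where clinicians already expect
seizures to start. Any analysis that relates electrode-level features to the
seizure onset zone (SOZ) therefore competes with a strong confound: the
electrode positions themselves encode the pre-implant hypothesis. This
package approaches the problem from two directions. First, hemisphere
contrasts are restricted to *symmetric coverage* — atlas regions covered on
both sides — so that a region is always compared with its homotopic twin
under identical sampling. Second, a *spatial null model* predicts SOZ
membership from electrode placement alone (coarse anatomy plus a kernel
density of neighbouring electrodes); EEG-derived classifiers are judged by
how much they beat this benchmark, not chance.

## The processing model

**Preprocessing.** Recordings are channels x samples matrices in microvolts.
A (channel, 2-s window) cell is masked when its peak amplitude exceeds
`amp_thresh` (default 1000 µV) or its range falls below `flat_thresh`
(default 0.1 µV); these thresholds are a deliberately simple, fully
configurable stand-in rule whose role is to exclude gross artifact from
window averages. The common average reference subtracts the instantaneous
channel mean. Filtering is zero-phase Butterworth: a band-stop around 60 Hz
and a 1–70 Hz bandpass. The filter family and order are configurable because
only gross band shaping matters downstream; the defaults give > 20 dB notch
attenuation and < 3 dB passband loss after forward-backward application.

**Networks.** The primary metric is the signed Pearson correlation computed
in non-overlapping 2-s windows, averaged within 1-min segments and then
across segments. With equal numbers of usable windows per segment this
equals the flat window mean (a tested invariant); with masking, edges
average only their defined windows and become NA when no window survives —
undefined edges propagate and are never imputed as zero. The secondary
metric is Welch magnitude-squared coherence (2-s hamming window, 1-s
overlap) averaged within delta (0.5–4), theta (4–8), alpha (8–12), beta
(12–30) and gamma (30–80 Hz) bands. Two conventions are worth noting: with
the default 1–70 Hz bandpass, the effective delta band starts at 1 Hz and
the effective gamma band ends at 70 Hz unless the filter is reconfigured;
and within-patient normalization uses the population SD (divide by n) —
stated here because both conventions silently change third decimals.

**Atlas mapping.** The atlas is consumed as a lookup table (region id,
hemisphere, homotopic partner, coarse anatomy, representative centroid), not
volumetric images — this removes all imaging dependencies while preserving
the algorithmic content, and any parcellation expressible as a table plugs
in. Electrodes get the nearest centroid within `max_dist` (default 20 mm, a
choice on the scale of a parcel radius; beyond it an electrode is
"excluded"); ties break to the smallest region id. Region edges average all
spanning electrode pairs; the diagonal is unknown by definition, so every
downstream average studies inter-regional connections only.

**Contrasts.** Three homotopic contrasts are computed per patient on the
symmetric-coverage network: connectivity incident to SOZ regions vs their
homotopic partners; intra-hemispheric connectivity on the SOZ side vs the
other side (unilateral patients with at least two symmetric regions per
hemisphere); and intrinsic within-SOZ connectivity vs the homotopic set
(SOZ spanning at least two regions). Where the design was genuinely open we
chose: edges between the SOZ set and its homotopic control set count toward
neither average, keeping the two quantities structurally parallel; and SOZ
regions whose homotopic partner is itself an SOZ region (bilateral overlap)
are dropped from the contrast, since no uncontaminated control exists.
Paired tests are Wilcoxon signed-rank with classical conventions (zeros
dropped, midranks for ties), exact for n ≤ 25 via a subset-sum dynamic
program over doubled ranks, normal approximation with tie and continuity
correction beyond.

**Laterality.** A plain maximum-likelihood logistic model (no
regularization, matching the simplicity of the classifier it emulates) is
evaluated leave-one-patient-out with a 0.5 threshold; probability exactly
0.5 predicts left. Hemispheric spike rates average electrodes within
symmetric-coverage regions, so both feature families see the same parcels.

**Spatial null model.** The kernel density at electrode *i* is
`(1/radius^2) * sum_{j != i} (3/pi) (1 - (d_ij/radius)^2)^2`, truncated at
the search radius. The default radius is patient-specific — the distance
between the two furthest electrodes — which makes the truncation inactive
for the default but it is kept so user-supplied radii behave per the
formula. Densities, node-average connectivity and spike rates are
z-normalized within patient; coarse anatomy enters as a categorical with
"other cortex" as the reference level. Four logistic models (anatomy +
density; + connectivity; + spikes; + both) are compared over patient-level
random splits (2/3 train, default 1000 splits; degenerate folds are redrawn
and counted). ROC curves are tie-aware so the trapezoidal area equals the
rank (Mann-Whitney) AUC exactly — both implementations exist and are tested
against each other — and split-averaged ROC curves use vertical averaging on
a fixed false-positive grid. Model pairs are compared with the counting
p-value `2 (min[N(diff<=0), N(diff>=0)] + 1)/(N+1)`, whose floor at 1000
splits is 2/1001 ≈ 0.002. The mixed-effects association model is a
random-intercept logistic regression (intercept-only random effects: the
simplest structure consistent with patients as exchangeable clusters) fit
with `lme4::glmer` at `nAGQ = 0`; the penalized-quasi-Laplace fit is orders
of magnitude faster and its fixed-effect estimates are indistinguishable at
these scales, which is what makes a 1000-resample patient bootstrap
tractable.

## What the synthetic generator emulates

`generate_cohort()` is first-class, tested code, and its defaults define the
study conditions used throughout the test suite:

- laterality sampled as 43.6% left / 30% right / 22.7% bilateral / 3.7%
  none, and 86% stereo implants, matching the composition of a typical
  pre-surgical cohort;
- region coverage bilateral with probability 0.5, otherwise unilateral or
  absent — the asymmetric-coverage regime the symmetric-coverage atlas
  exists to handle;
- two SOZ region pairs per affected hemisphere, chosen uniformly over
  pairs and forced to bilateral coverage (implantation follows the
  pre-implant hypothesis, including the contralateral homologue). Uniform
  choice keeps coarse anatomy uninformative by construction, so the spatial
  null model's signal comes from sampling density alone and the
  uniform-sampling calibration check is honest;
- stereo implants place five tightly clustered electrodes in SOZ regions
  versus two elsewhere (the density bias); grid/strip/depth implants keep a
  uniform 8 mm pitch everywhere, so density carries no SOZ information in
  that stratum;
- signals are correlated Gaussian noise (Cholesky of a target correlation
  matrix applied to AR(1)-smoothed white noise; identical per-channel
  smoothing preserves zero-lag correlations exactly). The target scales
  SOZ-involving edges by `1 - soz_conn_reduction`; per-electrode lognormal
  gains (SD 0.3 on the log scale) add realistic electrode-level variability
  in broad connectivity, making connectivity an informative but imperfect
  electrode-level marker — without them the reduction is detected almost
  noiselessly, which no real biomarker achieves;
- spike rates are gamma-distributed with the SOZ-side mean exactly
  `spike_rate_ratio` times the contralateral mean, with one third of the
  elevation spread over the side and the rest focal to SOZ electrodes —
  spikes in practice concentrate at seizure generators, which is why
  spike-informed models outrank connectivity-informed ones.

The generator does *not* emulate realistic EEG spectra, seizure dynamics,
volume conduction, or electrode localization error. Passing tests therefore
demonstrate that the estimators and study design recover known structure
under the stated statistical assumptions — not that they would perform
identically on clinical recordings.

## Problem sizes and numerical choices

Replicated studies (contrast power, null calibration) simulate 30 s of
signal per patient at 256 Hz: fifteen 2-s windows put the Monte-Carlo error
of a window-averaged correlation near 0.01, far below the probed effect
sizes, so longer records only add runtime. Single-cohort demonstrations and
the covariance-recovery check use up to 600 s. Power and ordering checks use
40-patient cohorts with `soz_conn_reduction = 0.5` and `spike_rate_ratio =
2`; calibration uses 200 replicates of 20-patient null cohorts and asserts
the nominal 5% rejection rate within binomial tolerance, and chance AUC
(±0.05) for the spatial null model under uniform sampling. Study helpers
compute networks on the raw generated signals — the generator emits
referenced, artifact-free, zero-mean signals, so preprocessing would be a
no-op there; `run_pipeline()` applies the full preprocessing chain, and the
preprocessing module carries its own attenuation and commutation tests.

Degenerate inputs are handled explicitly rather than silently: all-masked
networks warn and return NA edges; constant vectors refuse z-normalization;
all-zero difference vectors make the signed-rank test undefined; non-PSD
target covariances are repaired by eigenvalue clipping and flagged;
single-class training folds are skipped (leave-one-out) or redrawn
(split resampling) and counted in the output.

## Known limitations

Coherence networks drop any Welch segment overlapping an artifact-masked
window on *any* channel, which is stricter than the per-channel Pearson
masking. The symmetric-coverage design cannot control intra-regional
electrode-count differences, only inter-regional ones — the subsampling
control exists precisely to show the residual count imbalance does not bias
inter-regional averages. EDF ingestion is not provided; recordings enter as
matrices (or Feather/CSV via the cohort writer). And the spatial null
model's benchmark value is institution-specific by nature: it reflects how
strongly implantation strategy encodes the clinical hypothesis, so absolute
AUCs from synthetic cohorts transfer only qualitatively.
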