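---
title: "Quantifying early tumor therapy response from diffusion-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early tumor therapy response from diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiresponse)
```

## The problem

Size-based response criteria (RECIST-style longest diameters) are often
insensitive to the early effects of anti-angiogenic and pro-apoptotic
therapies: a treated tumor may keep growing while its microstructure is
already changing. Diffusion-weighted MRI (DW-MRI) offers a complementary,
functional readout. The apparent diffusion coefficient (ADC) quantifies
water mobility in tissue; dense, highly cellular tumor tissue restricts
diffusion (low ADC), while apoptosis and necrosis increase it. In a
two-group preclinical design — tumor-bearing animals imaged before and
after a week of drug or placebo — the per-animal *changes* in median tumor
ADC (dADC, absolute, units 1e-3 mm^2/s) and in tumor volume (dVOL, percent
of baseline) can each be used as a classifier separating treated from
control animals, and their linear combination via Fisher's discriminant
typically separates better than either alone.

This package implements that full analysis chain as reusable, tested
components:

1. **Registration** of the multi-b-value DWI series (translation-only,
   Fourier cross-correlation) to keep bulk motion out of the decay fit.
2. **Voxelwise ADC mapping** by nonlinear least-squares fitting of the
   monoexponential decay `S(b) = S0 * exp(-b * ADC)`.
3. **VOI metrics**: median tumor ADC over a 3D volume of interest, and
   voxel-count tumor volume from a (typically T2-weighted) mask.
4. **Statistics**: paired Wilcoxon signed-rank, Mann-Whitney U, Pearson
   correlation, empirical ROC curves with Youden-optimal thresholds,
   DeLong's test for correlated AUCs, and a two-class Fisher linear
   discriminant on (dVOL, dADC).
5. **Synthetic data**: DWI phantoms with known ground truth and two-group
   cohorts with configurable effect sizes, so every stage is testable
   end-to-end without animal data.

## Signal model and ADC fitting

Each voxel's signal over the b-values is modelled as
`S(b) = S0 * exp(-b * ADC)` and fitted by unweighted nonlinear least
squares over `S0 > 0` and `ADC` in `[0, adc_max]`. Conventions and
numerical choices:

* **Units.** ADC is carried in 1e-3 mm^2/s throughout (free water at body
  temperature is about 3; typical cellular tumor tissue 0.6-1.2). The
  default acquisition has 9 b-values, 10-800 s/mm^2, with no b = 0 image,
  so `S0` is an extrapolated free parameter, not a measured intensity.
* **Bounds.** `adc_max = 10` (1e-3 mm^2/s) only rejects pathological fits;
  a fit landing exactly on a bound is still reported as converged, since a
  zero decay rate is the correct least-squares answer for, e.g., constant
  signal.
* **Solver.** `S0` is profiled out in closed form (for fixed ADC the
  optimal `S0` is `sum(S*w)/sum(w^2)`, `w = exp(-b*ADC)`), leaving a 1-D
  maximization of a smooth profile function. That profile is seeded on a
  161-point grid over the full ADC range together with the log-linear
  least-squares initial estimate, and polished by a bracketed,
  bisection-safeguarded Newton iteration to a relative bracket width of
  1e-13, vectorized across all voxels of a map. On model-consistent
  (noiseless) data this recovers the generating parameters to better than
  1e-9 relative, which the test suite asserts; equivalence with a dense 2D
  grid-search oracle is asserted on noisy voxels.
* **Unfittable voxels.** A voxel with at least half its signals
  non-positive (air, background) is flagged invalid rather than raising an
  error, and carries `NA` in the map. Invalid voxels are *excluded* from
  VOI statistics, never zero-filled — zeros would bias the median ADC
  downward.
* **No Rician-bias correction.** The objective is plain least squares, so
  at very low SNR the noise floor biases ADC estimates downward at high b.
  This is a documented limitation, consistent with keeping the fit model
  minimal; the phantom tests quantify the residual bias at SNR 50 (well
  under 2 % on the median).

Trace images (the average over three orthogonal diffusion-gradient
directions) are supported by `trace_average()`; the synthetic phantom emits
trace-equivalent images directly, and direction-level simulation is out of
scope.

## Registration

The series is aligned along the b-value dimension with a translation-only,
per-slice phase correlation: the cross-power spectrum of reference and
moving slice is whitened to unit magnitude and inverted; the peak of the
resulting surface is the displacement. Sub-voxel refinement evaluates the
surface on a 0.01-voxel grid within half a voxel of the integer peak using
a local matrix DFT. Design choices, made where the method family leaves
them open:

* **Reference = lowest b-value** (highest SNR); registration is 2D
  per-slice, as bulk motion in an anesthetized animal on an axial protocol
  is predominantly in-plane. Rotation is out of scope: the estimator
  family is translational.
* **Circular boundary semantics** are inherent to the Fourier model; both
  estimation and resampling (by frequency-domain phase ramp, exact for
  band-limited content) wrap around. Phantoms keep objects away from
  edges; real data with structure at the FOV edge would need windowing,
  which is not implemented.
* **Featureless slices.** If reference *and* moving slice are constant (up
  to floating-point ripple), there is no motion information and shifting a
  constant image is the identity, so the shift is defined as exactly zero;
  if only one of the two is constant, that is a degenerate-input error.
  This keeps noiseless phantoms with empty outer slices registrable while
  still surfacing genuinely broken inputs.
* **Zero estimated shift skips resampling**, so a motion-free series is
  returned bit-identically.

The test suite checks integer-shift recovery against a brute-force
cross-correlation argmax, fractional recovery within 0.1 voxel on smooth
images, anti-symmetry, intensity-scale invariance, and that registration
strictly reduces the voxelwise ADC error on a moving phantom.

## VOI metrics

The representative tumor ADC is the **median** over valid voxels inside the
VOI (medians resist the long right tail that necrotic regions produce).
Tumor volume is `count * voxel_x * voxel_y * (thickness + gap)` mm^3; for
gapless T2-weighted masks this is count times voxel volume. Growth is
always expressed relative to baseline, `100 * (VOL_F - VOL_B)/VOL_B`, and
change summaries are computed **per animal first**: the group median of
per-animal changes is not the change of group medians, and the test suite
pins that distinction. The caliper formula `a*b*c*0.5` is provided for
pre-imaging enrollment volumetry.

## Statistical layer

* **Rank tests.** Paired Wilcoxon signed-rank (within group,
  baseline vs follow-up) and Mann-Whitney U (between groups), both
  two-sided, delegate to `stats::wilcox.test` with pinned conventions:
  zero differences dropped (classic Wilcoxon), exact distributions
  whenever the (pooled) sample size is at most 25 and the data are
  tie-free — so 12-vs-11 designs are exact — and the normal approximation
  with tie and continuity correction otherwise. Exactness requires a fully
  tie-free pooled sample (not only cross-group ties), matching the
  switching rule of the underlying implementation. The suite verifies the
  exact branch against full enumeration (all 2^n sign assignments, all
  C(n1+n2, n1) labelings).
* **ROC.** Threshold candidates are midpoints between consecutive distinct
  scores plus infinite sentinels — the convention under which printed
  optimal thresholds that fall *between* two observed animals are
  reproducible. AUC is the trapezoidal area, identical to the
  tie-corrected Mann-Whitney statistic `(U + t/2)/(n1*n2)` (asserted on
  random data). The operating point maximizes Youden's J, with ties broken
  by higher specificity, then lower threshold.
* **DeLong.** Correlated AUCs are compared through placement values
  (structural components): per-case conditional concordance probabilities
  whose empirical covariance yields the variance of the AUC difference;
  the difference is referred to a two-sided z-test. The suite cross-checks
  p-values against the pROC package and against a 1e5-replicate paired
  stratified bootstrap, and verifies the test holds its nominal size at
  n = 23 over 2000 null simulations.
* **FLDA.** The two-class Fisher direction is the inverse pooled
  within-class covariance (denominator `n1 + n2 - 2`) times the mean
  difference. Fisher weights are defined only up to positive scale, so the
  canonical model is unit-norm and oriented so that the *control* group
  scores higher (therapy falls below the decision threshold);
  `rescale_flda()` re-expresses the model with a pinned dADC weight for
  comparison with weights reported on another scale, where only the weight
  ratio and induced classification are meaningful. The model is fitted and
  evaluated on the same animals (resubstitution), mirroring the original
  study design at n = 23; no cross-validation is attempted, and reported
  FLDA accuracies should be read accordingly.

## The synthetic-data module

**Phantoms.** An ellipsoidal tumor (default ADC 0.75) in a homogeneous
background (default 1.40, approximating partially necrotic/edematous
surroundings), optionally with a necrotic-core sub-ellipsoid and an
air-filled exterior (signal exactly zero). The default grid is 64 x 48 x 6
voxels at 1 x 1 mm in-plane, 2 mm slices with 0.4 mm gap — a coarse
analog of a 65 x 50 mm rodent field of view — with the 9-point b-value
scheme above; this size keeps the full register-fit-summarize closure
tests fast while leaving >800 tumor voxels for order statistics. Noise is
**Rician** (`sqrt((v+n1)^2 + n2^2)`, `n1, n2 ~ N(0, sigma^2)`),
parameterized by `snr = s0_tumor/sigma`, the physically standard model for
magnitude MR images; it deliberately stresses the fit's low-signal
behaviour at b = 800. Bulk motion is injected per b-value *before* noise;
fractional shifts use the same Fourier resampling as the registration
module, so the phantom and the corrector share one interpolation model.

**Cohorts.** Per group, `(dADC, dVOL)` pairs are drawn from a bivariate
normal — Gaussian margins at the configured location/scale, coupled with
the configured correlation (a Gaussian copula with Gaussian margins; the
configured `r` is then also the Pearson correlation, which is what the
study-level scatter plots report). Because Gaussian medians equal means,
reported median +/- SD summaries can be used directly as locations and
scales; the defaults encode a 12-vs-11 regorafenib-vs-placebo xenograft
study: therapy dADC `0.10 +/- 0.11` (1e-3 mm^2/s), dVOL `33.30 +/- 47.30 %`,
r = 0.05; control `0.03 +/- 0.09`, `96.43 +/- 31.66 %`, r = 0.65; baseline
ADC `0.76/0.73 +/- 0.09`. Baseline volumes are **log-normal** with the
configured median and SD (therapy `347.8 +/- 449.1` mm^3): with a SD larger
than the median, a Gaussian would produce negative volumes. Follow-up
values are derived so the deltas are exact (`adc_f = adc_b + d_adc`,
`vol_f = vol_b * (1 + d_vol_pct/100)`), and draws violating positivity
(`d_vol_pct <= -100`, non-positive ADC) are redrawn inside the seeded
stream. That truncation removes about 0.24 % of the therapy group's lower
tail and shifts the realized therapy dVOL median up by roughly +0.14
percentage points — negligible against the between-cohort spread at n = 12,
and quantified by the generator-calibration tests.

What the generator does *not* emulate: realistic anatomy, coil
sensitivities, EPI distortion, perfusion/IVIM signal components, kurtosis,
or any within-animal linkage between the imaging phantom and the cohort
tables. Passing tests therefore demonstrate correctness of the estimation
and statistics chain under the declared models, not robustness to
artifacts those models exclude.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::with_seed`,
leaving the session RNG untouched), and identical seeds give bit-identical
outputs. The shipped checks use: full phantoms (64 x 48 x 6) for noiseless
closure, 32 x 28 x 5 phantoms for motion studies, n = 1e4/group for
generator calibration, 500 repeated cohorts for mean-AUC ordering, 2000
null simulations for the DeLong size check, and a 1e5-replicate bootstrap
for the DeLong oracle comparison. `scripts/acceptance.R` re-runs the main
pipeline quantities from scratch for any seed.

## A worked example

```{r example, eval = FALSE}
# simulate a study-sized cohort and analyze it
cohort <- generate_cohort(cohort_config(seed = 42))
report <- run_cohort_analysis(cohort)
print(report)

# image side: phantom with motion, registered and fitted
cfg <- phantom_config(snr = 50,
                      shifts = cbind(runif(9, -1, 1), runif(9, -1, 1)))
ph <- generate_phantom(cfg)
reg <- register_series(ph$study)
map <- compute_adc_map(reg$study, mask = ph$mask)
median_adc(map, ph$mask)
```

## Known limitations

* Translation-only registration; no rotation, affine, or deformable model,
  and no baseline-to-follow-up (inter-session) registration — sessions are
  analyzed independently.
* Unweighted least squares without Rician bias correction; IVIM and
  kurtosis models are out of scope.
* Resubstitution evaluation of the FLDA classifier (by design, to mirror
  the two-group study layout).
* The exact scaling and intercept conventions of discriminant weights vary
  across implementations; only weight ratios and the induced
  classification transfer between packages.
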