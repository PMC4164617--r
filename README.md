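# dwiresponse

Early monitoring of tumor therapy response from diffusion-weighted MRI
(DW-MRI), for preclinical two-group designs: animals bearing xenograft
tumors are imaged before and after a treatment interval, and the per-animal
changes in median tumor ADC and in tumor volume are evaluated — singly and
combined — as classifiers separating treated from control animals.

The package covers the whole chain from multi-b-value images to a study
report:

* **Registration** of the DWI series along the b-value dimension
  (translation-only phase correlation with sub-voxel refinement).
* **ADC mapping**: voxelwise nonlinear least-squares fit of the
  monoexponential decay *S(b) = S₀·exp(−b·ADC)* over S₀ > 0,
  ADC ∈ [0, adc_max]; validity flags for unfittable voxels.
* **VOI metrics**: median tumor ADC over a 3D volume of interest,
  voxel-count volume (`count · vx · vy · (thickness + gap)`), relative
  growth in percent of baseline, caliper volume `a·b·c·0.5`.
* **Statistics**: paired Wilcoxon signed-rank and Mann-Whitney U tests
  (exact for tie-free samples up to n = 25), Pearson correlation, empirical
  ROC curves with Youden-optimal thresholds, DeLong's test for correlated
  AUCs (placement-value covariance), and a two-class Fisher linear
  discriminant FLDA(ΔVOL, ΔADC) = w₁·ΔVOL[%] + w₂·ΔADC[10⁻³ mm²/s].
* **Synthetic data**: DWI phantoms with known ground-truth ADC, Rician
  noise and per-b-value bulk motion; two-group cohorts with configurable
  medians, spreads and ΔADC–ΔVOL correlation (defaults encode a 12-vs-11
  therapy/control xenograft study).

I/O uses NIfTI-1 (via RNifti) with FSL-style `.bval` or JSON sidecars and
plain CSV cohort tables.

## Worked example

```r
library(dwiresponse)

# a study-sized synthetic cohort: 12 therapy vs 11 control animals
cohort <- generate_cohort(cohort_config(seed = 42))
report <- run_cohort_analysis(cohort)
print(report)
```

```
Two-group DWI therapy-response report
  therapy n = 12, control n = 11
  Tumor ADC (1e-3 mm^2/s), median +/- SD:
    therapy ADC_B 0.77+/-0.10  ADC_F 0.93+/-0.15  dADC 0.16+/-0.10
    control ADC_B 0.72+/-0.08  ADC_F 0.81+/-0.10  dADC 0.05+/-0.11
  Tumor volume (mm^3), median +/- SD:
    therapy VOL_B 228.0+/-290.0  VOL_F 221.8+/-577.7  dVOL% 22.2+/-62.0
    control VOL_B 226.3+/-57.8  VOL_F 465.4+/-165.9  dVOL% 107.5+/-28.5
  Intergroup dADC p = 0.001688, dVOL p = 0.0001435
  ROC:
    d_adc     AUC 0.871  thr 0.09212  sens 75.0%  spec 90.9%  acc 82.6%
    d_vol_pct AUC 0.932  thr 40.22  sens 75.0%  spec 100.0%  acc 87.0%
    flda      AUC 0.992  thr 0.07356  sens 91.7%  spec 100.0%  acc 95.7%
  DeLong FLDA vs dADC p = 0.1251, FLDA vs dVOL p = 0.1821, dADC vs dVOL p = 0.5563
  Pearson r(dADC, dVOL): therapy 0.17 (p = 0.606), control 0.83 (p = 0.00162)
```

Reading the report: the therapy group shows the larger ADC increase
(median ΔADC +0.16 vs +0.05 ×10⁻³ mm²/s) and the smaller relative growth
(+22 % vs +108 %); each single classifier leaves overlap between groups
(AUC 0.87 / 0.93, accuracy ≤ 87 %), while their Fisher combination
separates almost perfectly (AUC 0.99, accuracy 95.7 % — one animal
misclassified out of 23). Scores below the FLDA threshold are called
"therapy".

The image side of the pipeline, on a ground-truth phantom with Rician
noise (SNR 50):

```r
ph  <- generate_phantom(phantom_config(snr = 50, seed = 7))
map <- compute_adc_map(ph$study, mask = ph$mask)
median_adc(map, ph$mask)   # 0.7510269  (true tumor ADC: 0.75)
mask_volume(ph$mask)       # 2054.4 mm^3
```

`run_image_pipeline()` chains register → fit → VOI metrics over a cohort
of sessions (NIfTI files or phantom configs) into a cohort table;
`run_cohort_analysis()` turns any cohort table into the report above. A
thin command-line front end with `simulate` / `image` / `analyze`
subcommands is installed under `inst/scripts/dwiresponse-cli.R`.

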