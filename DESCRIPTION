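Package: dwiresponse
Title: Therapy-Response Analysis for Diffusion-Weighted MRI of Tumor Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying early tumor therapy response
    from multi-b-value diffusion-weighted MRI. Provides translation-only
    Fourier cross-correlation registration along the b-value dimension,
    voxelwise monoexponential fitting of apparent diffusion coefficient (ADC)
    maps, volume-of-interest summary metrics (median tumor ADC, voxel-count
    volume), and a statistical layer: paired Wilcoxon and Mann-Whitney tests,
    Pearson correlation, empirical ROC curves with Youden-optimal thresholds,
    DeLong comparison of correlated AUCs, and a two-class Fisher linear
    discriminant combining ADC and volume changes. A synthetic-data module
    generates DWI phantoms with known ground truth (Rician noise, bulk
    motion) and two-group cohorts with configurable effect sizes, so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
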