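Package: cestkit
Title: Preclinical CEST-MRI Processing, Fitting and Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A scriptable toolkit for preclinical chemical exchange saturation
    transfer (CEST) MRI analysis. Covers reading ParaVision-style experiment
    directories and portable bundles, respiratory motion binning for radial
    acquisitions, PCA Z-spectral denoising with Malinowski's empirical
    indicator, thermal drift correction, manual and six-segment left
    ventricular myocardial segmentation, two-step Lorentzian Z-spectral
    fitting with internal B0 correction, WASSR B0 and double-angle B1 field
    mapping, variable-TR T1 mapping, QUESP exchange-rate quantification by
    three analytical routes, and CEST fingerprinting dictionary generation
    and dot-product matching backed by a multi-pool Bloch-McConnell
    simulator. A synthetic phantom generator provides ground-truth fixtures
    for every experiment type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png
Config/testthat/edition: 3
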