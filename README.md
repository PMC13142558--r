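# cestkit

Scriptable preclinical CEST-MRI analysis for R: Z-spectral fitting, field
mapping, quantitative exchange-rate mapping, and CEST fingerprinting, with
a synthetic phantom generator so every stage is testable without scanner
data.

Chemical exchange saturation transfer (CEST) MRI saturates exchangeable
solute protons (amide, creatine, hydroxyl, ...) off-resonance and reads out
the attenuation they transfer to the water signal. The measurement is the
Z-spectrum — normalized water signal `Z(Δω) = S(Δω)/S0` versus saturation
offset — and the analysis problem is to separate small solute dips from the
dominant water line, semisolid magnetization transfer (MT) background, and
B0/B1 field inhomogeneity. cestkit packages the standard preclinical
workflow for this problem as composable R functions plus a batch pipeline,
aimed at small-animal imaging groups (cardiac and phantom studies in
particular) who want reproducible, scriptable analysis rather than
per-lab one-off scripts.

## What it does

* **Input**: ParaVision-style experiment directories (JCAMP-DX `method`
  file + image block, PV6/7 MT-module dialect) via
  `read_paravision_experiment()`, or portable bundles (binary arrays + JSON
  sidecar) via `read_bundle()`/`write_bundle()`.
* **Preprocessing**: respiratory motion binning for radial acquisitions
  (`motion_bin()`), global PCA Z-spectral denoising with Malinowski's
  empirical indicator for rank selection (`pca_denoise()`), thermal drift
  correction (`thermal_drift_correct()`), rotations/flips (`orient()`).
* **Segmentation**: manual polygon ROIs (`polygon_mask()`) and
  semi-automated six-segment left-ventricular myocardial segmentation from
  epi-/endocardial contours and the two LV insertion points
  (`lv_segments()`).
* **Z-spectral fitting**: two-step Lorentzian fitting with internal
  B0 self-correction and Lorentzian-difference contrast extraction
  (`fit_two_step()`, `fit_pixelwise()`, `fit_segmentwise()`), modeling

  `Z(Δω) = 1 − Σᵢ Aᵢ (γᵢ²/4) / (γᵢ²/4 + (Δω − ωᵢ)²)`.

* **Field maps**: WASSR B0 (`wassr_b0()`), double-angle B1
  `κ = acos(M2θ/2Mθ)/θnom` (`dam_b1()`, `upsample_map()`), variable-TR T1
  (`t1_map()`), per-segment statistics (`segment_field_stats()`).
* **QUESP**: proton volume fraction `fb` and exchange rate `kb` from
  multi-B1 series by three routes — the closed-form CW MTRasym solution,
  the steady-state MTRRex metric `fb·kb·α/R1a` with
  `α = ω1²/(ω1²+kb²)`, and the omega-plot linearization — with
  steady-state validity warnings (`fit_quesp()`,
  `steady_state_warning()`).
* **CEST fingerprinting**: Bloch-McConnell dictionary simulation over
  `(fb, kb, R1a, R2a)` grids and dot-product matching
  (`build_dictionary()`, `match_dictionary()`, `to_concentration()`).
* **Reporting**: sequential κ/B0/MT pixel filtering (`filter_pixels()`),
  percentile display clipping (`percentile_clip()`), CSV tables and map
  exports, and the deterministic batch pipeline (`run_pipeline()`), with a
  thin CLI wrapper in `inst/cli/cestkit.R`.
* **Synthetic phantoms** (`make_zspec_phantom()`, `make_field_fixtures()`,
  `make_radial_series()`, `make_mrf_fixture()`) generate every input class
  with known ground truth.

## Worked example

Fit a noisy synthetic Z-spectrum whose truth is water (A = 0.9), MT
(A = 0.1) and amide (A = 0.05 at +3.5 ppm), shifted by +0.2 ppm to emulate
B0 inhomogeneity:

```r
library(cestkit)
offs <- seq(-6, 6, by = 0.2)
z <- rep(1, length(offs))
truth <- data.frame(A = c(0.9, 0.1, 0.05), g = c(1.4, 25, 1.0),
                    w = c(0, -2.5, 3.5))
for (i in 1:3) z <- z - lorentzian(truth$A[i], truth$g[i], truth$w[i],
                                   offs - 0.2)
set.seed(1)
z <- z + rnorm(length(offs), sd = 0.005)

fit <- fit_two_step(offs, z, pools_requested = "amide")
round(fit$pools, 4)
#>            A gamma_ppm omega_ppm
#> water 0.8986    1.4163    0.0000
#> MT    0.0979   28.4615   -2.4008
#> amide 0.0466    0.8372    3.4904
round(fit$b0_shift_ppm, 4)
#> [1] 0.201
```

The fit recovers the imposed +0.2 ppm B0 shift, the amide amplitude within
the noise (0.047 vs 0.05 true, i.e. a 4.7% CEST effect at 3.5 ppm), and
reports the step RMSEs (`fit$rmse_step1`, `fit$rmse_step2`, here ~0.005,
matching the noise level). A noiseless QUESP series inverts exactly:

```r
b1 <- c(1, 2, 3, 4, 6)                      # saturation amplitudes, uT
y <- mtrasym_model(fb = 7.2e-4, kb = 800, b1, r1a = 0.33, tp_s = 4)
qf <- fit_quesp(quesp_series(b1, 4, mtr_asym = y, r1a = 0.33), "mtr_asym")
c(fb = qf$fb$values[1, 1], kb = qf$kb$values[1, 1])
#>      fb      kb
#> 7.2e-04 8.0e+02
```

`run_pipeline()` ties the stages together: given a bundle with CEST, WASSR
and double-angle members plus an LV geometry JSON, it writes the six-segment
fit table, B0/κ maps, per-segment field statistics and a manifest into a
results directory, deterministically for a fixed config and seed.

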