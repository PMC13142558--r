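---
title: "Models and methods in cestkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cestkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestkit)
```

cestkit is a batch-oriented toolkit for preclinical CEST-MRI analysis. This
vignette explains the models behind each stage, the parameters that matter,
the numerical choices we made where the literature leaves them open, and the
limits of what the synthetic-phantom tests can demonstrate.

## The Z-spectrum model and the two-step fit

A CEST experiment saturates at a series of frequency offsets $\Delta\omega$
(ppm, positive downfield of water) and records the normalized water signal
$Z(\Delta\omega) = S(\Delta\omega)/S_0$. We model the spectrum as a constant
baseline minus a sum of Lorentzian lines,

$$Z(\Delta\omega) = 1 - \sum_i L_i, \qquad
L_i = A_i \frac{\gamma_i^2/4}{\gamma_i^2/4 + (\Delta\omega - \omega_i)^2},$$

with amplitude $A_i$ (fraction of $M_0$), full width at half maximum
$\gamma_i$ (ppm), and center $\omega_i$ (ppm relative to water).

`fit_two_step()` proceeds in three passes:

1. **Step 0** fits water + semisolid MT over the entire spectrum. The fitted
   water center is the per-spectrum $B_0$ shift and is subtracted from the
   frequency axis. All points are used here; the exclusion band applies only
   to the refit.
2. **Step 1** refits water + MT on the corrected axis with offsets at
   $1.4 \le |\Delta\omega| \le 4$ ppm excluded, so the CEST and rNOE pools
   cannot bias the reference. The axis is recentred once more on the refitted
   water line (the fitted centers move with it, leaving the model unchanged
   in the original frame).
3. **Step 2** forms the Lorentzian difference (reference fit minus measured
   $Z$, so CEST peaks are positive) and fits the requested solute pools to
   it.

Both step RMSEs are reported, and pixels whose fits fail to converge are
marked invalid rather than aborting a batch.

**Pool table.** Two-step fits are notoriously sensitive to initial values
and bounds, so the defaults live in one editable table
(`default_pools()`): water (0 ppm, FWHM 1.4, $A \in [0.02, 1]$), MT
(−2.5 ppm, FWHM 25, $A \in [0, 0.4]$), amide (+3.5), creatine/amine (+2.0),
hydroxyl (+1.0), rNOE (−3.5), following common 7 T literature values. We
bound the MT center tightly ($-2.5 \pm 0.1$ ppm): with a free MT center the
reference fit drifts toward the solute side of the spectrum and absorbs part
of the CEST signal, which biased amide amplitudes by ~15% on noiseless
fixtures. Pinning the semisolid line at its conventional position removed
that bias; the center remains editable in the table for tissues where the
convention differs.

**Least squares.** All nonlinear fits use bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with `ftol = 1e-8` and at most 400 iterations,
recorded in the fit configuration.

## Bloch–McConnell simulation

The simulator (`simulate_z()`, `simulate_trajectory()`) propagates the
coupled magnetization of up to four proton pools: free water plus solutes,
each with volume fraction $f_b$, exchange rate $k_b$ (solute to water,
s$^{-1}$), chemical shift, $R_1$ and $R_2$. Exchange obeys detailed balance
(water-to-solute rate $k_b f_b$); solute–solute exchange is not modeled.
Only continuous-wave saturation is supported, so each segment is a linear,
time-invariant ODE solved exactly by the matrix exponential of the augmented
$(3N{+}1)$ system. We evaluate the exponential through the
eigendecomposition of the generator, which is exact for these matrices and
fast enough to build fingerprinting dictionaries in seconds; decompositions
are cached per distinct (B1, offset) event within a trajectory.

**Readout model.** Dictionary simulations need a readout convention, which
published descriptions typically delegate to the sequence object. We model
the single-shot EPI readout as an instantaneous sampling of
$\sin\theta \cdot M_z$ followed by scaling of all longitudinal components by
$\cos\theta$ with transverse spoiling. The additional `readout_scaling`
factor (default 1) is exposed and recorded so alternative conventions can be
matched; magnetization is always carried across schedule entries with no
full-relaxation assumption.

## Field mapping

**WASSR B0.** Each pixel's narrow-band water-saturation spectrum is
interpolated onto 1000 uniform points with a cubic spline and fitted with a
single Lorentzian on a free baseline $b \in [0.8, 1.2]$; the fitted center
is the B0 shift. The interpolation count and the free (rather than unity)
baseline are deliberate: the former follows the standard WASSR recipe, and
the latter tolerates imperfect normalization of the reference frame.

**Double-angle B1.** $\theta = \cos^{-1}(M_{2\theta} / 2 M_\theta)$ and
$\kappa = \theta/\theta_{\text{nominal}}$. Pixels whose arccosine argument
leaves $[-1, 1]$ or whose signal sits below a noise floor (default five
background standard deviations) are invalid. Low-resolution maps are
upsampled to the reference matrix by separable cubic splines, which
reproduce constants and linear ramps exactly; no coregistration is applied
because the acquisitions share a field of view.

**Variable-TR T1.** Per pixel we fit
$S(\text{TR}) = M_0 (1 - e^{-\text{TR}/T_1})$ by bounded least squares. The
fixtures use eight TRs from 0.3 to 10 s around a 1.8 s myocardial-like T1.

## QUESP

With $\omega_1 = \gamma B_1$ ($\gamma = 2\pi \cdot 42.577$ rad s$^{-1}
\mu$T$^{-1}$; B1 inputs are in microtesla), the saturation efficiency is
$\alpha = \omega_1^2 / (\omega_1^2 + k_b^2)$. Three routes recover
$(f_b, k_b)$ from a multi-B1 series:

* `mtr_asym`: bounded nonlinear fit of the closed-form CW MTR$_{asym}$
  solution, including its transient terms in the initial magnetization
  $Z_i$ (default 1, overridable);
* `mtr_rex`: fit of the steady-state inverse-difference metric
  $\text{MTR}_{Rex} = f_b k_b \alpha / R_{1a}$;
* `omega_plot`: ordinary least squares of $1/\text{MTR}_{Rex}$ against
  $1/\omega_1^2$, with $k_b = \sqrt{\text{slope}/\text{intercept}}$ and
  $f_b = R_{1a}/(\text{intercept} \cdot k_b)$. The y-variable must be the
  *inverse* metric for the linear form to hold. Nonpositive intercepts mark
  the pixel invalid.

$R_{1a}$ comes from a pixelwise T1 map when supplied, else from a scalar T1.
`steady_state_warning()` flags acquisitions where $t_p < 5\,T_{1a}$ (the
steady-state routes assume saturation equilibrium) or where the recovery
delay is shorter than $5\,T_{1a}$ (incomplete relaxation between readouts).
Default fit bounds are $f_b \in [10^{-6}, 0.05]$ and
$k_b \in [10, 2\times10^4]$ s$^{-1}$.

The closed-form solution ignores direct water saturation and solute
linewidth, so we validate it against the full simulator only in the dilute,
low-spillover regime (fb $\le 10^{-3}$, offsets $\ge 2$ ppm at 7 T,
B1 $\le 2\,\mu$T, long water T2 as in phosphate-buffered phantoms), where
the two agree within 10%. At higher powers or shorter water T2 the
discrepancy grows beyond that; that reflects the model's known range of
validity, not a numerical defect.

## CEST fingerprinting

A scenario defines parameter grids for $(f_b, k_b, R_{1a}, R_{2a})$, fixed
solute relaxation and shift, and an acquisition schedule (per-image B1,
offset, saturation time, recovery, flip). `build_dictionary()` simulates one
trajectory per grid point in deterministic lexicographic order and
L2-normalizes each row; `match_dictionary()` normalizes the measured
trajectory and selects the row with the largest inner product (cosine
similarity, so the reported dot product is bounded by 1), breaking ties
toward the lowest row index. Proton volume fractions convert to
concentrations as $f_b \cdot 111000 / n_{\text{protons}}$ mM, taking water
as 55.5 M with two protons per molecule.

Only one solute pool's $(f_b, k_b)$ varies per dictionary, mirroring the
single-solute creatine phantom setting; the grid-size cap (default
$2\times10^6$) guards against accidental desk-scale explosions. The test
dictionaries use a 30-image schedule with B1 cycling over 1–6 µT, 2 s
saturation and 1.5 s recovery — the short recovery deliberately keeps T1
information in the trajectory so water relaxation rates remain identifiable.

## Preprocessing

**Respiratory motion binning** (radial acquisitions): projections are
summed per acquisition segment, a centered moving average (default window
5 segments) tracks the slow trend, and segments whose sum drops more than
`n_sigma` (default 1.0) global standard deviations of that moving average
below it are flagged as motion-corrupted. The same number of segments is
then discarded at every offset — the maximum flagged count, removing the
lowest-sum segments elsewhere — because unequal projection counts across
offsets would bias quantified contrasts. Whether the threshold should use a
global or windowed standard deviation is not settled; we use the global one
and record it. Retained projections are never altered, only selected, and
can be exported for external gridding reconstruction (image reconstruction
itself is out of scope).

**PCA denoising** is global (all pixels, not tissue-wise). The pixels ×
offsets matrix is mean-centered over offsets and truncated at the rank
minimizing Malinowski's empirical indicator
$\text{IND}(n) = \text{RE}(n)/(c-n)^2$ with
$\text{RE}(n) = \sqrt{\sum_{j>n}\lambda_j / (r(c-n))}$. Eigenvalues at
numerical-noise level are clamped to zero so exact low-rank data selects
the true rank. Constant stacks return unchanged with rank 0.

**Thermal drift** is modeled as a single multiplicative factor linear in
acquisition time, fitted to the means of time-stamped reference frames and
normalized to 1 at the first reference time; the cited drift-correction
literature gives no formula, so we chose the minimal model and log its
coefficients.

**Orientation** fixes (quarter-turn rotations, flips) apply identically to
every frame and the M0 image and are recorded; the LV segmentation assumes
radiological short-axis display convention.

## LV segmentation

The myocardial mask is the epicardial polygon minus the endocardial one
(pixel-center, even-odd rasterization). Coordinates are centered on the mask
centroid, per-pixel angles computed by `atan2` in a y-up frame, and the
frame rotated so the inferior insertion point sits at 0° with angles
increasing counterclockwise. The arc from the inferior to the anterior
insertion spanning less than 180° is the septum (anatomically correct for
short-axis slices; overridable for atypical geometry), split into two equal
*angular* halves — inferoseptal adjacent to the inferior point; whether the
split should be by angle or by mid-wall arc length is unstated in the
six-segment convention, and we chose angle. The free wall splits into four
equal quarters ordered anterior → anterolateral → inferolateral → inferior
from the anterior insertion point. All sector intervals are half-open, so
boundary pixels are assigned deterministically and the six masks partition
the annulus exactly.

## Pixel filtering and display

The post-hoc filter chain runs in a fixed order: (1) discard pixels whose
$\kappa$ deviates from the per-dataset mean by more than 1 standard
deviation ("per-animal", since one bundle holds one animal); (2) discard
$|B_0| > 0.25$ ppm; (3) discard MT amplitude < 2%. Attrition is logged per
step and re-running is bit-identical. Display maps are percentile-clipped
(linear interpolation between closest ranks, i.e. `quantile` type 7);
values strictly inside the percentile range are never changed.

## Synthetic phantoms, and what the tests do and do not show

Every fixture generator emits its ground truth alongside the data: Z-spectra
by the Lorentzian forward model (fast path) or the Bloch–McConnell simulator
(physics path), WASSR dips centered at the true B0, double-angle pairs from
$\sin(\kappa\theta)$, variable-TR series from the T1 model, annulus
sinograms with amplitude-attenuated segments for motion corruption, and
vial layouts with simulated MRF trajectories. Defaults mirror the two
target settings: a 64×64 matrix (as in the phantom EPI protocol), a
cardiac annulus of outer radius 20 and inner radius 12 pixels with
insertion points at 180°/270°, 50 mM-creatine-like solute parameters, and
Gaussian noise on normalized signal (σ = 0.002–0.005; Rician noise is not
simulated).

Passing tests therefore demonstrate correctness of the algorithms against
known truth and internal consistency between the analytical models and the
simulator. They do not demonstrate robustness to real-scanner effects the
generators omit: Rician noise floors at low SNR, B0/B1 fields with
structure finer than the imposed gradients, imperfect spoiling, pulsed (as
opposed to CW) saturation, through-plane motion, or reconstruction
artifacts. Problem sizes in the suite (64×64 single-slice images, 61-offset
spectra, dictionaries up to a few thousand entries, 100-draw Monte-Carlo
loops) were chosen as the smallest that exercise every code path while
keeping the whole suite quick to run routinely.

## Known limitations

* Single-slice, single-solute-per-dictionary workflows only; no 3D or
  multi-slice support.
* CW saturation only; pulsed saturation trains and shaped pulses are not
  modeled, and the semisolid MT pool uses a Lorentzian line rather than a
  super-Lorentzian.
* The ParaVision reader targets the PV6/7 MT-module dialect through a
  configurable key map and fails loudly on unknown dialects; its default
  key names should be validated against real PV6/7 archives.
* Image reconstruction (gridding/NUFFT for radial data) is out of scope;
  the toolkit bins projections and consumes reconstructed images.
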