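---
title: "Quantitative ultrasound tumor characterization and cross-scanner agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound tumor characterization and cross-scanner agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative ultrasound (QUS) estimates tissue microstructure from calibrated
spectral analysis of beamformed radiofrequency (RF) echo data, rather than
from B-mode brightness. In breast-cancer response monitoring, tumors of
patients on neoadjuvant chemotherapy are imaged at a pre-treatment baseline
and again around week 4; changes in QUS features between the two time points
track microstructural changes associated with cell death. A practical
question is whether such features — and especially their *between-time-point
differences* — transfer across scanners, e.g. from a cart-based clinical
system to a handheld probe with coarser line density and lower sampling rate.

`qusagree` implements the full estimation chain and the agreement analysis,
plus a seeded synthetic RF generator so that every estimator can be validated
by parameter recovery and the cross-scanner phenomenon can be reproduced at
desk scale.

## The estimation chain

### Blocks and spectra

A polygonal tumor ROI is tiled into square analysis blocks 2 mm on a side
(about ten wavelengths at the pulse center frequency) on a regular grid with
80% linear overlap along both axes (step 0.2 × block). A block is kept if its
center falls inside the polygon. At 40 MHz sampling and the conventional
1540 m/s sound speed a 2 mm block is 104 RF samples; at 30 MHz it is 78.

Per block, each RF line segment is de-meaned, tapered with a symmetric Hann
window (`w(n) = 0.5(1 − cos(2πn/(N−1)))`; for N = 104 the at-or-above-half-
maximum span is 51 sample intervals), zero-padded to the next power of two,
Fourier transformed, squared, and averaged across the block's lines. Spectra
are interpolated (linearly in log power) onto a fixed 0.05 MHz grid so the
two scanners share frequency bins; cross-system work uses the intersection of
the two −6 dB bands, 5.1–8 MHz.

### Reference-phantom normalization

Each block spectrum is divided by the depth-matched mean spectrum of a
homogeneous tissue-mimicking phantom with known properties (attenuation
0.7861 dB·cm⁻¹·MHz⁻¹, sound speed 1488 m/s, tabulated backscatter spectrum
σ_r(f)), acquired with the same scanner and window settings. Any
frequency-smooth multiplicative system response applied to both sample and
reference cancels exactly; this is the mechanism that makes QUS features
comparable across hardware. The reference table steps finely in depth
(sample blocks are matched to the nearest bin within 1 mm) but tiles
laterally without overlap, which carries the same statistical information as
an overlapped lateral tiling at a fraction of the cost.

### Attenuation estimation and compensation

Attenuation coefficients are quoted in the clinical one-way convention,
dB·cm⁻¹·MHz⁻¹. All round-trip algebra uses the equivalent Np amplitude form
`e^{4·κ·α·f·z}` with κ = ln(10)/20, i.e. a round-trip *power* change of
exactly `2·α·f·z` dB; the package fixes this constant once (`kappa_db_np`)
and unit-tests it, because mixing the dB and Np conventions silently is the
classic failure mode of spectral-difference code. Under this convention the
depth slope of the normalized log spectrum is `−2(α_s − α_r)·f` dB/cm, and
the local (intra-tumor) estimate is

1. average the per-block 10·log₁₀ normalized power over all blocks at the
   same depth,
2. regress against depth per frequency (OLS) to get slopes `b(f)`,
3. `α_m(f) = α_r − b(f)/(2f)`, averaged over the band.

This self-consistently recovers the phantom's own coefficient when the
sample *is* the phantom (a fixed-point test in the suite). Estimates need at
least four depth rows with two blocks each and must land in a plausibility
gate of [0.2, 2.5] dB·cm⁻¹·MHz⁻¹; otherwise the assumed breast-tissue value
of 1 dB·cm⁻¹·MHz⁻¹ is used and flagged. Intervening tissue between the
transducer and the tumor interface is always assigned that literature value
(α_i = 1). Point compensation multiplies each normalized spectrum by
`exp(4κf(α_m z_m + α_i z_i − α_r z))`, where `z_i` is the depth of the ROI
entry on the block's central scan line, `z_m` the block-center depth below
it, and `z = z_i + z_m`.

### Spectral and backscatter features

On the compensated log spectrum over 5.1–8 MHz, ordinary least squares gives
the spectral slope (SS, dB/MHz), the spectral intercept (SI, dB, extrapolated
to 0 MHz) and the mid-band fit (MBF, dB, the fitted value at 6.55 MHz);
`MBF = SS·f_mid + SI` holds identically.

The sample backscatter coefficient is
`σ_s(f) = (W_s/W_r)·σ_r(f)·exp(4κf(α_m z_m + α_i z_i − α_r z))`;
stage bookkeeping (`raw → normalized → compensated`) guarantees the
attenuation exponent is applied exactly once. σ_s is fitted to the Gaussian
form-factor model

σ_theory(f) = π⁴/(36 c⁴) · f⁴ · a_eff⁶ · n̄γ₀² · exp(−0.827·(2πf·a_eff/c)²)

with c = 1540 m/s, by sweeping the effective radius a_eff over 1–150 μm in
0.25 μm steps. The fit is least squares on the dB scale, where the optimal
concentration for each candidate radius is a closed-form mean dB offset.
Reported features are the average scatterer *diameter* ASD = 2·a_eff (μm) —
the radius-vs-diameter convention is stated explicitly because the two are
conflated in parts of the literature — and the average acoustic
concentration AAC = 10·log₁₀(n̄γ₀²) in dB re 1 cm⁻³. The squared argument in
the form factor is the dimensionally consistent Gaussian form; sweep minima
on the grid boundary are flagged unreliable and excluded from aggregation.
Patient-level estimates average blocks within a frame, then frames (frames
weighted equally).

### Parametric maps and texture

Each of the five primary features is rendered as a parametric map by
averaging, at every pixel, the estimates of all overlapping blocks covering
that pixel. Maps live on an isotropic grid with pixel = tiling step
(0.4 mm): RF-sample grids are strongly anisotropic (≈20 μm axially vs
hundreds of μm laterally), and GLCM offsets of 1–4 pixels are only
meaningful if a pixel is commensurate with the estimate spacing. Per map,
valid pixels (inside the ROI and covered by at least one block) are
quantized to 16 gray levels over the per-map min–max range (the level map is
invariant under positive affine transforms, so flat gains cannot move
texture features), and 16 gray-level co-occurrence matrices are built: four
angles (0°, 45°, 90°, 135°; 0° = lateral, 90° = axial) × four step sizes
(1–4 pixels), counted symmetrically and normalized. Contrast, correlation,
energy and homogeneity (Σ p/(1+|i−j|)) are computed from each GLCM with
means/SDs from the marginals, then averaged over the 16 configurations.
Pairs crossing the validity boundary are excluded entirely; degenerate
correlations (σ = 0) propagate as missing. Five maps × four statistics plus
the five primary features give the 25-entry feature vector.

### Agreement analysis

For the three feature sets — baseline, week 4, and differences
(week4 − baseline) — each feature is compared across the two systems with
the paired two-sided Wilcoxon signed-rank test (zero differences dropped,
mid-ranks for ties, exact null for tie-free n ≤ 25, otherwise the corrected
normal approximation; `stats::wilcox.test` supplies the distribution and a
full 2ⁿ sign-flip enumeration is the test-suite oracle). Flags are raw
p < 0.05 per feature with no multiplicity adjustment, matching the reporting
convention of the clinical tables; an adjusted variant would be a one-line
change but defaults off. Bland–Altman summaries (mean difference ± 1.96 SD
limits, n−1 denominator) accompany every comparison. The difference
direction is fixed as week4 − baseline and cross-system differences as
first − second system; both are recorded in the report metadata.

## The synthetic data generator

The generator is phenomenological, not a wave solver: the downstream chain
consumes only block power spectra, so it suffices to synthesize speckle
whose expected spectrum matches a prescribed backscatter coefficient,
pulse, and attenuation. Each scan line is built in overlapping 128-sample
depth segments; within a segment the signal is Gaussian noise colored by
`sqrt(σ_truth(f)·|P(f)|²)·10^(−f·A(z)/10)`, where P is a Gaussian pulse
spanning the scanner's −6 dB band and A(z) is the cumulative one-way
attenuation path integral (piecewise through background and tumor along each
line). Segments are Hann-windowed and overlap-added at a quarter-window hop,
making the summed window *power* constant with depth — no seams, and the
constant cancels in normalization. Fixed seeds give bit-identical frames;
every stochastic object (frame, cohort, reference set) derives its seed from
one master seed.

Virtual scanners mirror the published device table: a cart-like system
(6.3 MHz center, 3–8 MHz band, 40 MHz sampling, dense lines) and a
handheld-like system (6.9 MHz, 5.1–8.3 MHz, 30 MHz, sparse lines). The
transducer tables give no aperture width; both scanners are assigned a 38 mm
aperture (configurable, recorded in every sidecar), so line pitch is
aperture/n_lines. Default problem sizes are desk-scale: 192 × 1024 and
144 × 768 frames at the true sampling rates. Line counts were chosen so a
2 mm block spans ≈8–10 RF lines, matching the per-block line counts of the
real systems: block-level dB-spectrum fits carry a noise-dependent upward
scatterer-size bias, and unrealistically sparse lines would inflate it.

The cohort generator emulates the study structure: 30 patients by default
(28/30 responders), elliptical tumors at ~10.5 mm depth with major axes
9–14 mm, four frames per (system, time point), and week-4 linear shrink
factor 0.71 ± 0.05 in responders (about half the area, the magnitude
suggested by the published ROI-size table). Week-4 microstructural shifts
(+15% effective radius, +3 dB concentration, +0.15 dB·cm⁻¹·MHz⁻¹) are
synthetic effect sizes, not biological claims — the source study does not
quantify them. Inter-scanner nuisance has two parts: a *cancelling* smooth
transfer function applied to both sample and reference frames of a scanner
(removed exactly by normalization) and a *non-cancelling* residual (4 dB
flat + 1.5 dB ripple) applied to the handheld system's sample frames only,
modeling imperfect normalization. The residual is constant across time
points, so it shifts absolute features but cancels in week4 − baseline
differences — the study's central phenomenon.

What the generator does *not* emulate: beam diffraction and elevational
focusing, nonlinear propagation, electronic noise floors, motion, and
anatomical heterogeneity of real breast tissue. Passing recovery tests
therefore validates the estimator algebra and its statistical behavior under
speckle, not clinical accuracy.

## Numerical choices and degenerate inputs

- FFT length: next power of two above the block length; spectra interpolated
  in log power onto a 0.05 MHz grid (scanner-independent bins).
- Depth matching tolerance for normalization: nearest reference bin within
  1 mm, otherwise an error naming the depth.
- Compensation exponents beyond e^±20 abort with the offending block named
  (they indicate inconsistent geometry, not data).
- ASD sweep ties break toward the smallest radius; boundary minima are
  flagged, excluded from frame averages, and a frame whose blocks are all
  unreliable yields missing ASD/AAC (and missing texture for those maps) —
  never silent zeros.
- Constant parametric maps are degenerate: all levels 0, correlation
  missing, excluded from config averaging.
- Wilcoxon with fewer than 6 non-zero differences is flagged unreliable;
  all-zero differences give p = 1 with n_effective = 0.
- Indexing is 1-based inclusive throughout the R interfaces.

## Validation design

Estimators are validated by recovery of known ground truth through the full
RF chain, at problem sizes chosen to keep the complete suite within a few
minutes of CPU time: local attenuation α = 1.0 recovered within ±0.15
dB·cm⁻¹·MHz⁻¹ against the 0.7861 phantom from ten frames of a deep ROI;
ASD grid-exact on noiseless forward-model input and within ±15% in the
median over 30 synthetic patients through the full pipeline; AAC exactly
+10 dB under a ×10 BSC scaling; phantom-vs-itself normalization flat at
0 ± 0.3 dB with MBF and SS near zero. GLCM statistics, exact Wilcoxon
p-values and Bland–Altman limits are checked against brute-force oracles
(direct pair enumeration, full 2ⁿ sign-flip enumeration, the closed form).

The cross-scanner experiment is run twice. With *identical* virtual
scanners plus the non-cancelling residual, every difference-set comparison
is null by construction, and agreement holds for ≥95% of features while the
gain-sensitive absolute features (MBF, SI, AAC) disagree — the isolated
mechanism. With the full published scanner contrast (different line
densities and sampling rates), all five primary feature differences agree
and differences agree more often than baselines, but the GLCM *correlation*
textures retain a small genuine scanner-dependent residual: the spatial
correlation of map noise differs with line pitch and interacts with the
week-4 ROI shrink. This mirrors the clinical finding, where all five
primary feature differences agreed between systems but only 12 of 20
texture differences did.

## Known limitations

- The speckle model is fully developed and Gaussian; envelope statistics
  features (and media with few scatterers per cell) are out of scope.
- Scatterer sizing is weakly identified at small ka: on the 5.1–8 MHz band,
  effective diameters below roughly 40 μm leave almost no curvature in the
  form factor, and speckle noise then biases the dB-scale sweep upward
  (`analysis/04_parameter_recovery.R` quantifies this). Recovery is accurate
  in the 50–90 μm range the cohort generator uses.
- Single-polygon ROIs only; no donut ROIs or interactive segmentation.
- Frequency-linear attenuation only; no power-law or hybrid compensation.
- The Gaussian form factor is the only scattering model; fluid-sphere or
  shell models would slot into `theoretical_bsc()` but are not provided.
- Absolute BSC units are only as meaningful as the phantom's σ_r(f) table;
  with the synthetic phantom they are internally consistent rather than
  traceable.
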