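---
title: "Methods: structured-phantom image quality analysis for coronary CT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured-phantom image quality analysis for coronary CT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nonlinear CT reconstructions — hybrid iterative reconstruction (HIR),
deep-learning reconstruction (DLR) and super-resolution DLR (SR-DLR) — have
image-quality characteristics that depend on the object being scanned, so
wires, beads and uniform cylinders do not predict their clinical behavior.
The remedy is a *structured* phantom that imitates the anatomy of a
contrast-enhanced cardiac scan, with a digital twin of known geometry acting
as ground truth. `cctaphantom` implements that analysis fully in software:

1. a **digital anthropomorphic cardiac phantom** with analytic ground truth
   (`phantom_model`),
2. an **image-domain emulator** that reproduces each reconstruction family's
   second-order statistics — PSF, noise magnitude, noise power spectrum
   shape (`recon_emulator`),
3. the **measurement stack**: ROI noise SD and 2-D noise power spectrum
   (NPS), task-based MTF in-plane and along the scanner axis, and
   profile-curve metrics of vessels and stents, all scored against the
   analytic truth.

Because the emulator replaces a scanner and two proprietary networks, the
physical scan results are *calibration targets*, not predictions: the
pipeline is judged by estimator-versus-oracle accuracy, by parameter
recovery (does a preset calibrated to SD 21.1 HU and f10 0.792 cycle/mm
measure back at those values through the full chain?), and by the
reported qualitative orderings.

## The phantom

The spec (`ccta_phantom_spec()`) describes a 30 x 20 cm thorax with hollow
lungs, a plaster-like vertebra and ribs (700 HU), a left ventricle filled
with dilute iodine contrast (18 mgI/ml) inside a myocardial shell, four
simulated coronary arteries (diameters spanning 4.0 to 1.0 mm) running
axially through the myocardium at 38.5 mm from the heart axis, a 70%
stenosis, a stent, and an iodine wedge whose top face is a plane inclined
30 degrees to the axial plane (the axial-resolution edge). The contrast HU
is fixed at 424 — the value obtained by averaging ROI readings of the three
emulated reconstructions (`model_vessel_ct()`), mirroring how the digital
model's CT number is anchored to measurements.

Material choices that were genuinely open:

* **Myocardium = 0 HU (water-equivalent).** The profile metric W_10% uses a
  threshold of 10% of the model peak, about 42 HU. A 40 HU background would
  sit 2 HU below that threshold and make the width reading ill-posed under
  noise; the published widths (stenosis W_10% near 1.8 mm rather than many
  mm) are only consistent with a background well below the threshold.
  Soft tissue elsewhere remains 40 HU.
* **Stenosis host vessel = the 1.6 mm branch.** "70% stenosis" is read as a
  diameter reduction, so the residual lumen is `0.3 x 1.6 = 0.48 mm`. This
  reproduces the published model widths at the lesion (W_90% 0.32 mm,
  W_10% 0.78 mm; this phantom: 0.24 and 0.84 mm) far better than a 70%
  lesion on the 3.2 mm vessel would (residual 0.96 mm, W_90% near 0.9 mm).
  The normal-vessel site is the 3.2 mm vessel, whose model W_10% of 3.59 mm
  matches the published model column exactly.
* **Stent = continuous thin shell, 0.17 mm x 3200 HU, on the 2.5 mm
  vessel.** Real stent struts are sub-resolution metal wires; what the image
  sees is their blooming. A shell in the dense-strut limit with effective
  metal HU reproduces the reported lumen-width behavior — the 110%-threshold
  lumen fully bloomed shut for HIR, narrow for DLR, widest for SR-DLR —
  with comfortable noise margins (verified across seeds). Discrete rings are
  available (`rings =` in `stent_spec()`) but rings thin enough to be
  literal are averaged away by the axial PSF and produce no blooming at all.
  The lumen reference W_truth is the full width at half maximum of the
  stent-free model profile; a literal 110% threshold is undefined on a
  profile whose maximum *is* the reference peak.

### Voxelization

Volumes are painted by material priority (stent > vessel lumen >
ventricle/myocardium > wedge > bone > soft tissue > lung/air) with sub-voxel
antialiasing: each painter evaluates an (approximate) signed distance to its
surface and assigns boundary coverage `clamp(0.5 - d/w)`, with `w` the voxel
footprint along the surface normal. For the smooth surfaces used here this
is equivalent to supersampled occupancy mixing — the tests verify rasterized
tube volumes against a 5x supersampled point-in-solid oracle to within 1% —
at a fraction of the cost. Interior voxels of a pure material carry exactly
its HU (424 at the ventricle center), which the tests assert.

## The reconstruction emulator

`recon_preset()` captures a family by `(sigma_xy, sigma_z)` of a separable
Gaussian PSF, a target ROI noise SD, an NPS shape tag and the output grid.
The pipeline is Gaussian blur, trilinear resampling onto the output grid
(0.3125 mm pixels for HIR/DLR, 0.15625 mm for SR-DLR, 0.25 mm slice
interval), and addition of a correlated noise field synthesized by filtering
white Gaussian noise per slice with the square root of the target NPS shape
and rescaling to the target SD. Repeat scans are fresh noise realizations
with seeds `seed, seed + 1, seed + 2`. Assumptions, stated plainly:

* image-domain only — no projection physics, no beam hardening, no network
  inference; DLR texture beyond second-order statistics is out of scope;
* noise is stationary across the (heart-sized) measured region and
  independent between slices (the analysis is slice-wise 2-D);
* the 0.5 mm slice sensitivity profile is not modeled as an explicit box —
  the calibrated `sigma_z` absorbs it (the PSF family is fixed to
  Gaussians);
* HIR and DLR noise is low-frequency weighted (`ramp-lowpass` shape,
  `f S(f) = f exp(-(f/f0)^2)` peaking at 0.15 cycle/mm); SR-DLR noise is
  white, matching the reported near-flat spectrum. The published curves
  constrain these shapes only qualitatively; the peak frequency is a
  calibration knob, not a claim.

### Calibration

The closed-form Gaussian relation `sigma = sqrt(ln 10 / (2 pi^2 f10^2))`
seeds each preset from its measured f10 target (XY: 0.792 / 0.976 / 1.379;
Z: 0.849 / 0.890 / 1.020 cycle/mm). `calibrate_presets()` then refines
`sigma_xy` on a synthetic in-plane edge and `sigma_z` on a 30-degree slanted
edge, measuring f10 through the *actual* emulate-ESF-MTF chain and updating
in quadrature until the measured value matches the target (default 0.5%).
This absorbs the apertures the closed form ignores: rasterization coverage
(~one model voxel), trilinear resampling (~one output pixel) and ESF
binning. Noise SD needs no calibration: the synthesized field's sample SD is
rescaled exactly, and noise is added after the blur stage.

## Measurements

**ROI SD and CT number** (`roi_sd`): per-slice standard deviation inside a
40 x 40 x 25 mm box centered in the ventricle, averaged over slices; the
mean HU is the CT-number reading.

**NPS** (`estimate_nps`): per slice, ROI pixels are detrended (default: a
least-squares second-order 2-D polynomial per slice, the TG-233 practice;
optionally the repeat-ensemble mean with the `n/(n-1)` correction), DFT'd,
normalized to HU^2 mm^2, averaged over slices and repeats, and radially
binned in annuli one frequency sample wide. No window is applied; the
spectrum is reported from `1/(ROI extent)` = 0.025 cycle/mm upward, the
cutoff imposed by the ROI size. The variance integral equals the detrended
variance by Parseval, which the tests assert to 2%.

**Task-based MTF** (`extract_esf`, `esf_to_mtf`): voxel centers in a band
around an analytic boundary are projected to signed distance — the in-plane
distance to the per-slice circular arc of the ventricle for XY, the normal
distance to the wedge plane for Z. The 30-degree tilt converts the 0.25 mm
slice interval into 0.125 mm effective sampling along the normal. Samples
are averaged in quarter-voxel bins; the LSF is the central difference of the
binned ESF, Hann-windowed about its peak, Fourier transformed, corrected for
the finite-difference and binning apertures, and normalized at zero
frequency. ESFs from the three repeat scans are averaged before
differentiation. Numerical choices worth recording:

* **Window length 16x the LSF FWHM** (not 8x): the shorter window's spectral
  curvature biases f10 upward by 2-3%, which would consume the whole
  estimator-accuracy budget; at 16x the residual bias is below 1%.
* Synthetic validation edges are tilted ~7 degrees in-plane: an exactly
  axis-aligned plane populates only every fourth quarter-pitch bin and the
  bin-fill interpolation then acts as an extra voxel-wide aperture. The
  phantom's own edges (circular arc, slanted wedge) sample distance densely
  by construction.
* The XY band keeps an azimuth sector (150-230 degrees by default) that
  avoids the simulated vessels embedded near the ventricle wall.
* `freq_at_fraction` takes the *first* downward crossing, linearly
  interpolated; an MTF that never reaches the fraction is an error that
  reports the last value rather than a fabricated number.

**Profile metrics** (`extract_profile`, `width_at_threshold`,
`measure_vessel_profile`, `measure_stent_lumen`): HU is sampled by trilinear
interpolation along the line through the centerline orthogonal to the local
tangent (default direction: tangential, i.e. `tangent x radial`, which keeps
the line inside the myocardium), at quarter-pixel pitch with extent at least
four local diameters. The peak CT number is the profile maximum (robust to
sub-voxel centerline offset). Widths at 90%/10% of the *model* peak
interpolate both crossings linearly and report 0 when the peak never reaches
the threshold — the expected reading for the stenosis at 90%. Percent errors
are computed from unrounded values and rounded last (half away from zero, one
decimal), because the published error cells do not all back-compute from the
rounded widths. Profiles are averaged over the three repeats; axially uniform
sites (normal vessel, stent) additionally average over a short arc-length
window (1-2 mm), mirroring measurement on a curved planar reformation. The
stenosis site is not arc-length averaged since the diameter varies along the
lesion.

**Dose** (`effective_dose`): `DLP = CTDIvol x length(cm)`, effective dose =
`DLP x k` with k = 0.014 mSv/(mGy cm); 3.7 mGy over 160 mm gives 0.83 mSv.

## Problem sizes

The default model grid (`analysis_grid()`) is a 112.5 x 112.5 x 36 mm
sub-volume at the model sampling (0.15625 / 0.15625 / 0.25 mm; 720 x 720 x
144 voxels, ~75 M). It contains every measurement region — the ventricle ROI,
both MTF edges, all vessels and the wedge — while keeping a full experiment
(phantom build, three calibrated presets, three repeats each, all
measurements) around ten minutes on one core within a few GB of memory.
Full 160 mm FoV grids and arbitrary windows (e.g. a small patch over a rib
or lung) are built with the same painters.

## What passing tests do and do not show

The generator emulates the *structure* of a cardiac CT scene and the
*second-order statistics* of three reconstruction families. Passing the
acceptance suite shows the measurement stack is accurate against analytic
oracles and that calibrated emulation round-trips its targets through
realistic structured surroundings. It does not show anything about the
proprietary reconstructions themselves: nonlinear, locally adaptive behavior
(edge-dependent noise suppression, hallucinated texture, position-dependent
PSFs) is exactly what an image-domain Gaussian/stationary model cannot
capture, and real-scanner effects (beam hardening from plaster and iodine,
cardiac motion, tube-current modulation) are absent by design. Results on
real DICOM series additionally depend on registration to the model frame,
which this package does not provide (volumes are assumed aligned; a generic
rigid resampler is included).

## Running the reference protocol

```{r}
library(cctaphantom)
cfg <- experiment_config(seed = 1L)
report <- run_experiment(cfg, out_dir = "ctiq_out")
print(report)
```

`scripts/acceptance.R` runs the same experiment from scratch and writes the
headline numbers as JSON; see the README.
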