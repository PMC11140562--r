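# cctaphantom

Structured digital-phantom analysis of CT image quality for coronary CT
angiography (CCTA).

Nonlinear CT reconstructions — hybrid iterative reconstruction (HIR),
deep-learning reconstruction (DLR), and super-resolution DLR (SR-DLR) —
behave differently on anatomy than on the uniform phantoms traditionally
used for quality assurance, so their resolution and noise must be measured
on a *structured* phantom that imitates a contrast-enhanced cardiac scan.
`cctaphantom` implements that entire workflow digitally, for medical
physicists and image-quality researchers:

* **Digital anthropomorphic phantom** — a 30 x 20 cm thorax with hollow
  lungs, plaster-like bones, a contrast-filled left ventricle (424 HU,
  18 mgI/ml), coronary arteries of 4.0–1.0 mm diameter with a 70% stenosis,
  an implanted stent, and a 30°-slanted resolution wedge; voxelized with
  sub-voxel antialiasing and paired with its exact analytic ground truth.
* **Reconstruction emulator** — image-domain emulation of each
  reconstruction family by its second-order statistics: separable Gaussian
  PSF, target noise SD, and noise-power-spectrum shape (low-frequency
  weighted for HIR/DLR, white for SR-DLR), on the published grids
  (512 matrix / 0.31 mm pixels for HIR and DLR, 1024 / 0.16 mm for SR-DLR,
  0.5 mm slices at 0.25 mm interval), with three repeat "scans".
* **Measurements against truth** — ROI noise SD and 2-D noise power
  spectrum (NPS, HU² mm², Parseval-consistent); task-based MTF from the
  ventricle/myocardium boundary (in-plane) and a ≤30° slanted edge (axial),
  summarized by f10/f50; vessel profile curves with peak CT number, W₉₀%
  and W₁₀% threshold widths and percent errors; stent lumen width at the
  110% threshold; CTDIvol → DLP → effective-dose conversion.

The core relations: a Gaussian PSF of width σ has
`MTF(f) = exp(-2π²σ²f²)`, so the 10%-MTF frequency is
`f10 = sqrt(ln 10 / (2π²σ²))`; the NPS is the slice-wise
`|DFT|² · pixel_area / n_pixels` of detrended ROI noise, radially averaged,
whose integral over frequency equals the noise variance; profile widths are
full widths at thresholds defined as fractions of the *digital model's*
peak CT number.

## Worked example

```r
library(cctaphantom)

cfg <- experiment_config(seed = 1L)      # phantom, presets, ROI, sites, dose
report <- run_experiment(cfg, out_dir = "ctiq_out")
print(report)
```

which prints (seed 1):

```
<ctiq_report> seed 1 - 3 repeats
  HIR     SD  21.1 HU  f10(XY) 0.783  f10(Z) 0.818 cycle/mm
  DLR     SD  19.0 HU  f10(XY) 0.958  f10(Z) 0.898 cycle/mm
  SR-DLR  SD  13.1 HU  f10(XY) 1.361  f10(Z) 1.024 cycle/mm
  model CT 424 HU; effective dose 0.83 mSv
```

Reading the output: each preset was calibrated so that, after emulation of
the full structured scene, the measured ROI noise SD and task-MTF f10 land
on its configured targets (HIR 21.1 HU / 0.792 cycle/mm, DLR 19.0 / 0.976,
SR-DLR 13.1 / 1.379 in-plane). SR-DLR shows the expected behavior: lowest
noise, highest resolution in both directions, the narrowest stenosis
blurring, and the widest visible stent lumen (the HIR lumen blooms
completely shut, width 0.00 mm). `ctiq_out/` contains the profile-metric
tables (`table1_profile_metrics.csv`, `table2_stent_lumen.csv`), per-preset
NPS/MTF/profile curve CSVs, PNG plots, and `summary.json`.

A thin CLI over the same functions is installed at
`inst/cli/cctaphantom.R` (subcommands `generate-phantom`, `emulate`,
`measure-noise`, `measure-mtf`, `measure-profile`, `run-all`).

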