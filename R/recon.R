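#' Reconstruction emulation preset
#'
#' Image-domain stand-in for a reconstruction family, characterized by its
#' second-order statistics only: a separable Gaussian PSF (in-plane and axial
#' sigma, mm), a target noise magnitude (ROI SD, HU), a radially symmetric
#' noise power spectrum shape, and the output grid. No projection physics and
#' no network inference are emulated.
#'
#' @param name preset label.
#' @param sigma_xy,sigma_z Gaussian PSF standard deviations (mm, >= 0).
#' @param noise_sd_target target image-noise SD (HU, >= 0).
#' @param nps_shape `list(type = "white")` or
#'   `list(type = "ramp-lowpass", peak_freq = cycles/mm)` (low-frequency
#'   weighted, peaking at `peak_freq`).
#' @param matrix output matrix size (per 160 mm display FoV convention).
#' @param fov_mm display field of view (mm) fixing the pixel size.
#' @param slice_thickness_mm,slice_interval_mm axial sampling (mm).
#' @param targets optional list of calibration targets
#'   (`sd`, `f10_xy`, `f10_z`).
#' @return object of class `recon_preset`.
#' @export
recon_preset <- function(name, sigma_xy, sigma_z, noise_sd_target,
                         nps_shape = list(type = "white"),
                         matrix = 512, fov_mm = 160,
                         slice_thickness_mm = 0.5, slice_interval_mm = 0.25,
                         targets = NULL) {
  if (sigma_xy < 0 || sigma_z < 0) stop("PSF sigmas must be >= 0")
  if (noise_sd_target < 0) stop("noise_sd_target must be >= 0")
  if (!nps_shape$type %in% c("white", "ramp-lowpass"))
    stop("unknown NPS shape: ", nps_shape$type)
  structure(list(name = name, sigma_xy = sigma_xy, sigma_z = sigma_z,
                 noise_sd_target = noise_sd_target, nps_shape = nps_shape,
                 grid = list(matrix = as.integer(matrix), fov_mm = fov_mm,
                             pixel_mm = fov_mm / matrix,
                             slice_thickness_mm = slice_thickness_mm,
                             slice_interval_mm = slice_interval_mm),
                 targets = targets),
            class = "recon_preset")
}

#' @method print recon_preset
#' @export
print.recon_preset <- function(x, ...) {
  cat(sprintf("<recon_preset> %s: sigma_xy %.3f mm, sigma_z %.3f mm, SD %.1f HU, NPS %s, %dx%d @ %.4f mm\n",
              x$name, x$sigma_xy, x$sigma_z, x$noise_sd_target,
              x$nps_shape$type, x$grid$matrix, x$grid$matrix, x$grid$pixel_mm))
  invisible(x)
}

# Closed form for a Gaussian PSF: MTF(f) = exp(-2 pi^2 sigma^2 f^2), so the
# sigma whose MTF reaches 10% at f10 is
sigma_for_f10 <- function(f10) sqrt(log(10) / (2 * pi^2 * f10^2))

#' Reference presets for the three reconstruction families
#'
#' HIR and DLR on a 512 matrix (0.31 mm pixels), SR-DLR on a 1024 matrix
#' (0.16 mm pixels), all with 0.5 mm slices at 0.25 mm interval over a 160 mm
#' display FoV. Noise SD targets are the measured values 21.1 / 19.0 /
#' 13.1 HU; PSF sigmas are seeded from the closed-form Gaussian relation
#' `sigma = sqrt(ln 10 / (2 pi^2 f10^2))` against the measured task-MTF
#' 10% frequencies (XY 0.792 / 0.976 / 1.379, Z 0.849 / 0.890 / 1.020
#' cycle/mm) and are meant to be refined with [calibrate_presets()], which
#' accounts for rasterization and resampling apertures. SR-DLR noise is
#' spectrally flat (white); HIR and DLR noise is low-frequency weighted.
#'
#' @return named list of three [recon_preset()]s (HIR, DLR, SR-DLR).
#' @export
reference_presets <- function() {
  mk <- function(name, sd, f10_xy, f10_z, shape, matrix) {
    s_xy <- sigma_for_f10(f10_xy)
    s_n <- sigma_for_f10(f10_z)     # edge-normal sigma on the 30-degree ramp
    th <- 30 * pi / 180
    s_z <- sqrt(max((s_n^2 - sin(th)^2 * s_xy^2) / cos(th)^2, 1e-4))
    recon_preset(name, sigma_xy = s_xy, sigma_z = s_z, noise_sd_target = sd,
                 nps_shape = shape, matrix = matrix,
                 targets = list(sd = sd, f10_xy = f10_xy, f10_z = f10_z))
  }
  list(
    HIR = mk("HIR", 21.1, 0.792, 0.849,
             list(type = "ramp-lowpass", peak_freq = 0.15), 512),
    DLR = mk("DLR", 19.0, 0.976, 0.890,
             list(type = "ramp-lowpass", peak_freq = 0.15), 512),
    `SR-DLR` = mk("SR-DLR", 13.1, 1.379, 1.020, list(type = "white"), 1024)
  )
}

# Centered DFT sample frequencies (cycle/mm), fftshift-free ordering.
fft_freq <- function(n, d) {
  (((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)) / (n * d)
}

nps_shape_value <- function(shape, f) {
  switch(shape$type,
         white = rep(1, length(f)),
         `ramp-lowpass` = {
           f0 <- shape$peak_freq * sqrt(2)
           f * exp(-(f / f0)^2)
         },
         stop("unknown NPS shape: ", shape$type))
}

#' Synthesize a correlated noise field with a target spectrum shape
#'
#' A white Gaussian field is filtered per axial slice in the frequency domain
#' by the square root of the target NPS shape, then rescaled so its sample SD
#' equals `sd_target`. Slices are mutually independent (the analysis is
#' slice-wise 2-D). Identical seeds give identical fields.
#'
#' @param dim integer length-3 field dimensions.
#' @param spacing voxel spacing (mm).
#' @param nps_shape as in [recon_preset()].
#' @param sd_target sample standard deviation (HU).
#' @param seed integer RNG seed.
#' @return a `voxel_volume` (origin 0) of zero-mean noise.
#' @export
synthesize_noise_field <- function(dim, spacing, nps_shape, sd_target, seed) {
  dim <- as.integer(dim)
  if (sd_target < 0) stop("sd_target must be >= 0")
  if (sd_target == 0)
    return(voxel_volume(array(0, dim), spacing))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  arr <- array(stats::rnorm(prod(dim)), dim)
  if (nps_shape$type != "white") {
    fx <- fft_freq(dim[1], spacing[1])
    fy <- fft_freq(dim[2], spacing[2])
    fr <- sqrt(outer(fx^2, fy^2, "+"))
    A <- sqrt(pmax(nps_shape_value(nps_shape, as.numeric(fr)), 0))
    dim(A) <- c(dim[1], dim[2])
    if (all(A == 0))
      stop("all-zero NPS shape cannot carry a positive noise SD")
    n2 <- dim[1] * dim[2]
    for (k in seq_len(dim[3])) {
      F2 <- stats::fft(arr[, , k]) * A
      arr[, , k] <- Re(stats::fft(F2, inverse = TRUE)) / n2
    }
  }
  arr <- arr - mean(arr)
  arr <- arr * (sd_target / stats::sd(arr))
  voxel_volume(arr, spacing)
}

# Output grid of a preset covering the physical extent of the model grid.
preset_output_grid <- function(preset, model_grid) {
  sp_out <- c(preset$grid$pixel_mm, preset$grid$pixel_mm,
              preset$grid$slice_interval_mm)
  if (any(sp_out < model_grid$spacing - 1e-9))
    stop("preset output grid is finer than the model grid; supply a finer model")
  extent <- (model_grid$dim - 1) * model_grid$spacing
  n <- pmax(2L, as.integer(floor(extent / sp_out + 1e-9)) + 1L)
  center <- model_grid$origin + extent / 2
  image_grid(n, sp_out, center = center)
}

#' Deterministic emulation stage: PSF blur and grid resampling
#'
#' @param model phantom `voxel_volume` on the fine model grid.
#' @param preset a [recon_preset()].
#' @return noise-free `voxel_volume` on the preset output grid.
#' @export
emulate_deterministic <- function(model, preset) {
  out_grid <- preset_output_grid(preset, vol_grid(model))
  blurred <- gaussian_blur(model, preset$sigma_xy, preset$sigma_z)
  resample_to_grid(blurred, out_grid)
}

#' Add a preset's noise realization to a deterministic emulation
#' @param det noise-free emulated `voxel_volume`.
#' @param preset a [recon_preset()].
#' @param seed integer RNG seed.
#' @return noisy `voxel_volume`.
#' @export
add_preset_noise <- function(det, preset, seed) {
  noise <- synthesize_noise_field(dim(det$values), det$spacing,
                                  preset$nps_shape, preset$noise_sd_target,
                                  seed)
  voxel_volume(det$values + noise$values, det$spacing, det$origin)
}

#' Emulate one reconstructed scan of the phantom
#'
#' Pipeline: Gaussian PSF blur (in-plane and axial) -> resample to the
#' preset's output grid -> add a correlated noise field scaled to the
#' preset's noise SD. Identical inputs and seed give bit-identical output;
#' zero blur, zero noise and a matching grid return the input unchanged.
#'
#' @param model phantom `voxel_volume` (must be at least as fine as the
#'   preset output grid).
#' @param preset a [recon_preset()].
#' @param seed integer RNG seed for the noise stage.
#' @return emulated `voxel_volume`.
#' @export
emulate_reconstruction <- function(model, preset, seed) {
  det <- emulate_deterministic(model, preset)
  if (preset$noise_sd_target == 0) return(det)
  add_preset_noise(det, preset, seed)
}

#' Synthetic edge volume
#'
#' A half-space edge between two materials, rasterized either with the same
#' linear-coverage antialiasing as the phantom painters (`profile = "ramp"`)
#' or as an analytic Gaussian-blurred edge (`profile = "gauss"`, exact
#' samples of `lo + (hi - lo) * Phi(-d / sigma)`). The latter has a
#' closed-form MTF and serves as the estimator oracle.
#'
#' @param grid an [image_grid()].
#' @param normal unit edge normal (points toward the `lo` side).
#' @param point a point on the edge plane (mm).
#' @param contrast `c(hi, lo)` HU on the negative/positive-distance sides.
#' @param profile `"ramp"` or `"gauss"`.
#' @param sigma Gaussian edge sigma (mm) for `profile = "gauss"`.
#' @return a `voxel_volume`.
#' @export
synthetic_edge_volume <- function(grid, normal = c(1, 0, 0), point = c(0, 0, 0),
                                  contrast = c(424, 40),
                                  profile = c("ramp", "gauss"), sigma = 0.5) {
  profile <- match.arg(profile)
  normal <- normal / sqrt(sum(normal^2))
  ax <- grid_axes(grid)
  d <- outer3_sum(normal[1] * (ax[[1]] - point[1]),
                  normal[2] * (ax[[2]] - point[2]),
                  normal[3] * (ax[[3]] - point[3]))
  vals <- if (profile == "ramp") {
    w <- sqrt(sum((normal * grid$spacing)^2))
    contrast[2] + (contrast[1] - contrast[2]) * coverage(d, w)
  } else {
    contrast[2] + (contrast[1] - contrast[2]) * stats::pnorm(-d / sigma)
  }
  voxel_volume(array(vals, grid$dim), grid$spacing, grid$origin)
}

# Measure a preset's noiseless f10 on a synthetic edge through the actual
# emulation + ESF + MTF chain.
measure_edge_f10 <- function(preset, direction = c("xy", "z"),
                             model_spacing = c(0.15625, 0.15625, 0.25)) {
  direction <- match.arg(direction)
  quiet <- preset
  quiet$noise_sd_target <- 0
  if (direction == "xy") {
    # slight in-plane tilt so voxel centers sample the edge distance densely
    tilt <- 7 * pi / 180
    nrm <- c(cos(tilt), sin(tilt), 0)
    grid <- image_grid(c(round(18 / model_spacing[1]), round(16 / model_spacing[2]),
                         round(6 / model_spacing[3])),
                       model_spacing, center = c(0, 0, 0))
    vol <- synthetic_edge_volume(grid, normal = nrm)
    det <- emulate_deterministic(vol, quiet)
    edge <- plane_edge_spec(point = c(0, 0, 0), normal = nrm,
                            band = 4, contrast = c(424, 40),
                            bounds = list(y = c(-6, 6), z = c(-2, 2)),
                            direction = "XY")
  } else {
    th <- 30 * pi / 180
    grid <- image_grid(c(round(12 / model_spacing[1]), round(12 / model_spacing[2]),
                         round(16 / model_spacing[3])),
                       model_spacing, center = c(0, 0, 0))
    vol <- synthetic_edge_volume(grid, normal = c(0, -sin(th), cos(th)))
    det <- emulate_deterministic(vol, quiet)
    edge <- plane_edge_spec(point = c(0, 0, 0), normal = c(0, -sin(th), cos(th)),
                            band = 4, contrast = c(424, 40),
                            bounds = list(x = c(-4, 4), y = c(-4, 4)),
                            direction = "Z")
  }
  mtf <- esf_to_mtf(extract_esf(det, edge))
  mtf$f10
}

#' Calibrate preset PSF sigmas against their task-MTF targets
#'
#' The closed-form Gaussian sigma ignores the apertures introduced by
#' rasterization, trilinear resampling and finite ESF binning. This routine
#' measures the noiseless f10 of each preset on a synthetic edge through the
#' actual emulation and measurement chain and adjusts `sigma_xy` (in-plane
#' edge) and `sigma_z` (30-degree slanted edge, in-plane sigma held fixed) by
#' a quadrature-update fixed point until the measured f10 matches the
#' preset's target within `tol`.
#'
#' @param presets named list of [recon_preset()]s with `targets` set.
#' @param tol relative f10 tolerance (default 0.005).
#' @param max_iter maximum update iterations per sigma.
#' @param model_spacing model-grid spacing used for the calibration edges.
#' @return the presets with calibrated sigmas.
#' @export
calibrate_presets <- function(presets, tol = 0.005, max_iter = 4,
                              model_spacing = c(0.15625, 0.15625, 0.25)) {
  th <- 30 * pi / 180
  lapply(presets, function(p) {
    tgt_xy <- p$targets$f10_xy
    s_tgt <- sigma_for_f10(tgt_xy)
    for (i in seq_len(max_iter)) {
      f_meas <- measure_edge_f10(p, "xy", model_spacing)
      if (abs(f_meas / tgt_xy - 1) < tol) break
      s_eff <- sigma_for_f10(f_meas)
      extra2 <- s_eff^2 - p$sigma_xy^2
      p$sigma_xy <- sqrt(max(s_tgt^2 - extra2, 1e-4))
    }
    tgt_z <- p$targets$f10_z
    sn_tgt <- sigma_for_f10(tgt_z)
    for (i in seq_len(max_iter)) {
      f_meas <- measure_edge_f10(p, "z", model_spacing)
      if (abs(f_meas / tgt_z - 1) < tol) break
      sn_eff <- sigma_for_f10(f_meas)
      base2 <- sin(th)^2 * p$sigma_xy^2 + cos(th)^2 * p$sigma_z^2
      extra2 <- sn_eff^2 - base2
      p$sigma_z <- sqrt(max((sn_tgt^2 - extra2 - sin(th)^2 * p$sigma_xy^2) /
                              cos(th)^2, 1e-4))
    }
    p
  })
}
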