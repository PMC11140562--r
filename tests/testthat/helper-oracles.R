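# Independent oracles and shared fixtures for the test suite.

# Closed-form Gaussian-PSF MTF: the frequency at which exp(-2 pi^2 s^2 f^2)
# falls to `frac`.
gaussian_f_at <- function(sigma, frac = 0.10) {
  sqrt(log(1 / frac) / (2 * pi^2 * sigma^2))
}

# Supersampled point-in-solid occupancy oracle: fraction of `factor`^3
# sub-voxel sample points of each voxel for which `inside(x, y, z)` is TRUE.
supersample_occupancy <- function(grid, inside, factor = 5) {
  ax <- lapply(1:3, function(i)
    grid$origin[i] + (seq_len(grid$dim[i]) - 1) * grid$spacing[i])
  offs <- lapply(1:3, function(i)
    ((seq_len(factor) - 0.5) / factor - 0.5) * grid$spacing[i])
  occ <- array(0, grid$dim)
  for (ox in offs[[1]]) for (oy in offs[[2]]) for (oz in offs[[3]]) {
    m <- inside(outer(outer(ax[[1]] + ox, rep(1, grid$dim[2])),
                      rep(1, grid$dim[3])),
                outer(outer(rep(1, grid$dim[1]), ax[[2]] + oy),
                      rep(1, grid$dim[3])),
                outer(outer(rep(1, grid$dim[1]), rep(1, grid$dim[2])),
                      ax[[3]] + oz))
    occ <- occ + m
  }
  occ / factor^3
}

# Dense 1-D convolution oracle for blurred profile widths: convolve a
# rectangular lumen profile with a Gaussian on a fine grid and read the
# threshold width directly.
conv_profile_oracle <- function(width, sigma, peak = 424, background = 0,
                                pitch = 0.002, half = 8) {
  x <- seq(-half, half, by = pitch)
  v <- background + (peak - background) *
    (stats::pnorm((width / 2 - x) / sigma) - stats::pnorm((-width / 2 - x) / sigma))
  structure(list(position = x, hu = v, pitch = pitch), class = "profile_curve")
}

small_grid <- function(extent = c(10, 10, 5), spacing = c(0.25, 0.25, 0.25),
                       center = c(0, 0, 0)) {
  image_grid(round(extent / spacing), spacing, center = center)
}

# The acceptance-scale experiment is expensive; build it once per test run
# and share it across acceptance blocks.
.world <- new.env(parent = emptyenv())

acceptance_report <- function() {
  if (is.null(.world$report)) {
    cfg <- experiment_config(seed = 7L)
    .world$report <- run_experiment(cfg, verbose = FALSE)
  }
  .world$report
}

# Target radial NPS shape ("ramp-lowpass"), restated independently.
nps_shape_value_for_test <- function(shape, f) {
  f0 <- shape$peak_freq * sqrt(2)
  f * exp(-(f / f0)^2)
}
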