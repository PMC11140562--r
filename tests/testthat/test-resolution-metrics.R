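tilt <- 7 * pi / 180
nrm_xy <- c(cos(tilt), sin(tilt), 0)

edge_vol <- function(sigma, sp = c(0.15625, 0.15625, 0.25)) {
  g <- image_grid(c(round(14 / sp[1]), round(12 / sp[2]), round(4 / sp[3])),
                  sp, center = c(0, 0, 0))
  synthetic_edge_volume(g, normal = nrm_xy, profile = "gauss", sigma = sigma)
}

test_that("a hard step edge yields a step ESF", {
  g <- image_grid(c(60, 60, 8), c(0.2, 0.2, 0.25), center = c(0, 0, 0))
  v <- synthetic_edge_volume(g, normal = nrm_xy, profile = "ramp")
  esf <- extract_esf(v, plane_edge_spec(c(0, 0, 0), nrm_xy, band = 3,
                                        direction = "XY"))
  expect_true(all(esf$hu[esf$distance < -0.5] > 423))
  expect_true(all(esf$hu[esf$distance > 0.5] < 41))
})

test_that("Gaussian edge recovers the closed-form f10 and f50", {
  v <- edge_vol(0.5)
  edge <- plane_edge_spec(c(0, 0, 0), nrm_xy, band = 4,
                          bounds = list(y = c(-4.5, 4.5)), direction = "XY")
  m <- esf_to_mtf(extract_esf(v, edge))
  expect_equal(m$f10, 0.683, tolerance = 0.02)
  expect_equal(m$f50, gaussian_f_at(0.5, 0.5), tolerance = 0.02)
  expect_identical(m$direction, "XY")
})

test_that("MTF is invariant to the edge contrast scale", {
  v <- edge_vol(0.4)
  edge <- plane_edge_spec(c(0, 0, 0), nrm_xy, band = 3.5,
                          bounds = list(y = c(-4.5, 4.5)), direction = "XY")
  m1 <- esf_to_mtf(extract_esf(v, edge))
  v2 <- voxel_volume((v$values - 40) * 5 + 40, v$spacing, v$origin)
  m2 <- esf_to_mtf(extract_esf(v2, edge))
  expect_equal(m2$mtf, m1$mtf, tolerance = 1e-9)
})

test_that("circular-arc ESF matches a dense radial line profile", {
  # a blurred disc: the arc-projected ESF equals a 1-D profile through the
  # center (oracle: dense radial sampling along a diameter)
  sp <- c(0.2, 0.2, 0.25)
  g <- image_grid(c(160, 160, 10), sp, center = c(0, 0, 0))
  ax <- lapply(1:3, function(i) g$origin[i] + (seq_len(g$dim[i]) - 1) * sp[i])
  R <- 10; sigma <- 0.5
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
  sl <- 40 + 384 * stats::pnorm((R - sqrt(r2)) / sigma)
  v <- voxel_volume(array(rep(sl, g$dim[3]), g$dim), sp, g$origin)
  truth_like <- structure(list(
    ventricle = list(center = c(0, 0, 0), semi = c(R, R, 1e6)),
    xy_edge = list(contrast = c(424, 40))), class = "phantom_truth")
  esf <- extract_esf(v, xy_edge_spec(truth_like, band = 3,
                                     z_range = c(-1, 1),
                                     azimuth_deg = c(0, 360)))
  d_line <- seq(-2.5, 2.5, by = 0.05)
  oracle <- 40 + 384 * stats::pnorm(-d_line / sigma)
  interp <- stats::approx(esf$distance, esf$hu, xout = d_line)$y
  expect_lt(max(abs(interp - oracle)), 0.02 * 384)
})

test_that("the slanted edge oversamples the slice direction", {
  # plane at 30 degrees: 0.25 mm slices project to 0.125 mm along the
  # normal, so quarter-pitch distance bins are densely populated
  th <- 30 * pi / 180
  expect_equal(0.25 * sin(th), 0.125)
  sp <- c(0.15625, 0.15625, 0.25)
  g <- image_grid(c(64, 64, 48), sp, center = c(0, 0, 0))
  v <- synthetic_edge_volume(g, normal = c(0, -sin(th), cos(th)),
                             profile = "gauss", sigma = 0.4)
  esf <- extract_esf(v, plane_edge_spec(c(0, 0, 0), c(0, -sin(th), cos(th)),
                                        band = 3, direction = "Z",
                                        bounds = list(x = c(-3, 3),
                                                      y = c(-3, 3))))
  expect_gt(mean(esf$n > 0), 0.95)
  m <- esf_to_mtf(esf)
  expect_equal(m$f10, gaussian_f_at(0.4), tolerance = 0.02)
  expect_identical(m$direction, "Z")
})

test_that("freq_at_fraction interpolates crossings linearly", {
  m <- list(freq = c(0, 0.8, 0.9), mtf = c(1, 0.12, 0.08))
  expect_equal(freq_at_fraction(m, 0.10), 0.85)
  expect_equal(freq_at_fraction(list(freq = c(0, 1), mtf = c(1, 0.5)), 1), 0)
  expect_error(freq_at_fraction(list(freq = c(0, 1), mtf = c(1, 0.9)), 0.10),
               "never falls")
  expect_error(freq_at_fraction(m, 0), "fraction")
})

test_that("degenerate ESF inputs are rejected", {
  v <- edge_vol(0.4)
  # single-material band
  off_edge <- plane_edge_spec(c(5, 0, 0), nrm_xy, band = 0.8,
                              direction = "XY")
  expect_error(extract_esf(v, off_edge), "single material")
  short_esf <- structure(list(hu = c(1, 2, 3), pitch = 0.1, direction = "XY"),
                         class = "esf_curve")
  expect_error(esf_to_mtf(short_esf), "at least 8 bins")
})

test_that("averaging repeat ESFs reduces noise before differentiation", {
  v <- edge_vol(0.5)
  p <- recon_preset("n", 0, 0, 18, matrix = 1024, fov_mm = 160)
  edge <- plane_edge_spec(c(0, 0, 0), nrm_xy, band = 4,
                          bounds = list(y = c(-4.5, 4.5)), direction = "XY")
  esfs <- lapply(1:3, function(r)
    extract_esf(add_preset_noise(v, p, 30 + r), edge))
  avg <- average_esfs(esfs)
  resid_one <- stats::sd(esfs[[1]]$hu - extract_esf(v, edge)$hu)
  resid_avg <- stats::sd(avg$hu - extract_esf(v, edge)$hu)
  expect_lt(resid_avg, resid_one)
})
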