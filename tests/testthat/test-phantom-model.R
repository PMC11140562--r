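spec <- ccta_phantom_spec()

test_that("pure-material regions carry a single exact HU value", {
  g <- image_grid(c(64, 64, 24), c(0.25, 0.25, 0.25), center = c(0, 0, 0))
  b <- build_digital_phantom(spec, g, with_stent = FALSE)
  # ventricle interior: exactly the contrast value
  inner <- crop_volume(b$volume, c(-6, -6, -2), c(6, 6, 2))
  expect_true(all(inner$values == 424))
  expect_equal(sample_trilinear(b$volume, matrix(c(0, 0, 0), 1)), 424)
})

test_that("lung region is hollow (air) and bone reads the plaster value", {
  g_lung <- image_grid(c(32, 32, 8), c(0.5, 0.5, 0.5), center = c(95, 0, 0))
  b <- build_digital_phantom(spec, g_lung, with_stent = FALSE)
  ctr <- crop_volume(b$volume, c(91, -4, -1), c(99, 4, 1))
  expect_true(all(ctr$values == -1000))

  g_bone <- image_grid(c(32, 32, 8), c(0.5, 0.5, 0.5), center = c(0, -75, 0))
  b2 <- build_digital_phantom(spec, g_bone, with_stent = FALSE)
  ctr2 <- crop_volume(b2$volume, c(-4, -79, -1), c(4, -71, 1))
  expect_true(all(ctr2$values == 700))
})

test_that("rasterized tube occupancy matches the supersampled oracle", {
  # 4.0 mm straight vessel on a 0.16 mm grid: per-slice lumen area ~ pi r^2
  g <- image_grid(c(40, 40, 6), c(0.16, 0.16, 0.25), center = c(0, 0, 0))
  occ <- rasterize_tube(rbind(c(0, 0, -2), c(0, 0, 2)), 4.0, g)
  per_slice <- apply(occ$values, 3, sum)
  analytic <- pi * 2^2 / (0.16^2)
  expect_lt(max(abs(per_slice[2:5] / analytic - 1)), 0.01)

  oracle <- supersample_occupancy(g, function(x, y, z) x^2 + y^2 < 2^2)
  expect_lt(abs(sum(occ$values[, , 3]) / sum(oracle[, , 3]) - 1), 0.01)
})

test_that("tapered tube cross-sections match the analytic cone within 1%", {
  g <- image_grid(c(50, 50, 44), c(0.16, 0.16, 0.25), center = c(0, 0, 0))
  # diameters 4 -> 1 mm over 10 mm: per-slice area pi r(z)^2, r linear in z
  occ <- rasterize_tube(rbind(c(0, 0, -5), c(0, 0, 5)), c(4, 1), g)
  z <- vol_axes(occ)[[3]]
  # interior slab away from the end faces and from sub-voxel radii, where
  # the linear-coverage area bias (~ pi w^2 / 12) would dominate
  inside <- which(z > -4.9 & z < 3.2)
  area_meas <- apply(occ$values[, , inside], 3, sum) * prod(g$spacing[1:2])
  r <- 1.25 - 0.15 * z[inside]
  expect_lt(max(abs(area_meas / (pi * r^2) - 1)), 0.01)
  # integrated slab volume against the exact frustum integral (slice sums
  # are a midpoint rule over half-slice-extended bounds)
  r_lo <- 1.25 - 0.15 * (max(z[inside]) + g$spacing[3] / 2)
  r_hi <- 1.25 - 0.15 * (min(z[inside]) - g$spacing[3] / 2)
  v_true <- pi / 0.45 * (r_hi^3 - r_lo^3)
  v_meas <- sum(area_meas) * g$spacing[3]
  expect_lt(abs(v_meas / v_true - 1), 0.01)
})

test_that("stenosis reduces the true diameter to exactly 30% at its center", {
  truth <- phantom_truth(spec)
  expect_equal(vessel_true_diameter(truth, "stenotic_1.6", 12), 0.3 * 1.6)
  # reference diameter recovered away from the lesion
  expect_equal(vessel_true_diameter(truth, "stenotic_1.6", 2), 1.6)
  # smooth taper: monotone into the throat
  d <- vessel_true_diameter(truth, "stenotic_1.6", seq(9, 12, by = 0.5))
  expect_true(all(diff(d) < 0))
})

test_that("invalid geometry is rejected with informative errors", {
  g_coarse <- image_grid(c(40, 40, 8), c(0.6, 0.6, 0.5), center = c(0, 0, 0))
  expect_error(build_digital_phantom(spec, g_coarse), "too coarse")
  expect_error(vessel_spec("v", rbind(c(0, 0, 0), c(0, 0, 0)), 2),
               "strictly increasing")
  expect_error(vessel_spec("v", rbind(c(0, 0, 0), c(0, 0, 5)), 0.5),
               "\\[1.0, 4.0\\]")
  runaway <- vessel_spec("runaway", rbind(c(0, 0, 0), c(200, 0, 0)), 2)
  expect_error(ccta_phantom_spec(vessels = list(runaway),
                                 include_stent = FALSE), "runaway")
  expect_error(stent_spec("v", 5, 5), "empty")
})

test_that("the stent paints a high-attenuation shell around the lumen", {
  g <- image_grid(c(90, 90, 16), c(0.16, 0.16, 0.25),
                  center = c(38.5 * cos(240 * pi / 180),
                             38.5 * sin(240 * pi / 180), 0))
  b <- build_digital_phantom(spec, g, with_stent = TRUE)
  truth <- b$truth
  pr <- extract_profile(b$volume, truth, "stented_2.5", 9, extent = 8)
  # strut peaks flank the lumen above the contrast value
  left <- pr$hu[pr$position < -0.5 & pr$position > -2]
  right <- pr$hu[pr$position > 0.5 & pr$position < 2]
  expect_gt(max(left), 1000)
  expect_gt(max(right), 1000)
  # lumen center still reads contrast
  expect_equal(pr$hu[which.min(abs(pr$position))], 424, tolerance = 1)
})
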