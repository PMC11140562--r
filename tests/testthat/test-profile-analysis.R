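rect_profile <- function(width, peak = 424, background = 0, pitch = 0.01,
                         half = 6) {
  x <- seq(-half, half, by = pitch)
  structure(list(position = x,
                 hu = ifelse(abs(x) <= width / 2, peak, background),
                 pitch = pitch), class = "profile_curve")
}

test_that("width_at_threshold reads rectangular and sub-threshold profiles", {
  p <- rect_profile(3.2)
  for (f in c(0.1, 0.5, 0.9))
    expect_equal(width_at_threshold(p, 424, f), 3.2, tolerance = 0.011)
  # peak below the threshold: width 0 (the stenosis rows of the tables)
  low <- rect_profile(1, peak = 200)
  expect_equal(width_at_threshold(low, 424, 0.9), 0)
  expect_error(width_at_threshold(p, 0, 0.5), "positive")
})

test_that("percent errors reproduce the table arithmetic", {
  expect_equal(percent_error(409.5, 424.0), -3.4)
  expect_equal(percent_error(236.0, 423.6), -44.3)
  expect_equal(percent_error(191.9, 423.6), -54.7)
  expect_equal(percent_error(190.7, 423.6), -55.0)
  expect_equal(percent_error(5, 5), 0)
  expect_true(is.na(percent_error(1, 0)))
})

test_that("blurred-profile widths bracket the true width (convolution oracle)", {
  sig_grid <- c(0.2, 0.35, 0.5, 0.7)
  w10 <- numeric(0); w90 <- numeric(0)
  for (s in sig_grid) {
    p <- conv_profile_oracle(3.2, s)
    w90k <- width_at_threshold(p, 424, 0.90)
    w10k <- width_at_threshold(p, 424, 0.10)
    expect_lte(w90k, 3.2 + 1e-6)
    expect_gte(w10k, 3.2 - 1e-6)
    w10 <- c(w10, w10k); w90 <- c(w90, w90k)
  }
  # blur monotonicity: W10 grows, W90 shrinks
  expect_true(all(diff(w10) > 0))
  expect_true(all(diff(w90) < 0))
  # both widths collapse to 0 for a narrow lumen under heavy blur
  narrow <- conv_profile_oracle(0.48, 0.6)
  expect_equal(width_at_threshold(narrow, 424, 0.90), 0)
})

test_that("measuring the model against itself gives zero errors", {
  p <- conv_profile_oracle(3.2, 0.1)
  m <- measure_vessel_profile(p, p)
  expect_equal(m$errors$peak, 0)
  expect_equal(m$errors$w10, 0)
  expect_equal(m$errors$w90, 0)
  expect_equal(m$w10, m$model_w10)
  expect_lte(m$w90, m$w10)
})

test_that("profiles through a straight vessel are symmetric and peaked at 0", {
  spec <- ccta_phantom_spec()
  g <- image_grid(c(90, 90, 12), c(0.16, 0.16, 0.25), center = c(38.5, 0, 0))
  b <- build_digital_phantom(spec, g, with_stent = FALSE)
  pr <- extract_profile(b$volume, b$truth, "normal_3.2", 12, extent = 10)
  # the lumen plateau contains the centerline: the center sample is (at) the peak
  expect_equal(pr$hu[pr$position == 0], max(pr$hu), tolerance = 1e-6)
  flip <- rev(pr$hu)
  expect_lt(mean(abs(pr$hu - flip)), 2)
  # unblurred rasterized width equals the true diameter within a supersample
  expect_equal(width_at_threshold(pr, max(pr$hu), 0.5), 3.2,
               tolerance = 0.16 / 5)
})

test_that("CPR arc length follows the polyline chord sum", {
  spec <- ccta_phantom_spec()
  curved <- vessel_spec("curved",
                        cbind(2 * cos(seq(0, pi / 3, length.out = 12)) - 2 + 38.5,
                              2 * sin(seq(0, pi / 3, length.out = 12)),
                              seq(-6, 6, length.out = 12)),
                        2.5)
  chord <- sum(sqrt(rowSums(diff(curved$centerline)^2)))
  expect_equal(max(curved$s), chord, tolerance = 1e-9)
  g <- image_grid(c(80, 80, 56), c(0.2, 0.2, 0.25), center = c(37.5, 1, 0))
  vol <- rasterize_tube(curved$centerline, 2.5, g)
  vol$values <- 424 * vol$values
  truth_like <- structure(list(vessels = list(curved = curved),
                               spec = list(heart_center = c(0, 0, 0))),
                          class = "phantom_truth")
  cpr <- make_cpr(vol, truth_like, "curved", offset_half = 3, s_step = 1)
  expect_equal(max(cpr$s) , chord, tolerance = 1e-3 * chord)
  # straightened image: lumen stays centered along the whole vessel
  mid <- cpr$image[, abs(cpr$offset) < 0.8]
  expect_true(all(mid[2:(nrow(mid) - 1), ] > 300))
})

test_that("stent lumen width and W_truth behave like the table definitions", {
  # synthetic struts at +/- d/2 with a clean lumen between them
  x <- seq(-4, 4, by = 0.01)
  d <- 2.0
  v <- 424 + 2000 * (stats::dnorm(x, -d / 2 - 0.1, 0.15) +
                     stats::dnorm(x, d / 2 + 0.1, 0.15)) * 0.15
  prof <- structure(list(position = x, hu = v, pitch = 0.01),
                    class = "profile_curve")
  model <- rect_profile(2.5, peak = 424, pitch = 0.01, half = 4)
  res <- measure_stent_lumen(prof, model)
  thr <- 1.10 * 424
  # oracle: direct threshold crossings of the synthetic profile
  inside <- which(x > -d / 2 - 0.1 & x < d / 2 + 0.1 & v <= thr)
  expect_equal(res$w_lumen, diff(range(x[inside])), tolerance = 0.03)
  expect_equal(res$w_truth, 2.5, tolerance = 0.011)
  # fully bloomed profile: lumen 0
  v2 <- v + 200
  prof2 <- structure(list(position = x, hu = v2, pitch = 0.01),
                     class = "profile_curve")
  expect_equal(measure_stent_lumen(prof2, model)$w_lumen, 0)
  # a profile without struts is rejected
  expect_error(measure_stent_lumen(model, model), "strut")
})
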