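test_that("configs validate their labels before any computation", {
  expect_error(experiment_config(sites = list(bad = list(label = "nope",
                                                         s = 1))),
               "unknown vessel label")
  expect_error(experiment_config(repeats = 0), "repeats")
  expect_error(experiment_config(stent_site = "missing"), "stent site")
})

test_that("a toy end-to-end run writes a deterministic report bundle", {
  # coarse grid + coarse presets keep this a plumbing test, not a physics one
  spec <- ccta_phantom_spec()
  grid <- image_grid(c(232, 232, 64), c(0.5, 0.5, 0.5), center = c(0, 0, 0))
  presets <- list(
    A = recon_preset("A", 0.9, 0.9, 12, matrix = 128,
                     nps_shape = list(type = "ramp-lowpass", peak_freq = 0.1),
                     slice_interval_mm = 0.5,
                     targets = list(sd = 12, f10_xy = 0.3, f10_z = 0.3)),
    B = recon_preset("B", 0.6, 0.6, 8, matrix = 256,
                     slice_interval_mm = 0.5,
                     targets = list(sd = 8, f10_xy = 0.45, f10_z = 0.45)))
  cfg <- experiment_config(spec = spec, grid = grid, presets = presets,
                           repeats = 2, seed = 3L,
                           roi = roi_spec(c(0, 0, 0), c(30, 30, 10)),
                           calibrate = FALSE)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r1 <- run_experiment(cfg, out_dir = d1, verbose = FALSE)
  r2 <- run_experiment(cfg, out_dir = d2, verbose = FALSE)
  # same config + seed: byte-identical tables and summary
  for (f in c("table1_profile_metrics.csv", "table2_stent_lumen.csv",
              "summary.json", "log.txt")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # report carries one row per preset per metric
  t1 <- utils::read.csv(file.path(d1, "table1_profile_metrics.csv"))
  expect_true(all(c("A", "B", "Model") %in% names(t1)))
  expect_equal(nrow(t1), 3 * 2)          # 3 metrics x (normal, stenosis)
  expect_true(all(grepl("\\(-\\)$", t1$Model)))
  # curve CSVs traceable for every reported number
  expect_true(file.exists(file.path(d1, "nps_A.csv")))
  expect_true(file.exists(file.path(d1, "mtf_xy_B.csv")))
  expect_true(file.exists(file.path(d1, "profile_stenosis_A.csv")))
  expect_true(file.exists(file.path(d1, "profile_normal_model.csv")))
  # the emulated mean CT readings average back to the model contrast value
  expect_equal(r1$model_ct, 424, tolerance = 1)
})

test_that("partial results still produce headers plus a warning", {
  empty <- structure(list(presets = list(), sites = list(), seed = 0L,
                          repeats = 0L,
                          grid = image_grid(c(2, 2, 2), c(1, 1, 1)),
                          dose = effective_dose(3.7, 160, 0.014),
                          model_ct = NA),
                     class = "ctiq_report")
  d <- file.path(tempdir(), "rep_empty")
  expect_warning(write_report(empty, d), "partial results")
  expect_true(file.exists(file.path(d, "table1_profile_metrics.csv")))
})

test_that("YAML configs round-trip into runnable configurations", {
  f <- tempfile(fileext = ".yaml")
  write_default_config(f)
  cfg <- experiment_config_from_yaml(f)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$repeats, 3L)
  expect_equal(cfg$dose$ctdivol, 3.7)
  expect_equal(cfg$roi$size, c(40, 40, 25))
})

test_that("truth geometry serializes to valid JSON", {
  truth <- phantom_truth(ccta_phantom_spec())
  f <- tempfile(fileext = ".json")
  write_truth_json(truth, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$materials$contrast_hu, 424)
  expect_equal(length(back$vessels), 4)
  expect_equal(back$vessels$stenotic_1.6$stenosis$severity, 0.7)
})
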