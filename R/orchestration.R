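#' Default analysis grid for the digital model data
#'
#' The reference model-data sampling: 0.15625 mm pixels (1024 matrix over
#' a 160 mm display FoV) and 0.25 mm slice interval. The default covers a
#' 112.5 x 112.5 x 36 mm sub-volume centered on the heart, which contains
#' every measurement region (ventricle ROI, edge bands, vessels, wedge); a
#' full-FoV grid can be requested explicitly.
#'
#' @param fov_mm in-plane extent (mm) of the generated model volume.
#' @param z_extent_mm axial extent (mm).
#' @param pixel_mm in-plane model pixel size.
#' @param slice_mm model slice interval.
#' @param center world center of the grid.
#' @return an [image_grid()].
#' @export
analysis_grid <- function(fov_mm = 112.5, z_extent_mm = 36,
                          pixel_mm = 160 / 1024, slice_mm = 0.25,
                          center = c(0, 0, 0)) {
  image_grid(c(round(fov_mm / pixel_mm), round(fov_mm / pixel_mm),
               round(z_extent_mm / slice_mm)),
             c(pixel_mm, pixel_mm, slice_mm), center = center)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the phantom spec, the model
#' grid, the reconstruction presets, the number of repeat scans, the master
#' seed, the noise ROI, the profile measurement sites and the dose inputs.
#'
#' @param spec a [ccta_phantom_spec()].
#' @param grid model [image_grid()].
#' @param presets named list of [recon_preset()]s.
#' @param repeats number of repeat scans (>= 1; default protocol uses 3).
#' @param seed master RNG seed.
#' @param roi noise/CT [roi_spec()].
#' @param sites named list of profile sites, each
#'   `list(label =, s =, s_window =, extent =)`.
#' @param stent_site name of the entry in `sites` crossing the stent.
#' @param dose `list(ctdivol, scan_length_mm, k_factor)`.
#' @param calibrate run [calibrate_presets()] before emulating.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(spec = ccta_phantom_spec(),
                              grid = analysis_grid(),
                              presets = reference_presets(),
                              repeats = 3,
                              seed = 1L,
                              roi = roi_spec(c(0, 0, 0)),
                              sites = list(
                                normal = list(label = "normal_3.2", s = 12,
                                              s_window = 1, extent = 13),
                                stenosis = list(label = "stenotic_1.6", s = 12,
                                                s_window = 0, extent = 8),
                                stent = list(label = "stented_2.5", s = 9,
                                             s_window = 2, extent = 10)),
                              stent_site = "stent",
                              dose = list(ctdivol = 3.7, scan_length_mm = 160,
                                          k_factor = 0.014),
                              calibrate = TRUE) {
  if (repeats < 1) stop("repeats must be >= 1")
  for (nm in names(sites)) {
    lab <- sites[[nm]]$label
    if (is.null(spec$vessels[[lab]]))
      stop(sprintf("site '%s' references unknown vessel label '%s'", nm, lab))
  }
  if (!is.null(stent_site)) {
    if (is.null(sites[[stent_site]])) stop("unknown stent site: ", stent_site)
    if (is.null(spec$stent)) stent_site <- NULL
  }
  for (p in presets)
    if (!inherits(p, "recon_preset")) stop("presets must be recon_preset objects")
  structure(list(spec = spec, grid = grid, presets = presets,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 roi = roi, sites = sites, stent_site = stent_site,
                 dose = dose, calibrate = calibrate),
            class = "experiment_config")
}

site_profile <- function(vol, truth, site, ...) {
  extract_profile(vol, truth, site$label, site$s,
                  s_window = site$s_window %||% 0,
                  extent = site$extent, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full image-quality experiment
#'
#' Builds the digital phantom, emulates each reconstruction preset with the
#' configured number of repeat scans, and measures noise (ROI SD, NPS),
#' task-based MTF (in-plane and axial), profile-curve metrics at the normal,
#' stenotic and stented sites, and the effective dose. All measurements are
#' averaged over the repeat scans before metric extraction. Fully
#' deterministic for a fixed master seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; when given, [write_report()] is
#'   called on the results.
#' @param verbose print progress.
#' @return object of class `ctiq_report`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  presets <- config$presets
  if (config$calibrate) {
    say("calibrating presets ...")
    presets <- calibrate_presets(presets,
                                 model_spacing = config$grid$spacing)
  }
  say("building digital phantom (%d x %d x %d) ...",
      config$grid$dim[1], config$grid$dim[2], config$grid$dim[3])
  built <- build_digital_phantom(config$spec, config$grid, with_stent = FALSE)
  truth <- built$truth
  model <- built$volume

  xy_edge <- xy_edge_spec(truth)
  z_edge <- z_edge_spec(truth)
  model_profiles <- lapply(config$sites, function(st)
    site_profile(model, truth, st))
  model_mtf_xy <- esf_to_mtf(extract_esf(model, xy_edge))
  model_mtf_z <- esf_to_mtf(extract_esf(model, z_edge))
  model_roi <- roi_sd(model, config$roi)

  object_vol <- if (!is.null(config$spec$stent)) add_stent(model, config$spec)
                else model
  rm(built, model); gc(FALSE)

  per_preset <- vector("list", length(presets))
  names(per_preset) <- names(presets)
  for (pi in seq_along(presets)) {
    p <- presets[[pi]]
    say("emulating %s ...", p$name)
    det <- emulate_deterministic(object_vol, p)
    sds <- numeric(config$repeats); means <- numeric(config$repeats)
    crops <- vector("list", config$repeats)
    esfs_xy <- vector("list", config$repeats)
    esfs_z <- vector("list", config$repeats)
    profs <- lapply(config$sites, function(...) vector("list", config$repeats))
    for (r in seq_len(config$repeats)) {
      seed_r <- config$seed + 100L * (pi - 1L) + (r - 1L)
      noisy <- add_preset_noise(det, p, seed_r)
      st <- roi_sd(noisy, config$roi)
      sds[r] <- st$sd; means[r] <- st$mean_hu
      crops[[r]] <- crop_volume(noisy,
                                config$roi$center - config$roi$size / 2 - 1,
                                config$roi$center + config$roi$size / 2 + 1)
      esfs_xy[[r]] <- extract_esf(noisy, xy_edge)
      esfs_z[[r]] <- extract_esf(noisy, z_edge)
      for (nm in names(config$sites))
        profs[[nm]][[r]] <- site_profile(noisy, truth, config$sites[[nm]])
      rm(noisy)
    }
    rm(det); gc(FALSE)
    nps <- estimate_nps(crops, config$roi)
    mtf_xy <- esf_to_mtf(average_esfs(esfs_xy))
    mtf_z <- esf_to_mtf(average_esfs(esfs_z))
    avg_profiles <- lapply(profs, average_profiles)
    metrics <- list()
    for (nm in names(config$sites)) {
      if (!is.null(config$stent_site) && nm == config$stent_site) {
        metrics[[nm]] <- measure_stent_lumen(avg_profiles[[nm]],
                                             model_profiles[[nm]])
      } else {
        metrics[[nm]] <- measure_vessel_profile(avg_profiles[[nm]],
                                                model_profiles[[nm]])
      }
    }
    per_preset[[pi]] <- list(
      preset = p, sd = mean(sds), mean_hu = mean(means),
      per_repeat_sd = sds, nps = nps, mtf_xy = mtf_xy, mtf_z = mtf_z,
      profiles = avg_profiles, metrics = metrics)
  }

  report <- structure(list(
    presets = per_preset,
    model = list(profiles = model_profiles, mtf_xy = model_mtf_xy,
                 mtf_z = model_mtf_z, roi = model_roi),
    model_ct = model_vessel_ct(vapply(per_preset, `[[`, 0, "mean_hu")),
    dose = effective_dose(config$dose$ctdivol, config$dose$scan_length_mm,
                          config$dose$k_factor),
    sites = config$sites, stent_site = config$stent_site,
    seed = config$seed, repeats = config$repeats,
    grid = config$grid), class = "ctiq_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @method print ctiq_report
#' @export
print.ctiq_report <- function(x, ...) {
  cat("<ctiq_report> seed", x$seed, "-", x$repeats, "repeats\n")
  for (p in x$presets)
    cat(sprintf("  %-7s SD %5.1f HU  f10(XY) %5.3f  f10(Z) %5.3f cycle/mm\n",
                p$preset$name, p$sd, p$mtf_xy$f10, p$mtf_z$f10))
  cat(sprintf("  model CT %d HU; effective dose %.2f mSv\n",
              x$model_ct, x$dose$effective_dose_msv))
  invisible(x)
}

fmt_cell <- function(value, error, digits = 2) {
  if (is.null(value) || length(value) == 0 || is.na(value)) return("")
  err <- if (is.null(error) || is.na(error)) "(-)" else
    sprintf("(%.1f%%)", error)
  sprintf(paste0("%.", digits, "f%s"), value, err)
}

#' Write the report bundle to disk
#'
#' Emits CSV tables mirroring the standard profile-metric layout (per-site
#' peak CT number, W_10%, W_90% with percent errors and the model column),
#' the stent lumen-width table, per-preset NPS/MTF/profile curve CSVs, PNG
#' plots, a JSON summary, and a run log. Identical results produce identical
#' bytes.
#'
#' @param report a `ctiq_report` (possibly partial).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  pres <- report$presets
  pnames <- names(pres)
  vessel_sites <- setdiff(names(report$sites %||% list()), report$stent_site)
  if (length(pres) == 0 || length(vessel_sites) == 0) {
    utils::write.csv(data.frame(metric = character(), target = character()),
                     file.path(dir, "table1_profile_metrics.csv"),
                     row.names = FALSE)
    warning("partial results: profile-metric table is empty")
  } else {
    rows <- list()
    for (metric in c("peak_ct", "w10", "w90")) {
      for (site in vessel_sites) {
        row <- list(metric = c(peak_ct = "Peak CT# [HU]",
                               w10 = "Curve width W_10% [mm]",
                               w90 = "Curve width W_90% [mm]")[[metric]],
                    target = site)
        for (pn in pnames) {
          m <- pres[[pn]]$metrics[[site]]
          val <- switch(metric, peak_ct = m$peak_ct, w10 = m$w10, w90 = m$w90)
          err <- switch(metric, peak_ct = m$errors$peak, w10 = m$errors$w10,
                        w90 = m$errors$w90)
          row[[pn]] <- fmt_cell(val, err,
                                digits = if (metric == "peak_ct") 1 else 2)
        }
        m0 <- pres[[1]]$metrics[[site]]
        mval <- switch(metric, peak_ct = m0$model_peak, w10 = m0$model_w10,
                       w90 = m0$model_w90)
        row$Model <- fmt_cell(mval, NA,
                              digits = if (metric == "peak_ct") 1 else 2)
        rows[[length(rows) + 1]] <- row
      }
    }
    utils::write.csv(do.call(rbind, lapply(rows, as.data.frame)),
                     file.path(dir, "table1_profile_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$stent_site) && length(pres) > 0) {
    row <- list(metric = "Curve width lumen [mm]")
    for (pn in pnames) {
      m <- pres[[pn]]$metrics[[report$stent_site]]
      row[[pn]] <- fmt_cell(m$w_lumen, m$error)
    }
    row$`Model(W_truth)` <-
      fmt_cell(pres[[1]]$metrics[[report$stent_site]]$w_truth, NA)
    utils::write.csv(as.data.frame(row),
                     file.path(dir, "table2_stent_lumen.csv"),
                     row.names = FALSE)
  }
  for (pn in pnames) {
    p <- pres[[pn]]
    utils::write.csv(data.frame(freq_cyc_mm = p$nps$freq,
                                nps_hu2_mm2 = p$nps$nps),
                     file.path(dir, sprintf("nps_%s.csv", pn)),
                     row.names = FALSE)
    for (dirn in c("xy", "z")) {
      m <- p[[paste0("mtf_", dirn)]]
      utils::write.csv(data.frame(freq_cyc_mm = m$freq, mtf = m$mtf),
                       file.path(dir, sprintf("mtf_%s_%s.csv", dirn, pn)),
                       row.names = FALSE)
    }
    for (site in names(p$profiles))
      utils::write.csv(data.frame(position_mm = p$profiles[[site]]$position,
                                  hu = p$profiles[[site]]$hu),
                       file.path(dir, sprintf("profile_%s_%s.csv", site, pn)),
                       row.names = FALSE)
  }
  if (!is.null(report[["model"]]))
    for (site in names(report[["model"]]$profiles))
      utils::write.csv(
        data.frame(position_mm = report[["model"]]$profiles[[site]]$position,
                   hu = report[["model"]]$profiles[[site]]$hu),
        file.path(dir, sprintf("profile_%s_model.csv", site)),
        row.names = FALSE)
  summary <- list(
    seed = report$seed, repeats = report$repeats,
    model_ct_hu = report$model_ct,
    dose = report$dose,
    presets = lapply(pres, function(p) list(
      name = p$preset$name, sigma_xy_mm = p$preset$sigma_xy,
      sigma_z_mm = p$preset$sigma_z,
      noise_sd_hu = p$sd, mean_ct_hu = p$mean_hu,
      nps_variance_integral_hu2 = p$nps$variance_integral,
      f10_xy_cyc_mm = p$mtf_xy$f10, f50_xy_cyc_mm = p$mtf_xy$f50,
      f10_z_cyc_mm = p$mtf_z$f10, f50_z_cyc_mm = p$mtf_z$f50,
      metrics = lapply(p$metrics, function(m) rapply(unclass(m), identity,
                                                     how = "list")))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  plot_report(report, dir)
  writeLines(c(
    sprintf("cctaphantom %s / R %s.%s",
            as.character(utils::packageVersion("cctaphantom")),
            R.version$major, R.version$minor),
    sprintf("seed %d, repeats %d", report$seed, report$repeats),
    sprintf("grid %d x %d x %d @ %s mm", report$grid$dim[1],
            report$grid$dim[2], report$grid$dim[3],
            paste(signif(report$grid$spacing, 5), collapse = " x "))),
    file.path(dir, "log.txt"))
  invisible(dir)
}

plot_report <- function(report, dir) {
  pres <- report$presets
  if (length(pres) == 0) return(invisible(NULL))
  cols <- c("#D55E00", "#0072B2", "#009E73", "grey40")
  safe_png <- function(path, expr) {
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    expr()
  }
  safe_png(file.path(dir, "nps.png"), function() {
    ymax <- max(vapply(pres, function(p) max(p$nps$nps), 0))
    graphics::plot(NULL, xlim = c(0, max(pres[[1]]$nps$freq)),
                   ylim = c(0, ymax), xlab = "spatial frequency [cycle/mm]",
                   ylab = expression(NPS ~ "[" * HU^2 ~ mm^2 * "]"),
                   main = "Noise power spectrum")
    for (i in seq_along(pres))
      graphics::lines(pres[[i]]$nps$freq, pres[[i]]$nps$nps, col = cols[i], lwd = 2)
    graphics::legend("topright", names(pres), col = cols[seq_along(pres)], lwd = 2)
  })
  for (dirn in c("xy", "z")) {
    safe_png(file.path(dir, sprintf("mtf_%s.png", dirn)), function() {
      graphics::plot(NULL, xlim = c(0, 2), ylim = c(0, 1.05),
                     xlab = "spatial frequency [cycle/mm]", ylab = "T-MTF",
                     main = sprintf("Task-based MTF (%s)", toupper(dirn)))
      for (i in seq_along(pres)) {
        m <- pres[[i]][[paste0("mtf_", dirn)]]
        graphics::lines(m$freq, m$mtf, col = cols[i], lwd = 2)
      }
      if (!is.null(report[["model"]])) {
        m <- report[["model"]][[paste0("mtf_", dirn)]]
        graphics::lines(m$freq, m$mtf, col = "grey40", lwd = 2, lty = 2)
      }
      graphics::abline(h = 0.1, lty = 3)
      graphics::legend("topright", c(names(pres), "model"),
                       col = c(cols[seq_along(pres)], "grey40"),
                       lwd = 2, lty = c(rep(1, length(pres)), 2))
    })
  }
  for (site in names(report$sites %||% list())) {
    safe_png(file.path(dir, sprintf("profiles_%s.png", site)), function() {
      rng <- range(vapply(pres, function(p) range(p$profiles[[site]]$hu),
                          numeric(2)))
      mp <- report[["model"]]$profiles[[site]]
      rng <- range(rng, mp$hu)
      graphics::plot(NULL, xlim = range(mp$position), ylim = rng,
                     xlab = "orthogonal position [mm]", ylab = "CT number [HU]",
                     main = sprintf("Profile curve: %s", site))
      for (i in seq_along(pres))
        graphics::lines(pres[[i]]$profiles[[site]]$position,
                        pres[[i]]$profiles[[site]]$hu, col = cols[i], lwd = 2)
      graphics::lines(mp$position, mp$hu, col = "grey40", lwd = 2, lty = 2)
      graphics::legend("topright", c(names(pres), "model"),
                       col = c(cols[seq_along(pres)], "grey40"),
                       lwd = 2, lty = c(rep(1, length(pres)), 2))
    })
  }
  invisible(NULL)
}

#' Build an experiment configuration from a YAML file
#'
#' Recognized top-level keys (all optional): `seed`, `repeats`, `calibrate`,
#' `grid` (`fov_mm`, `z_extent_mm`), `roi` (`center`, `size`), `dose`
#' (`ctdivol`, `scan_length_mm`, `k_factor`), `phantom`
#' (`contrast_hu`, `stent_hu`, `include_stent`).
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$phantom %||% list()
  spec <- do.call(ccta_phantom_spec, spec_args)
  grid_args <- y$grid %||% list()
  grid <- do.call(analysis_grid, grid_args)
  roi <- if (!is.null(y$roi))
    roi_spec(y$roi$center %||% c(0, 0, 0), y$roi$size %||% c(40, 40, 25))
  else roi_spec(c(0, 0, 0))
  experiment_config(
    spec = spec, grid = grid,
    repeats = y$repeats %||% 3,
    seed = y$seed %||% 1L,
    roi = roi,
    dose = y$dose %||% list(ctdivol = 3.7, scan_length_mm = 160,
                            k_factor = 0.014),
    calibrate = y$calibrate %||% TRUE)
}

#' Write a commented default configuration file
#' @param path output YAML path.
#' @export
write_default_config <- function(path) {
  writeLines(c(
    "# cctaphantom experiment configuration (units: mm, HU, mGy)",
    "seed: 1",
    "repeats: 3",
    "calibrate: true",
    "grid:",
    "  fov_mm: 112.5",
    "  z_extent_mm: 36",
    "roi:",
    "  center: [0, 0, 0]",
    "  size: [40, 40, 25]",
    "dose:",
    "  ctdivol: 3.7",
    "  scan_length_mm: 160",
    "  k_factor: 0.014",
    "phantom:",
    "  contrast_hu: 424",
    "  include_stent: true"), path)
  invisible(path)
}
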