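#' Edge specifications for task-based MTF measurement
#'
#' Task-based MTFs are measured from analytically known boundaries of the
#' phantom rather than from wires or beads, so the estimator sees the same
#' contrast and structure a reconstruction algorithm sees clinically.
#' `xy_edge_spec()` uses the ventricle/myocardium boundary (a circular arc in
#' each axial slice, radius known per slice from the ellipsoidal ventricle);
#' `z_edge_spec()` uses the wedge top face, a plane inclined at most 30
#' degrees to the axial plane, whose tilt converts the 0.25 mm slice interval
#' into `0.25 * sin(theta)` mm effective sampling along the edge normal.
#' `plane_edge_spec()` builds an explicit plane edge (calibration and
#' synthetic tests).
#'
#' @param truth a `phantom_truth`.
#' @param band half-width (mm) of the sampling band around the boundary;
#'   must cover the full edge transition (>= 6 sigma of the expected blur).
#' @param z_range axial slab (mm) over which the in-plane arc is sampled.
#' @param azimuth_deg azimuth interval (degrees) of the arc kept for
#'   sampling; the default avoids the simulated vessels.
#' @return object of class `edge_spec`.
#' @export
xy_edge_spec <- function(truth, band = 3, z_range = c(-3, 3),
                         azimuth_deg = c(150, 230)) {
  v <- truth$ventricle
  structure(list(type = "circle", center = v$center, semi = v$semi,
                 band = band, z_range = z_range, azimuth_deg = azimuth_deg,
                 contrast = truth$xy_edge$contrast, direction = "XY"),
            class = "edge_spec")
}

#' @rdname xy_edge_spec
#' @export
z_edge_spec <- function(truth, band = 3) {
  e <- truth$z_edge
  if (e$theta_deg > 30 + 1e-9) stop("slant angle must be <= 30 degrees")
  structure(list(type = "plane", point = e$point, normal = e$normal,
                 band = band,
                 bounds = list(x = e$bounds$x, y = e$bounds$y, z = NULL),
                 contrast = e$contrast, direction = "Z"),
            class = "edge_spec")
}

#' @rdname xy_edge_spec
#' @param point,normal plane origin and unit normal (normal points from the
#'   high-HU side to the low-HU side).
#' @param bounds named list of world ranges (`x`, `y`, `z`; `NULL` = no
#'   restriction) limiting the sampling band laterally.
#' @param contrast `c(inside_hu, outside_hu)`.
#' @param direction `"XY"` or `"Z"` tag carried into the MTF result.
#' @export
plane_edge_spec <- function(point, normal, band = 3, bounds = list(),
                            contrast = c(424, 40), direction = "XY") {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(type = "plane", point = point, normal = normal, band = band,
                 bounds = bounds, contrast = contrast, direction = direction),
            class = "edge_spec")
}

#' Extract an oversampled edge-spread function
#'
#' Every voxel center inside the sampling band is projected to its signed
#' distance from the analytic boundary (along the in-plane radius for the
#' circular edge; along the surface normal for plane edges, which is what
#' gives sub-slice oversampling on the slanted edge). Samples are then
#' averaged in distance bins of `bin_pitch`.
#'
#' @param vol a `voxel_volume`.
#' @param edge an `edge_spec`.
#' @param bin_pitch bin width (mm); default one quarter of the smallest voxel
#'   pitch.
#' @return object of class `esf_curve`: data frame columns `distance`
#'   (mm, negative inside the high-HU material), `hu`, `n`.
#' @export
extract_esf <- function(vol, edge, bin_pitch = NULL) {
  if (is.null(bin_pitch)) bin_pitch <- min(vol$spacing) / 4
  ax <- vol_axes(vol)
  if (edge$type == "circle") {
    zr <- edge$z_range
    iz <- which(ax[[3]] >= zr[1] & ax[[3]] <= zr[2])
    if (length(iz) == 0) stop("edge band exits the volume (z)")
    a_xy <- edge$semi[1]; c_z <- edge$semi[3]
    dist_list <- vector("list", length(iz))
    val_list <- vector("list", length(iz))
    dx <- ax[[1]] - edge$center[1]
    dy <- ax[[2]] - edge$center[2]
    r2 <- outer(dx^2, dy^2, "+")
    phi <- atan2(outer(rep(1, length(dx)), dy, "*"),
                 outer(dx, rep(1, length(dy)), "*")) * 180 / pi
    phi <- (phi + 360) %% 360
    in_az <- phi >= edge$azimuth_deg[1] & phi <= edge$azimuth_deg[2]
    for (k in seq_along(iz)) {
      z <- ax[[3]][iz[k]] - edge$center[3]
      r_slice <- a_xy * sqrt(max(1 - (z / c_z)^2, 0))
      d <- sqrt(r2) - r_slice          # signed in-plane distance to the arc
      sel <- abs(d) <= edge$band & in_az
      dist_list[[k]] <- d[sel]
      val_list[[k]] <- vol$values[, , iz[k]][sel]
    }
    dists <- unlist(dist_list); vals <- unlist(val_list)
  } else {
    n <- edge$normal; p0 <- edge$point
    # restrict to the lateral bounds (and the axial span of the tilted band)
    # before forming distance arrays, so large volumes are never touched whole
    idx <- lapply(1:3, function(i) seq_along(ax[[i]]))
    for (axis in c("x", "y", "z")) {
      b <- edge$bounds[[axis]]
      i <- match(axis, c("x", "y", "z"))
      if (!is.null(b)) idx[[i]] <- which(ax[[i]] >= b[1] & ax[[i]] <= b[2])
    }
    if (is.null(edge$bounds$z) && abs(n[3]) > 1e-6) {
      xr <- range(ax[[1]][idx[[1]]]); yr <- range(ax[[2]][idx[[2]]])
      corners <- expand.grid(x = xr, y = yr)
      zc <- (sum(n * p0) - n[1] * corners$x - n[2] * corners$y) / n[3]
      zr <- range(zc) + c(-1, 1) * (edge$band + max(vol$spacing)) / abs(n[3])
      idx[[3]] <- which(ax[[3]] >= zr[1] & ax[[3]] <= zr[2])
    }
    if (any(vapply(idx, length, 1L) == 0L)) stop("edge band exits the volume")
    d <- outer3_sum(n[1] * (ax[[1]][idx[[1]]] - p0[1]),
                    n[2] * (ax[[2]][idx[[2]]] - p0[2]),
                    n[3] * (ax[[3]][idx[[3]]] - p0[3]))
    sel <- abs(d) <= edge$band
    if (!any(sel)) stop("edge band exits the volume")
    sub <- vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dists <- d[sel]; vals <- sub[sel]
  }
  if (length(dists) < 8) stop("edge band exits the volume")
  contrast_span <- abs(diff(edge$contrast))
  if (diff(range(vals)) < 0.2 * contrast_span)
    stop("sampling band contains a single material; no edge to measure")
  edges <- seq(-edge$band, edge$band + bin_pitch - 1e-12, by = bin_pitch)
  bin <- findInterval(dists, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin < length(edges)
  hu <- tapply(vals[ok], bin[ok], mean)
  cnt <- tapply(vals[ok], bin[ok], length)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  out <- data.frame(distance = centers, hu = NA_real_, n = 0L)
  ix <- as.integer(names(hu))
  out$hu[ix] <- as.numeric(hu)
  out$n[ix] <- as.integer(cnt)
  # fill empty bins by linear interpolation
  if (anyNA(out$hu)) {
    good <- !is.na(out$hu)
    out$hu <- stats::approx(out$distance[good], out$hu[good],
                            xout = out$distance, rule = 2)$y
  }
  structure(list(distance = out$distance, hu = out$hu, n = out$n,
                 pitch = bin_pitch, contrast = edge$contrast,
                 direction = edge$direction),
            class = "esf_curve")
}

#' Average edge-spread functions over repeat scans
#' @param esfs list of `esf_curve`s on identical bin grids.
#' @return an `esf_curve`.
#' @export
average_esfs <- function(esfs) {
  stopifnot(length(esfs) >= 1)
  base <- esfs[[1]]
  hu <- rowMeans(vapply(esfs, `[[`, numeric(length(base$hu)), "hu"))
  base$hu <- hu
  base
}

#' Edge-spread function to task-based MTF
#'
#' The line-spread function is the central finite difference of the binned
#' ESF; it is windowed with a Hann taper centered on its peak (length
#' `window_fwhm_mult` times the LSF full width at half maximum), zero-padded,
#' Fourier transformed, corrected for the finite-difference and binning
#' apertures, and normalized to 1 at zero frequency.
#'
#' @param esf an `esf_curve` (>= 8 bins).
#' @param window_fwhm_mult Hann window length in LSF-FWHM units (default 16;
#'   shorter windows bias the MTF tail upward through the window's spectral
#'   curvature).
#' @param pad_factor zero-padding factor for the frequency grid.
#' @return object of class `mtf_result`: `freq` (cycle/mm), `mtf`
#'   (normalized to 1 at f = 0), `f10`, `f50`, `direction`.
#' @export
esf_to_mtf <- function(esf, window_fwhm_mult = 16, pad_factor = 8) {
  v <- esf$hu; p <- esf$pitch
  if (length(v) < 8) stop("ESF must have at least 8 bins")
  n <- length(v)
  lsf <- c(0, (v[3:n] - v[1:(n - 2)]) / (2 * p), 0)
  al <- abs(lsf)
  pk <- which.max(al)
  half <- al >= al[pk] / 2
  fwhm <- (max(which(half)) - min(which(half)) + 1) * p
  hw <- window_fwhm_mult * fwhm / 2
  x <- (seq_len(n) - pk) * p
  wnd <- ifelse(abs(x) <= hw, cos(pi * x / (2 * hw))^2, 0)
  lw <- lsf * wnd
  npad <- stats::nextn(n * pad_factor, 2)
  lw <- c(lw, rep(0, npad - n))
  spec <- Mod(stats::fft(lw))
  freq <- (0:(npad - 1)) / (npad * p)
  keep <- seq_len(floor(npad / 2))
  spec <- spec[keep]; freq <- freq[keep]
  # correct the finite-difference and bin-averaging apertures
  arg_d <- 2 * pi * freq * p
  arg_b <- pi * freq * p
  corr <- ifelse(arg_d < 2.2, sinc(arg_d) * sinc(arg_b), NA_real_)
  mtf <- spec / spec[1] / corr
  ok <- !is.na(mtf)
  mtf <- mtf[ok]; freq <- freq[ok]
  res <- structure(list(freq = freq, mtf = mtf, direction = esf$direction),
                   class = "mtf_result")
  res$f10 <- freq_at_fraction(res, 0.10)
  res$f50 <- freq_at_fraction(res, 0.50)
  res
}

sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)

#' @method print mtf_result
#' @export
print.mtf_result <- function(x, ...) {
  cat(sprintf("<mtf_result> %s: f50 %.3f, f10 %.3f cycle/mm (%d freq samples)\n",
              x$direction, x$f50, x$f10, length(x$freq)))
  invisible(x)
}

#' Frequency at which the MTF falls to a given fraction
#'
#' Locates the first downward crossing of `fraction` by linear interpolation
#' between the bracketing frequency samples.
#'
#' @param mtf an `mtf_result` (or any list with `freq` and `mtf`).
#' @param fraction modulation fraction in (0, 1].
#' @return frequency in cycle/mm.
#' @export
freq_at_fraction <- function(mtf, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- mtf$mtf; f <- mtf$freq
  if (m[1] <= fraction) return(f[1])
  below <- which(m <= fraction)
  if (length(below) == 0)
    stop(sprintf("MTF never falls to %.2f below Nyquist (last value %.3f)",
                 fraction, m[length(m)]))
  i <- below[1]
  f[i - 1] + (f[i] - f[i - 1]) * (m[i - 1] - fraction) / (m[i - 1] - m[i])
}
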