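#' Vessel specification
#'
#' A simulated coronary artery: a 3-D centerline polyline with a per-vertex
#' diameter profile and an optional focal stenosis. The stenosis tapers the
#' local diameter smoothly (cosine-squared bump) down to
#' `(1 - severity) * reference` at its center, the standard diameter-reduction
#' reading of percent stenosis.
#'
#' @param label vessel name.
#' @param centerline n x 3 matrix of world points (mm), n >= 2; arc length
#'   must be strictly increasing (no repeated points).
#' @param diameter_mm scalar or length-n vector of lumen diameters (mm),
#'   nominal range 1.0--4.0 mm.
#' @param stenosis `NULL` or `list(s = arc-length mm, severity = fraction in
#'   (0,1), length = mm)`.
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(label, centerline, diameter_mm, stenosis = NULL) {
  centerline <- matrix(as.numeric(centerline), ncol = 3L)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 points")
  seg <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                         centerline[-nrow(centerline), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("centerline arc length must be strictly increasing")
  s <- c(0, cumsum(seg))
  diameter_mm <- as.numeric(diameter_mm)
  if (length(diameter_mm) == 1L) diameter_mm <- rep(diameter_mm, nrow(centerline))
  if (length(diameter_mm) != nrow(centerline))
    stop("diameter_mm must be scalar or one value per centerline vertex")
  if (any(diameter_mm < 1.0 - 1e-9) || any(diameter_mm > 4.0 + 1e-9))
    stop(sprintf("vessel '%s': nominal diameters must lie in [1.0, 4.0] mm", label))
  if (!is.null(stenosis)) {
    if (!(stenosis$severity > 0 && stenosis$severity < 1))
      stop("stenosis severity must be in (0, 1)")
    if (stenosis$s < 0 || stenosis$s > max(s))
      stop("stenosis location outside vessel extent")
  }
  structure(list(label = label, centerline = centerline, s = s,
                 diameter_mm = diameter_mm, stenosis = stenosis),
            class = "vessel_spec")
}

# Local radius (mm) as a function of arc length, including the stenosis taper.
tube_radius_profile <- function(vessel) {
  s_v <- vessel$s; d_v <- vessel$diameter_mm; sten <- vessel$stenosis
  function(s) {
    d <- stats::approx(s_v, d_v, xout = pmin(pmax(s, 0), max(s_v)),
                       rule = 2)$y
    if (!is.null(sten)) {
      u <- (s - sten$s) / (sten$length / 2)
      bump <- ifelse(abs(u) <= 1, cos(pi * u / 2)^2, 0)
      d <- d * (1 - sten$severity * bump)
    }
    d / 2
  }
}

#' Stent specification
#'
#' A stent implanted in a named vessel, modeled as a thin high-attenuation
#' shell at the vessel wall (the dense-strut limit of a wire mesh), optionally
#' broken into discrete rings.
#'
#' @param vessel_label host vessel name.
#' @param s_start,s_end arc-length extent (mm) along the host vessel.
#' @param strut_hu strut attenuation (HU); must exceed the contrast HU.
#' @param strut_thickness_mm radial shell thickness (mm).
#' @param nominal_diameter_mm stent outer diameter (mm).
#' @param rings `NULL` for a continuous shell, or `list(count =, width_mm =)`
#'   for discrete rings.
#' @return object of class `stent_spec`.
#' @export
stent_spec <- function(vessel_label, s_start, s_end, strut_hu = 3200,
                       strut_thickness_mm = 0.17, nominal_diameter_mm = 2.5,
                       rings = NULL) {
  if (s_end <= s_start) stop("stent extent is empty")
  structure(list(vessel_label = vessel_label, s_start = s_start, s_end = s_end,
                 strut_hu = strut_hu, strut_thickness_mm = strut_thickness_mm,
                 nominal_diameter_mm = nominal_diameter_mm, rings = rings,
                 length_mm = s_end - s_start),
            class = "stent_spec")
}

#' Structured cardiac phantom specification
#'
#' The digital anthropomorphic phantom used throughout the package: a
#' 30 x 20 cm thorax with hollow lungs, a plaster-like vertebra and ribs, a
#' contrast-filled left ventricle inside a myocardial shell, simulated
#' coronary arteries (1.0--4.0 mm) carrying a 70% stenotic lesion and an
#' implanted stent, plus an iodine-filled wedge insert whose top face is a
#' plane inclined 30 degrees to the axial plane (the axial-resolution edge).
#' Contrast spaces are filled with dilute iodine (18 mgI/ml) whose CT number
#' is fixed at 424 HU.
#'
#' Default material HU (120 kV-plausible, all overridable): contrast 424,
#' soft tissue 40, myocardium 0 (water-equivalent, so the 10%-of-peak
#' profile threshold at ~42 HU stays clearly above the background the
#' vessels are embedded in), plaster bone 700, stent strut 3200, air -1000.
#'
#' @param contrast_hu HU of iodine-filled spaces (ventricle, vessels, wedge).
#' @param soft_hu,myocardium_hu,bone_hu,air_hu material HU values.
#' @param stent_hu stent strut HU.
#' @param include_stent logical; include the stent in the spec.
#' @param vessels optional list of [vessel_spec()] to replace the defaults.
#' @param stent optional [stent_spec()] to replace the default.
#' @return object of class `phantom_spec`.
#' @export
ccta_phantom_spec <- function(contrast_hu = 424, soft_hu = 40,
                              myocardium_hu = 0, bone_hu = 700,
                              air_hu = -1000, stent_hu = 3200,
                              include_stent = TRUE,
                              vessels = NULL, stent = NULL) {
  if (!(contrast_hu > myocardium_hu))
    stop("invariant violated: contrast_hu must exceed myocardium HU")
  if (!(myocardium_hu > air_hu))
    stop("invariant violated: myocardium HU must exceed lung/air HU")
  polar_vessel <- function(label, azimuth_deg, diameter, z0 = -12, z1 = 12,
                           stenosis = NULL) {
    a <- azimuth_deg * pi / 180
    p <- c(38.5 * cos(a), 38.5 * sin(a))
    vessel_spec(label, rbind(c(p, z0), c(p, z1)), diameter, stenosis)
  }
  if (is.null(vessels)) {
    vessels <- list(
      polar_vessel("normal_3.2", 0, 3.2),
      polar_vessel("taper_4_to_1", 60, c(4.0, 1.0)),
      polar_vessel("stenotic_1.6", 120, 1.6,
                   stenosis = list(s = 12, severity = 0.70, length = 6)),
      polar_vessel("stented_2.5", 240, 2.5, z0 = -9, z1 = 9)
    )
  }
  names(vessels) <- vapply(vessels, `[[`, "", "label")
  if (include_stent && is.null(stent)) {
    # 15 mm stent centered on the stented vessel (z = 0 <-> s = 9)
    stent <- stent_spec("stented_2.5", s_start = 1.5, s_end = 16.5,
                        strut_hu = stent_hu, strut_thickness_mm = 0.17,
                        nominal_diameter_mm = 2.5)
  }
  if (!include_stent) stent <- NULL
  if (!is.null(stent)) {
    if (stent$strut_hu <= contrast_hu)
      stop("invariant violated: stent strut HU must exceed contrast HU")
    host <- vessels[[stent$vessel_label]]
    if (is.null(host)) stop("stent references unknown vessel: ", stent$vessel_label)
    if (stent$s_end > max(host$s) + 1e-9)
      stop("stent segment extends beyond its host vessel")
  }
  spec <- structure(list(
    body_axes = c(300, 200),            # outer ellipse diameters (mm)
    body_center = c(0, 0),
    lungs = list(list(center = c(-95, 0), semi = c(48, 80)),
                 list(center = c(95, 0), semi = c(48, 80))),
    vertebra = list(center = c(0, -75), radius = 15),
    ribs = list(scale = 0.92, tube_radius = 4, z_levels = seq(-100, 100, by = 20)),
    heart_center = c(0, 0, 0),
    myocardium_semi = c(43, 43, 33),
    ventricle_semi = c(35, 35, 23),
    wedge = list(x_half = 7, y_range = c(-54, -44), pivot_y = -49,
                 angle_deg = 30, z_floor = -8),
    vessels = vessels, stent = stent,
    contrast_hu = contrast_hu, soft_hu = soft_hu,
    myocardium_hu = myocardium_hu, bone_hu = bone_hu,
    stent_hu = stent_hu, air_hu = air_hu,
    iodine_mg_per_ml = 18), class = "phantom_spec")
  check_vessels_in_heart(spec)
  spec
}

check_vessels_in_heart <- function(spec) {
  a <- spec$myocardium_semi; ctr <- spec$heart_center
  bx <- spec$body_axes / 2
  for (v in spec$vessels) {
    q <- sweep(v$centerline, 2, ctr)
    if (any(rowSums(sweep(q, 2, a, "/")^2) > 1 + 1e-9))
      stop(sprintf("vessel '%s' leaves the heart region", v$label))
    qb <- sweep(v$centerline[, 1:2, drop = FALSE], 2, spec$body_center)
    if (any(rowSums(sweep(qb, 2, bx, "/")^2) > 1))
      stop(sprintf("vessel '%s' leaves the phantom body", v$label))
  }
  invisible(TRUE)
}

# ---- signed-distance painters -----------------------------------------------
# All painters antialias by linear boundary coverage on the (approximate)
# signed distance: coverage = clamp(0.5 - d / w), where w is the voxel
# footprint along the local surface normal. This reproduces supersampled
# occupancy mixing for smooth boundaries at a fraction of the cost.

outer3_sum <- function(vx, vy, vz) outer(outer(vx, vy, "+"), vz, "+")

coverage <- function(d, w) pmin(1, pmax(0, 0.5 - d / w))

bbox_index <- function(axes, lo, hi) {
  idx <- lapply(1:3, function(i) which(axes[[i]] >= lo[i] & axes[[i]] <= hi[i]))
  if (any(vapply(idx, length, 1L) == 0L)) NULL else idx
}

# Approximate signed distance to an ellipsoid surface (exact for spheres,
# first-order elsewhere; ample for sub-voxel antialiasing).
ellipsoid_distance <- function(x, y, z, center, semi) {
  qx2 <- ((x - center[1]) / semi[1])^2
  qy2 <- ((y - center[2]) / semi[2])^2
  qz2 <- ((z - center[3]) / semi[3])^2
  Q <- outer3_sum(qx2, qy2, qz2)
  G <- outer3_sum(qx2 / semi[1]^2, qy2 / semi[2]^2, qz2 / semi[3]^2)
  f <- sqrt(Q)
  d <- f * (f - 1) / sqrt(pmax(G, 1e-300))
  d[f < 1e-6] <- -min(semi)
  d
}

paint_ellipsoid <- function(vals, axes, center, semi, hu, w) {
  idx <- bbox_index(axes, center - semi - 2 * w, center + semi + 2 * w)
  if (is.null(idx)) return(vals)
  d <- ellipsoid_distance(axes[[1]][idx[[1]]], axes[[2]][idx[[2]]],
                          axes[[3]][idx[[3]]], center, semi)
  cov <- coverage(d, w)
  vals[idx[[1]], idx[[2]], idx[[3]]] <-
    vals[idx[[1]], idx[[2]], idx[[3]]] * (1 - cov) + hu * cov
  vals
}

# Elliptical cylinder along z spanning the whole grid.
paint_ellipse_cylinder <- function(vals, axes, center2, semi2, hu, w) {
  qx2 <- ((axes[[1]] - center2[1]) / semi2[1])^2
  qy2 <- ((axes[[2]] - center2[2]) / semi2[2])^2
  Q <- outer(qx2, qy2, "+")
  G <- outer(qx2 / semi2[1]^2, qy2 / semi2[2]^2, "+")
  f <- sqrt(Q)
  d <- f * (f - 1) / sqrt(pmax(G, 1e-300))
  d[f < 1e-6] <- -min(semi2)
  cov2 <- coverage(d, w)
  cov <- array(cov2, dim = dim(vals))   # z-invariant, recycled slice-wise
  vals * (1 - cov) + hu * cov
}

paint_circular_cylinder <- function(vals, axes, center2, radius, hu, w) {
  idx <- bbox_index(axes,
                    c(center2 - radius - 2 * w, -Inf),
                    c(center2 + radius + 2 * w, Inf))
  if (is.null(idx)) return(vals)
  dx2 <- (axes[[1]][idx[[1]]] - center2[1])^2
  dy2 <- (axes[[2]][idx[[2]]] - center2[2])^2
  d2 <- sqrt(outer(dx2, dy2, "+")) - radius
  cov <- array(coverage(d2, w),
               dim = c(length(idx[[1]]), length(idx[[2]]), length(idx[[3]])))
  vals[idx[[1]], idx[[2]], idx[[3]]] <-
    vals[idx[[1]], idx[[2]], idx[[3]]] * (1 - cov) + hu * cov
  vals
}

# Rib: a tube of radius r following a scaled copy of the body ellipse at a
# fixed axial level.
paint_rib_ring <- function(vals, axes, center2, semi2, tube_r, z_level, hu, w) {
  zr <- c(z_level - tube_r - 2 * w, z_level + tube_r + 2 * w)
  idx <- bbox_index(axes, c(-Inf, -Inf, zr[1]), c(Inf, Inf, zr[2]))
  if (is.null(idx)) return(vals)
  qx2 <- ((axes[[1]][idx[[1]]] - center2[1]) / semi2[1])^2
  qy2 <- ((axes[[2]][idx[[2]]] - center2[2]) / semi2[2])^2
  Q <- outer(qx2, qy2, "+")
  G <- outer(qx2 / semi2[1]^2, qy2 / semi2[2]^2, "+")
  f <- sqrt(Q)
  d2d <- f * (f - 1) / sqrt(pmax(G, 1e-300))
  d2d[f < 1e-6] <- -min(semi2)
  dz <- axes[[3]][idx[[3]]] - z_level
  d <- sqrt(outer(d2d^2, dz^2, "+")) - tube_r
  cov <- coverage(d, w)
  vals[idx[[1]], idx[[2]], idx[[3]]] <-
    vals[idx[[1]], idx[[2]], idx[[3]]] * (1 - cov) + hu * cov
  vals
}

paint_wedge <- function(vals, axes, wedge, hu, spacing) {
  th <- wedge$angle_deg * pi / 180
  n <- c(0, -sin(th), cos(th))                 # upward normal of the top face
  w_plane <- sqrt(sum((n * spacing)^2))
  lo <- c(-wedge$x_half, wedge$y_range[1], wedge$z_floor)
  hi <- c(wedge$x_half, wedge$y_range[2],
          tan(th) * (wedge$y_range[2] - wedge$pivot_y) + 2)
  idx <- bbox_index(axes, lo - 2 * w_plane, hi + 2 * w_plane)
  if (is.null(idx)) return(vals)
  x <- axes[[1]][idx[[1]]]; y <- axes[[2]][idx[[2]]]; z <- axes[[3]][idx[[3]]]
  # signed distance to the inclined top face
  d_plane <- outer3_sum(0 * x, -tan(th) * (y - wedge$pivot_y) * cos(th),
                        z * cos(th))
  d_x <- outer3_sum(pmax(lo[1] - x, x - hi[1]), 0 * y, 0 * z)
  d_y <- outer3_sum(0 * x, pmax(wedge$y_range[1] - y, y - wedge$y_range[2]), 0 * z)
  d_z <- outer3_sum(0 * x, 0 * y, wedge$z_floor - z)
  d <- pmax(d_plane, d_x, d_y, d_z)
  cov <- coverage(d, w_plane)
  vals[idx[[1]], idx[[2]], idx[[3]]] <-
    vals[idx[[1]], idx[[2]], idx[[3]]] * (1 - cov) + hu * cov
  vals
}

#' Rasterize a tube (vessel) to an occupancy field
#'
#' Boundary voxels take fractional occupancy by linear coverage of the tube
#' surface; a focal stenosis reduces the local diameter smoothly to
#' `(1 - severity) * reference` at its center.
#'
#' @param centerline n x 3 matrix of mm points (n >= 2).
#' @param diameter_mm scalar or per-vertex diameters (mm).
#' @param grid an [image_grid()].
#' @param stenosis `NULL` or `list(s, severity, length)` as in [vessel_spec()].
#' @return a `voxel_volume` of occupancies in `[0, 1]`.
#' @export
rasterize_tube <- function(centerline, diameter_mm, grid, stenosis = NULL) {
  v <- vessel_spec("tube", centerline, diameter_mm, stenosis)
  occ <- array(0, grid$dim)
  axes <- grid_axes(grid)
  occ <- accumulate_tube(occ, axes, v, grid$spacing)
  voxel_volume(occ, grid$spacing, grid$origin)
}

accumulate_tube <- function(occ, axes, vessel, spacing) {
  radius_at <- tube_radius_profile(vessel)
  P <- vessel$centerline; s <- vessel$s
  rmax <- max(vessel$diameter_mm) / 2
  for (j in seq_len(nrow(P) - 1)) {
    p0 <- P[j, ]; p1 <- P[j + 1, ]
    L <- sqrt(sum((p1 - p0)^2))
    u <- (p1 - p0) / L
    w <- sqrt(sum(spacing^2 * (1 - u^2)) / 2)   # mean lateral voxel footprint
    lo <- pmin(p0, p1) - rmax - 3 * w
    hi <- pmax(p0, p1) + rmax + 3 * w
    idx <- bbox_index(axes, lo, hi)
    if (is.null(idx)) next
    x <- axes[[1]][idx[[1]]]; y <- axes[[2]][idx[[2]]]; z <- axes[[3]][idx[[3]]]
    tarr <- outer3_sum(u[1] * (x - p0[1]), u[2] * (y - p0[2]),
                       u[3] * (z - p0[3]))
    a2 <- outer3_sum((x - p0[1])^2, (y - p0[2])^2, (z - p0[3])^2)
    tc <- pmin(pmax(tarr, 0), L)
    dist <- sqrt(pmax(a2 - 2 * tc * tarr + tc^2, 0))
    r <- radius_at(s[j] + tc)
    cov <- coverage(dist - r, w)
    sub <- occ[idx[[1]], idx[[2]], idx[[3]]]
    occ[idx[[1]], idx[[2]], idx[[3]]] <- pmax(sub, cov)
  }
  occ
}

# Stent shell occupancy around its host vessel segment.
accumulate_stent <- function(occ, axes, spec, spacing) {
  st <- spec$stent
  vessel <- spec$vessels[[st$vessel_label]]
  radius_at <- tube_radius_profile(vessel)
  P <- vessel$centerline; s <- vessel$s
  r_out <- st$nominal_diameter_mm / 2
  r_in <- r_out - st$strut_thickness_mm
  for (j in seq_len(nrow(P) - 1)) {
    p0 <- P[j, ]; p1 <- P[j + 1, ]
    L <- sqrt(sum((p1 - p0)^2))
    u <- (p1 - p0) / L
    w <- sqrt(sum(spacing^2 * (1 - u^2)) / 2)
    lo <- pmin(p0, p1) - r_out - 3 * w
    hi <- pmax(p0, p1) + r_out + 3 * w
    idx <- bbox_index(axes, lo, hi)
    if (is.null(idx)) next
    x <- axes[[1]][idx[[1]]]; y <- axes[[2]][idx[[2]]]; z <- axes[[3]][idx[[3]]]
    tarr <- outer3_sum(u[1] * (x - p0[1]), u[2] * (y - p0[2]),
                       u[3] * (z - p0[3]))
    a2 <- outer3_sum((x - p0[1])^2, (y - p0[2])^2, (z - p0[3])^2)
    tc <- pmin(pmax(tarr, 0), L)
    dist <- sqrt(pmax(a2 - 2 * tc * tarr + tc^2, 0))
    s_loc <- s[j] + tc
    d_shell <- pmax(r_in - dist, dist - r_out)          # annular shell
    d_axial <- pmax(st$s_start - s_loc, s_loc - st$s_end)
    if (!is.null(st$rings)) {
      # discrete rings centered mid-pitch along the stent extent
      pitch <- st$length_mm / st$rings$count
      phase <- (s_loc - st$s_start) %% pitch
      d_ring <- abs(phase - pitch / 2) - st$rings$width_mm / 2
      d_axial <- pmax(d_axial, d_ring)
    }
    cov <- coverage(pmax(d_shell, d_axial), w)
    sub <- occ[idx[[1]], idx[[2]], idx[[3]]]
    occ[idx[[1]], idx[[2]], idx[[3]]] <- pmax(sub, cov)
  }
  occ
}

#' Build the digital phantom volume and its analytic ground truth
#'
#' Paints the phantom onto a voxel grid by material priority
#' (stent > vessel lumen > myocardium/ventricle > wedge > bone >
#' soft tissue > lung/air) with sub-voxel boundary antialiasing, and returns
#' the analytic geometry every downstream measurement is scored against.
#'
#' @param spec a [ccta_phantom_spec()].
#' @param grid an [image_grid()]; in-plane spacing must not exceed the
#'   smallest nominal vessel radius.
#' @param with_stent paint the stent (if the spec carries one). The digital
#'   model data used as ground truth is conventionally built without the
#'   stent; the emulated "scanned object" includes it.
#' @return `list(volume = voxel_volume, truth = phantom_truth)`.
#' @export
build_digital_phantom <- function(spec, grid, with_stent = !is.null(spec$stent)) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  min_r <- min(vapply(spec$vessels, function(v) min(v$diameter_mm), 0)) / 2
  if (max(grid$spacing[1:2]) > min_r + 1e-12)
    stop(sprintf(paste0("grid spacing %.3f mm too coarse: must not exceed the ",
                        "smallest vessel radius (%.3f mm)"),
                 max(grid$spacing[1:2]), min_r))
  check_vessels_in_heart(spec)
  axes <- grid_axes(grid)
  sp <- grid$spacing
  w_xy <- sqrt(sum(sp[1:2]^2) / 2)
  vals <- array(spec$air_hu, grid$dim)
  vals <- paint_ellipse_cylinder(vals, axes, spec$body_center,
                                 spec$body_axes / 2, spec$soft_hu, w_xy)
  for (lung in spec$lungs)
    vals <- paint_ellipse_cylinder(vals, axes, lung$center, lung$semi,
                                   spec$air_hu, w_xy)
  vals <- paint_circular_cylinder(vals, axes, spec$vertebra$center,
                                  spec$vertebra$radius, spec$bone_hu, w_xy)
  for (zl in spec$ribs$z_levels)
    vals <- paint_rib_ring(vals, axes, spec$body_center,
                           spec$ribs$scale * spec$body_axes / 2,
                           spec$ribs$tube_radius, zl, spec$bone_hu,
                           sqrt(sum(sp^2) / 3))
  vals <- paint_ellipsoid(vals, axes, spec$heart_center, spec$myocardium_semi,
                          spec$myocardium_hu, w_xy)
  vals <- paint_ellipsoid(vals, axes, spec$heart_center, spec$ventricle_semi,
                          spec$contrast_hu, w_xy)
  vals <- paint_wedge(vals, axes, spec$wedge, spec$contrast_hu, sp)
  occ <- array(0, grid$dim)
  for (v in spec$vessels) occ <- accumulate_tube(occ, axes, v, sp)
  vals <- vals * (1 - occ) + spec$contrast_hu * occ
  vol <- voxel_volume(vals, grid$spacing, grid$origin)
  truth <- phantom_truth(spec)
  if (with_stent) vol <- add_stent(vol, spec)
  list(volume = vol, truth = truth)
}

#' Paint the stent into an existing phantom volume
#' @param vol phantom `voxel_volume` (stent-free).
#' @param spec the [ccta_phantom_spec()] carrying the stent.
#' @return `voxel_volume` with the stent shell painted at highest priority.
#' @export
add_stent <- function(vol, spec) {
  if (is.null(spec$stent)) stop("spec carries no stent")
  axes <- vol_axes(vol)
  occ <- accumulate_stent(array(0, dim(vol$values)), axes, spec, vol$spacing)
  voxel_volume(vol$values * (1 - occ) + spec$stent$strut_hu * occ,
               vol$spacing, vol$origin)
}

#' Analytic ground truth of the phantom
#'
#' Derived surfaces used by the measurement modules: the ventricle boundary
#' (in-plane edge-spread extraction), the 30-degree wedge top face
#' (axial-resolution edge; slant never exceeds 30 degrees), and per-vessel
#' centerline geometry with the true local diameter.
#'
#' @param spec a [ccta_phantom_spec()].
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(spec) {
  th <- spec$wedge$angle_deg
  if (th > 30 + 1e-9) stop("axial edge slant must not exceed 30 degrees")
  thr <- th * pi / 180
  structure(list(
    spec = spec,
    ventricle = list(center = spec$heart_center, semi = spec$ventricle_semi),
    xy_edge = list(center = spec$heart_center, semi = spec$ventricle_semi,
                   contrast = c(spec$contrast_hu, spec$myocardium_hu)),
    z_edge = list(point = c(0, spec$wedge$pivot_y, 0),
                  normal = c(0, -sin(thr), cos(thr)),
                  theta_deg = th,
                  bounds = list(x = c(-spec$wedge$x_half + 2, spec$wedge$x_half - 2),
                                y = spec$wedge$y_range + c(2, -2)),
                  contrast = c(spec$contrast_hu, spec$soft_hu)),
    vessels = spec$vessels,
    stent = spec$stent), class = "phantom_truth")
}

#' @method print phantom_truth
#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>", length(x$vessels), "vessels;",
      if (is.null(x$stent)) "no stent" else
        sprintf("stent in '%s'", x$stent$vessel_label), "\n")
  invisible(x)
}

#' True local vessel diameter from the ground truth
#' @param truth a `phantom_truth`.
#' @param label vessel name.
#' @param s arc length (mm).
#' @return diameter in mm (vectorized over `s`).
#' @export
vessel_true_diameter <- function(truth, label, s) {
  v <- truth$vessels[[label]]
  if (is.null(v)) stop("unknown vessel: ", label)
  2 * tube_radius_profile(v)(s)
}

# Centerline point and unit tangent at arc length s.
vessel_point <- function(truth, label, s) {
  v <- truth$vessels[[label]]
  if (is.null(v)) stop("unknown vessel: ", label)
  s <- pmin(pmax(s, 0), max(v$s))
  vapply(1:3, function(k) stats::approx(v$s, v$centerline[, k], xout = s)$y,
         numeric(length(s)))
}

vessel_tangent <- function(truth, label, s) {
  v <- truth$vessels[[label]]
  if (is.null(v)) stop("unknown vessel: ", label)
  j <- findInterval(s, v$s, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), nrow(v$centerline) - 1L)
  d <- v$centerline[j + 1, ] - v$centerline[j, ]
  d / sqrt(sum(d^2))
}
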