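#' Orthogonal profile curve through a vessel
#'
#' Samples HU by trilinear interpolation along a line through the centerline
#' point at arc length `s`, orthogonal to the local tangent, with sub-pixel
#' pitch and symmetric extent about the centerline. For axially uniform
#' sites (normal vessel, continuous stent) the profile can be averaged over
#' a short arc-length window to suppress noise, mirroring measurement on a
#' curved planar reformation.
#'
#' @param vol a `voxel_volume`.
#' @param truth a `phantom_truth`.
#' @param label vessel name.
#' @param s arc length (mm) along the vessel.
#' @param direction optional in-plane unit vector orthogonal to the tangent;
#'   default is the tangential direction `tangent x radial` (radial taken
#'   from the heart center), falling back to `tangent x z`.
#' @param pitch sample pitch (mm); default one quarter of the in-plane voxel
#'   pitch.
#' @param extent total profile length (mm); default 4 x local true diameter.
#' @param s_window arc-length averaging window (mm; 0 = single profile).
#' @param s_step step within the window (mm).
#' @return object of class `profile_curve`: `position` (mm, centered on the
#'   centerline), `hu`, `pitch`.
#' @export
extract_profile <- function(vol, truth, label, s, direction = NULL,
                            pitch = NULL, extent = NULL,
                            s_window = 0, s_step = 0.5) {
  if (is.null(pitch)) pitch <- min(vol$spacing[1:2]) / 4
  v <- truth$vessels[[label]]
  if (is.null(v)) stop("unknown vessel: ", label)
  if (s < 0 || s > max(v$s)) stop("arc length outside vessel extent")
  if (is.null(extent)) extent <- 4 * vessel_true_diameter(truth, label, s)
  half <- ceiling(extent / 2 / pitch)
  pos <- (-half:half) * pitch
  s_list <- if (s_window > 0) {
    seq(s - s_window / 2, s + s_window / 2, by = s_step)
  } else s
  acc <- numeric(length(pos))
  for (si in s_list) {
    c0 <- vessel_point(truth, label, si)
    tg <- vessel_tangent(truth, label, si)
    u <- direction
    if (is.null(u)) {
      radial <- c0 - truth$spec$heart_center
      u <- cross3(tg, radial)
      if (sqrt(sum(u^2)) < 1e-6) u <- cross3(tg, c(0, 0, 1))
      if (sqrt(sum(u^2)) < 1e-6) u <- cross3(tg, c(1, 0, 0))
    }
    u <- u - sum(u * tg) * tg
    u <- u / sqrt(sum(u^2))
    pts <- cbind(c0[1] + pos * u[1], c0[2] + pos * u[2], c0[3] + pos * u[3])
    hu <- sample_trilinear(vol, pts)
    if (anyNA(hu)) stop("profile sampling line exits the volume")
    acc <- acc + hu
  }
  structure(list(position = pos, hu = acc / length(s_list), pitch = pitch,
                 label = label, s = s),
            class = "profile_curve")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Average profile curves over repeat scans
#' @param profiles list of `profile_curve`s on identical position grids.
#' @return a `profile_curve`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  base <- profiles[[1]]
  base$hu <- rowMeans(vapply(profiles, `[[`, numeric(length(base$hu)), "hu"))
  base
}

#' Curved planar reformation (straightened vessel image)
#'
#' Samples orthogonal profiles at regular arc-length steps along the
#' centerline, producing an image whose rows follow the vessel (arc length)
#' and whose columns are the orthogonal offset. The arc-length axis is the
#' cumulative chord length of the centerline polyline.
#'
#' @inheritParams extract_profile
#' @param offset_half half-extent (mm) of the orthogonal axis.
#' @param s_step arc-length step (mm).
#' @return object of class `cpr_image`: matrix `image` (arc length x
#'   offset), vectors `s` and `offset`.
#' @export
make_cpr <- function(vol, truth, label, offset_half = 5, s_step = 0.25,
                     pitch = NULL) {
  v <- truth$vessels[[label]]
  if (is.null(v)) stop("unknown vessel: ", label)
  if (is.null(pitch)) pitch <- min(vol$spacing[1:2]) / 4
  s_grid <- unique(c(seq(0, max(v$s), by = s_step), max(v$s)))
  half <- ceiling(offset_half / pitch)
  offs <- (-half:half) * pitch
  img <- matrix(NA_real_, length(s_grid), length(offs))
  for (i in seq_along(s_grid)) {
    pr <- extract_profile(vol, truth, label, s_grid[i], pitch = pitch,
                          extent = 2 * offset_half)
    img[i, ] <- pr$hu
  }
  structure(list(image = img, s = s_grid, offset = offs, label = label),
            class = "cpr_image")
}

#' Profile width at a threshold fraction of the model peak
#'
#' The threshold is `fraction` times the digital model's peak CT number (the
#' model peak defines 100%). The width is the length of the maximal
#' contiguous interval containing the profile's central peak on which the
#' profile stays at or above the threshold, with sub-sample linear
#' interpolation at both crossings. A profile whose peak never reaches the
#' threshold has width 0 (a valid reading for severe stenosis).
#'
#' @param profile a `profile_curve`.
#' @param model_peak peak CT number of the model profile (HU, > 0).
#' @param fraction threshold fraction (e.g. 0.90, 0.10).
#' @return width in mm.
#' @export
width_at_threshold <- function(profile, model_peak, fraction) {
  if (model_peak <= 0) stop("model_peak must be positive")
  v <- profile$hu; x <- profile$position
  thr <- fraction * model_peak
  peaks <- which(v == max(v))
  pk <- peaks[which.min(abs(x[peaks]))]
  if (v[pk] < thr) return(0)
  i <- pk
  while (i > 1 && v[i - 1] >= thr) i <- i - 1
  left <- if (i == 1) x[1] else
    x[i] - profile$pitch * (v[i] - thr) / (v[i] - v[i - 1])
  j <- pk
  n <- length(v)
  while (j < n && v[j + 1] >= thr) j <- j + 1
  right <- if (j == n) x[n] else
    x[j] + profile$pitch * (v[j] - thr) / (v[j] - v[j + 1])
  right - left
}

#' Percent error of a measurement against the model truth
#'
#' `100 * (measured - truth) / truth`, rounded to one decimal with halves
#' away from zero (the table-reporting convention). Undefined for zero
#' truth, where `NA` is returned (printed as "(-)").
#'
#' @param measured,truth numeric.
#' @return percent error (one decimal) or `NA`.
#' @export
percent_error <- function(measured, truth) {
  if (truth == 0) return(NA_real_)
  round_half_away(100 * (measured - truth) / truth, 1)
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Profile-curve width metrics for a vessel site
#'
#' Computes the standard profile readings: peak CT number (the maximum of
#' the orthogonal profile), W_90% and W_10% (widths at 90% / 10% of the
#' model peak), and percent errors against the model profile measured at the
#' same location. Errors are computed from unrounded values and rounded
#' last.
#'
#' @param profile measured `profile_curve` (repeat-averaged).
#' @param model_profile model-data `profile_curve` at the same site.
#' @return object of class `width_metrics`.
#' @export
measure_vessel_profile <- function(profile, model_profile) {
  model_profile <- align_model_profile(model_profile, profile)
  peak_ct <- max(profile$hu)
  model_peak <- max(model_profile$hu)
  w10 <- width_at_threshold(profile, model_peak, 0.10)
  w90 <- width_at_threshold(profile, model_peak, 0.90)
  m10 <- width_at_threshold(model_profile, model_peak, 0.10)
  m90 <- width_at_threshold(model_profile, model_peak, 0.90)
  structure(list(
    peak_ct = peak_ct, w10 = w10, w90 = w90,
    model_peak = model_peak, model_w10 = m10, model_w90 = m90,
    errors = list(peak = percent_error(peak_ct, model_peak),
                  w10 = if (m10 > 0) percent_error(w10, m10) else NA_real_,
                  w90 = if (m90 > 0) percent_error(w90, m90) else NA_real_)),
    class = "width_metrics")
}

align_model_profile <- function(model_profile, profile) {
  if (isTRUE(all.equal(model_profile$position, profile$position)))
    return(model_profile)
  hu <- stats::approx(model_profile$position, model_profile$hu,
                      xout = profile$position, rule = 2)$y
  structure(list(position = profile$position, hu = hu, pitch = profile$pitch),
            class = "profile_curve")
}

#' @method print width_metrics
#' @export
print.width_metrics <- function(x, ...) {
  cat(sprintf("<width_metrics> peak %.1f HU (%.1f%%), W10 %.2f mm, W90 %.2f mm (model peak %.1f, W10 %.2f, W90 %.2f)\n",
              x$peak_ct, x$errors$peak, x$w10, x$w90,
              x$model_peak, x$model_w10, x$model_w90))
  invisible(x)
}

#' Stent lumen width at the 110% threshold
#'
#' Blooming of the high-attenuation struts narrows the visible lumen. With
#' the stent-free model peak defining 100%, the lumen width is the length of
#' the maximal contiguous interval between the two strut peaks nearest the
#' centerline on which the profile stays at or below 110%, with sub-sample
#' interpolated crossings; it is 0 when blooming keeps the whole inter-strut
#' region above the threshold. The reference width W_truth is measured on
#' the stent-free model profile (full width at half maximum).
#'
#' @param profile measured `profile_curve` across the stented segment.
#' @param model_profile stent-free model `profile_curve` at the same site.
#' @param threshold_fraction lumen threshold (default 1.10).
#' @param w_truth_fraction threshold fraction for the model vessel width
#'   (default 0.5, FWHM).
#' @return list with `w_lumen` (mm), `w_truth` (mm), `error` (percent),
#'   `strut_positions` (mm), `threshold` (HU).
#' @export
measure_stent_lumen <- function(profile, model_profile,
                                threshold_fraction = 1.10,
                                w_truth_fraction = 0.5) {
  model_profile <- align_model_profile(model_profile, profile)
  model_peak <- max(model_profile$hu)
  thr <- threshold_fraction * model_peak
  v <- profile$hu; x <- profile$position
  left_side <- which(x < 0); right_side <- which(x > 0)
  il <- left_side[which.max(v[left_side])]
  ir <- right_side[which.max(v[right_side])]
  if (v[il] <= thr || v[ir] <= thr)
    stop("no strut peaks found; profile does not cross a stented segment")
  inner <- (il + 1):(ir - 1)
  if (length(inner) < 2) return_zero <- TRUE else return_zero <- FALSE
  w_truth <- width_at_threshold(model_profile, model_peak, w_truth_fraction)
  w_lumen <- 0
  if (!return_zero) {
    below <- v[inner] <= thr
    if (any(below)) {
      runs <- rle(below)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      mid <- (x[il] + x[ir]) / 2
      best <- NULL; best_d <- Inf
      for (k in which(runs$values)) {
        i0 <- inner[starts[k]]; i1 <- inner[ends[k]]
        d <- abs((x[i0] + x[i1]) / 2 - mid)
        if (d < best_d) { best <- c(i0, i1); best_d <- d }
      }
      i0 <- best[1]; i1 <- best[2]
      left <- x[i0] - profile$pitch * (thr - v[i0]) / (v[i0 - 1] - v[i0])
      right <- x[i1] + profile$pitch * (thr - v[i1]) / (v[i1 + 1] - v[i1])
      w_lumen <- max(right - left, 0)
    }
  }
  list(w_lumen = w_lumen, w_truth = w_truth,
       error = percent_error(w_lumen, w_truth),
       strut_positions = c(x[il], x[ir]), threshold = thr)
}
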