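#' Region-of-interest specification
#'
#' A box in world mm, half-open along each axis, used for noise and CT-number
#' readings. The reference ROI is 40 x 40 x 25 mm centered in the left ventricle.
#'
#' @param center length-3 world center (mm).
#' @param size length-3 box edge lengths (mm); default `c(40, 40, 25)`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(center, size = c(40, 40, 25)) {
  if (any(size <= 0)) stop("ROI size must be positive")
  structure(list(center = as.numeric(center), size = as.numeric(size)),
            class = "roi_spec")
}

roi_index <- function(vol, roi) {
  ax <- vol_axes(vol)
  lo <- roi$center - roi$size / 2
  hi <- roi$center + roi$size / 2
  idx <- lapply(1:3, function(i) which(ax[[i]] >= lo[i] & ax[[i]] < hi[i]))
  d <- dim(vol$values)
  for (i in 1:3) {
    if (length(idx[[i]]) == 0 || lo[i] < ax[[i]][1] - vol$spacing[i] / 2 ||
        hi[i] > ax[[i]][d[i]] + vol$spacing[i] / 2)
      stop("ROI extends outside the volume")
  }
  idx
}

#' ROI noise SD and mean CT number
#'
#' The protocol's noise reading: the standard deviation of HU inside the
#' ROI, computed slice by slice and averaged over slices; the mean HU over
#' the whole ROI is returned as the CT-number reading. Adding a constant to
#' the volume changes the mean but not the SD.
#'
#' @param vol a `voxel_volume`.
#' @param roi a [roi_spec()].
#' @return list with `sd` (slice-averaged SD, HU), `mean_hu`, and
#'   `per_slice_sd`.
#' @export
roi_sd <- function(vol, roi) {
  idx <- roi_index(vol, roi)
  if (length(idx[[1]]) * length(idx[[2]]) < 2)
    stop("ROI must contain at least 2 voxels per slice")
  block <- vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  per_slice <- apply(block, 3, stats::sd)
  list(sd = mean(per_slice), mean_hu = mean(block), per_slice_sd = per_slice)
}

# Least-squares projector onto 2-D polynomials up to order 2 (detrending).
poly2_basis <- function(nx, ny) {
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  X <- rep(x, times = ny); Y <- rep(y, each = nx)
  B <- cbind(1, X, Y, X^2, X * Y, Y^2)
  qr.Q(qr(B))
}

#' Estimate the 2-D noise power spectrum in a ROI
#'
#' Per axial slice of each repeat scan the ROI pixels are detrended, Fourier
#' transformed and normalized to HU^2 mm^2
#' (`|DFT|^2 * pixel_area / n_pixels`); the 2-D spectra are averaged over
#' slices and repeats, then radially binned in annuli one frequency sample
#' wide. No window function is applied; the lowest reported frequency is the
#' reciprocal of the in-plane ROI extent (the spectrum is cut off below it by
#' the ROI size). The variance integral is the sum of the 2-D NPS times the
#' frequency cell area and equals the detrended pixel variance (Parseval).
#'
#' @param repeats a `voxel_volume` or list of repeat-scan `voxel_volume`s on
#'   a common grid.
#' @param roi a [roi_spec()].
#' @param detrend `"poly2"` (subtract a per-slice second-order 2-D polynomial
#'   fit; default) or `"ensemble"` (subtract the repeat-ensemble mean slice,
#'   requires >= 2 repeats; spectra are rescaled by `n/(n-1)`).
#' @return object of class `nps_result`: `freq` (cycle/mm), `nps`
#'   (HU^2 mm^2, radial), `nps_2d`, `delta_f`, `variance_integral` (HU^2),
#'   `cutoff_freq`, `detrended_variance`.
#' @export
estimate_nps <- function(repeats, roi, detrend = c("poly2", "ensemble")) {
  detrend <- match.arg(detrend)
  if (inherits(repeats, "voxel_volume")) repeats <- list(repeats)
  if (length(repeats) < 1) stop("need at least one repeat")
  g0 <- vol_grid(repeats[[1]])
  for (r in repeats[-1]) {
    g <- vol_grid(r)
    if (!isTRUE(all.equal(g0, g))) stop("repeat scans must share one grid")
  }
  if (detrend == "ensemble" && length(repeats) < 2)
    stop("ensemble detrending needs >= 2 repeats")
  idx <- roi_index(repeats[[1]], roi)
  nx <- length(idx[[1]]); ny <- length(idx[[2]]); nz <- length(idx[[3]])
  px <- repeats[[1]]$spacing[1]; py <- repeats[[1]]$spacing[2]
  blocks <- lapply(repeats, function(v)
    v$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  if (detrend == "ensemble") {
    ens <- Reduce(`+`, blocks) / length(blocks)
    blocks <- lapply(blocks, function(b) b - ens)
    scale_unbias <- length(blocks) / (length(blocks) - 1)
  } else {
    Q <- poly2_basis(nx, ny)
    blocks <- lapply(blocks, function(b) {
      for (k in seq_len(nz)) {
        sl <- as.numeric(b[, , k])
        b[, , k] <- sl - Q %*% crossprod(Q, sl)
      }
      b
    })
    scale_unbias <- 1
  }
  acc <- matrix(0, nx, ny)
  var_acc <- 0
  for (b in blocks) {
    for (k in seq_len(nz)) {
      F2 <- Mod(stats::fft(b[, , k]))^2
      acc <- acc + F2
      var_acc <- var_acc + mean(b[, , k]^2)
    }
  }
  nobs <- length(blocks) * nz
  nps_2d <- acc / nobs * (px * py) / (nx * ny) * scale_unbias
  detrended_var <- var_acc / nobs * scale_unbias
  dfx <- 1 / (nx * px); dfy <- 1 / (ny * py)
  fx <- fft_freq(nx, px); fy <- fft_freq(ny, py)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  df <- dfx                      # annulus width: one frequency sample
  nyq <- 1 / (2 * px)
  kmax <- floor(nyq / df)
  bin_of <- pmin(pmax(round(as.numeric(fr) / df), 0), kmax + 1L)
  keep <- bin_of >= 1 & bin_of <= kmax
  radial <- as.numeric(tapply(as.numeric(nps_2d)[keep], bin_of[keep], mean))
  freq <- sort(unique(bin_of[keep])) * df
  structure(list(freq = freq, nps = radial, nps_2d = nps_2d,
                 delta_f = c(dfx, dfy),
                 variance_integral = sum(nps_2d) * dfx * dfy,
                 detrended_variance = detrended_var,
                 cutoff_freq = 1 / (nx * px),
                 n_slices = nz, n_repeats = length(blocks)),
            class = "nps_result")
}

#' @method print nps_result
#' @export
print.nps_result <- function(x, ...) {
  cat(sprintf("<nps_result> %d freq bins (%.4f - %.3f cycle/mm), variance integral %.2f HU^2 (%d slices x %d repeats)\n",
              length(x$freq), min(x$freq), max(x$freq),
              x$variance_integral, x$n_slices, x$n_repeats))
  invisible(x)
}
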