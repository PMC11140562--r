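#' 3-D voxel volume of CT numbers
#'
#' The universal image container of the package: a 3-D numeric array of
#' Hounsfield units together with voxel spacing and the world coordinate of
#' the first voxel center. World coordinates follow the convention
#' `world = origin + index * spacing` with 0-based indices and voxel-center
#' anchoring; axis 3 is the scanner (z) axis, so `values[, , k]` is an axial
#' slice.
#'
#' @param values 3-D numeric array (HU).
#' @param spacing numeric length-3, voxel spacing in mm (all positive).
#' @param origin numeric length-3, world position (mm) of voxel `[1, 1, 1]`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 axes = "RAS+z-axial"),
            class = "voxel_volume")
}

#' @method print voxel_volume
#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, HU range [%.1f, %.1f]\n",
              paste(signif(x$origin, 5), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' World coordinates of voxel centers along each axis
#' @param vol a `voxel_volume`
#' @return list of three numeric vectors (mm).
#' @export
vol_axes <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) * vol$spacing[i])
}

#' Regular image grid description
#'
#' @param dim integer length-3 voxel counts.
#' @param spacing numeric length-3 spacing (mm).
#' @param origin world position of the first voxel center; ignored when
#'   `center` is given.
#' @param center optional world position of the grid center; the origin is
#'   derived as `center - (dim - 1)/2 * spacing`.
#' @return list with `dim`, `spacing`, `origin` (class `image_grid`).
#' @export
image_grid <- function(dim, spacing, origin = NULL, center = NULL) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 1L)) stop("degenerate grid: `dim` must be three positive integers")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("degenerate grid: `spacing` must be positive")
  if (!is.null(center)) origin <- center - (dim - 1) / 2 * spacing
  if (is.null(origin)) origin <- c(0, 0, 0)
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "image_grid")
}

vol_grid <- function(vol) image_grid(dim(vol$values), vol$spacing, vol$origin)

grid_axes <- function(grid) {
  lapply(1:3, function(i) grid$origin[i] + (seq_len(grid$dim[i]) - 1) * grid$spacing[i])
}

#' Trilinear interpolation at arbitrary world points
#'
#' @param vol a `voxel_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param background value returned for points outside the voxel-center hull.
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(vol, pts, background = NA_real_) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  d <- dim(vol$values)
  t1 <- (pts[, 1] - vol$origin[1]) / vol$spacing[1]
  t2 <- (pts[, 2] - vol$origin[2]) / vol$spacing[2]
  t3 <- (pts[, 3] - vol$origin[3]) / vol$spacing[3]
  inside <- t1 >= 0 & t1 <= d[1] - 1 & t2 >= 0 & t2 <= d[2] - 1 &
    t3 >= 0 & t3 <= d[3] - 1
  out <- rep(background, nrow(pts))
  if (!any(inside)) return(out)
  t1 <- t1[inside]; t2 <- t2[inside]; t3 <- t3[inside]
  i1 <- pmin(floor(t1), d[1] - 2); i2 <- pmin(floor(t2), d[2] - 2)
  i3 <- pmin(floor(t3), d[3] - 2)
  i1 <- pmax(i1, 0); i2 <- pmax(i2, 0); i3 <- pmax(i3, 0)
  f1 <- t1 - i1; f2 <- t2 - i2; f3 <- t3 - i3
  v <- vol$values
  base <- 1 + i1 + d[1] * (i2 + d[2] * i3)
  s1 <- 1; s2 <- d[1]; s3 <- d[1] * d[2]
  val <-
    v[base]                * (1 - f1) * (1 - f2) * (1 - f3) +
    v[base + s1]           * f1 * (1 - f2) * (1 - f3) +
    v[base + s2]           * (1 - f1) * f2 * (1 - f3) +
    v[base + s1 + s2]      * f1 * f2 * (1 - f3) +
    v[base + s3]           * (1 - f1) * (1 - f2) * f3 +
    v[base + s1 + s3]      * f1 * (1 - f2) * f3 +
    v[base + s2 + s3]      * (1 - f1) * f2 * f3 +
    v[base + s1 + s2 + s3] * f1 * f2 * f3
  out[inside] <- val
  out
}

# Sparse two-band linear-interpolation matrix mapping source axis samples to
# target axis samples; out-of-range targets get all-zero rows (flagged).
interp_matrix <- function(src, tgt) {
  n <- length(src)
  t_idx <- (tgt - src[1]) / (src[2] - src[1])
  inside <- t_idx >= -1e-9 & t_idx <= n - 1 + 1e-9
  t_idx <- pmin(pmax(t_idx, 0), n - 1)
  i0 <- pmin(floor(t_idx), n - 2)
  f <- t_idx - i0
  rows <- seq_along(tgt)
  m <- Matrix::sparseMatrix(
    i = c(rows[inside], rows[inside]),
    j = c(i0[inside] + 1, i0[inside] + 2),
    x = c((1 - f)[inside], f[inside]),
    dims = c(length(tgt), n))
  list(m = m, inside = inside)
}

# Apply a (sparse) matrix A along one axis of a 3-D array.
apply_along_axis <- function(values, A, axis) {
  d <- dim(values)
  if (axis == 1L) {
    dim(values) <- c(d[1], d[2] * d[3])
    out <- as.matrix(A %*% values)
    dim(out) <- c(nrow(A), d[2], d[3])
    out
  } else if (axis == 2L) {
    v <- aperm(values, c(2, 1, 3))
    dim(v) <- c(d[2], d[1] * d[3])
    out <- as.matrix(A %*% v)
    dim(out) <- c(nrow(A), d[1], d[3])
    aperm(out, c(2, 1, 3))
  } else {
    v <- aperm(values, c(3, 2, 1))
    dim(v) <- c(d[3], d[2] * d[1])
    out <- as.matrix(A %*% v)
    dim(out) <- c(nrow(A), d[2], d[1])
    aperm(out, c(3, 2, 1))
  }
}

#' Resample a volume onto a target grid
#'
#' Trilinear interpolation onto `grid`, optionally through a rigid transform
#' mapping target world coordinates into the source frame. Samples falling
#' outside the source voxel-center hull take `background`. With the identity
#' transform and an identical grid the input is returned unchanged.
#'
#' @param vol a `voxel_volume`.
#' @param grid an `image_grid`.
#' @param transform `NULL` (identity) or `list(rotation = 3x3, translation =
#'   length-3)` applied as `source_point = rotation %*% target_point +
#'   translation`.
#' @param background HU value for out-of-domain samples.
#' @return a `voxel_volume` on `grid`.
#' @export
resample_to_grid <- function(vol, grid, transform = NULL,
                             background = -1000) {
  if (!inherits(grid, "image_grid")) stop("`grid` must be an image_grid")
  if (is.null(transform)) {
    same <- identical(dim(vol$values), as.integer(grid$dim)) &&
      isTRUE(all.equal(vol$spacing, grid$spacing)) &&
      isTRUE(all.equal(vol$origin, grid$origin))
    if (same) return(vol)
    src <- vol_axes(vol); tgt <- grid_axes(grid)
    vals <- vol$values
    outside <- vector("list", 3)
    for (ax in 1:3) {
      if (length(src[[ax]]) < 2) stop("source grid too small to interpolate")
      im <- interp_matrix(src[[ax]], tgt[[ax]])
      vals <- apply_along_axis(vals, im$m, ax)
      outside[[ax]] <- !im$inside
    }
    for (ax in 1:3) {
      if (any(outside[[ax]])) {
        idx <- which(outside[[ax]])
        if (ax == 1) vals[idx, , ] <- background
        if (ax == 2) vals[, idx, ] <- background
        if (ax == 3) vals[, , idx] <- background
      }
    }
    return(voxel_volume(vals, grid$spacing, grid$origin))
  }
  R <- transform$rotation; tr <- transform$translation
  if (is.null(R)) R <- diag(3)
  if (is.null(tr)) tr <- c(0, 0, 0)
  if (abs(det(R)) < 1e-12) stop("transform is not invertible")
  ax <- grid_axes(grid)
  pts <- cbind(rep(ax[[1]], times = grid$dim[2] * grid$dim[3]),
               rep(rep(ax[[2]], each = grid$dim[1]), times = grid$dim[3]),
               rep(ax[[3]], each = grid$dim[1] * grid$dim[2]))
  src_pts <- pts %*% t(R) + matrix(tr, nrow(pts), 3, byrow = TRUE)
  vals <- sample_trilinear(vol, src_pts, background = background)
  dim(vals) <- grid$dim
  voxel_volume(vals, grid$spacing, grid$origin)
}

# Row-normalized band convolution matrix for a centered odd-length kernel;
# truncation at the borders is renormalized (replicate-like edge handling).
conv_band_matrix <- function(n, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2 == 1)
  r <- (k - 1) / 2
  offs <- -r:r
  i <- rep(seq_len(n), each = k)
  j <- i + rep(offs, times = n)
  x <- rep(kernel, times = n)
  keep <- j >= 1 & j <= n
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                            dims = c(n, n))
  rs <- Matrix::rowSums(m)
  Matrix::Diagonal(x = 1 / rs) %*% m
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k / sum(k)
}

#' Separable Gaussian blur of a voxel volume
#'
#' Isotropic in-plane and independent axial Gaussian smoothing, expressed in
#' mm. Borders use renormalized (truncated-kernel) weights. `sigma = 0` along
#' an axis leaves that axis untouched.
#'
#' @param vol a `voxel_volume`.
#' @param sigma_xy in-plane standard deviation (mm).
#' @param sigma_z axial standard deviation (mm).
#' @return blurred `voxel_volume`.
#' @export
gaussian_blur <- function(vol, sigma_xy, sigma_z = sigma_xy) {
  if (sigma_xy < 0 || sigma_z < 0) stop("blur sigmas must be >= 0")
  vals <- vol$values
  sig_vox <- c(sigma_xy / vol$spacing[1], sigma_xy / vol$spacing[2],
               sigma_z / vol$spacing[3])
  for (axn in 1:3) {
    if (sig_vox[axn] > 1e-9) {
      A <- conv_band_matrix(dim(vals)[axn], gaussian_kernel(sig_vox[axn]))
      vals <- apply_along_axis(vals, A, axn)
    }
  }
  voxel_volume(vals, vol$spacing, vol$origin)
}

#' Crop a volume to the voxels whose centers fall inside a world-mm box
#'
#' The box is half-open: `[lo, hi)` along each axis.
#' @param vol a `voxel_volume`.
#' @param lo,hi length-3 world coordinates (mm).
#' @return a `voxel_volume`.
#' @export
crop_volume <- function(vol, lo, hi) {
  ax <- vol_axes(vol)
  idx <- lapply(1:3, function(i) which(ax[[i]] >= lo[i] & ax[[i]] < hi[i]))
  if (any(vapply(idx, length, 1L) == 0L)) stop("crop box contains no voxels")
  voxel_volume(vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               vol$spacing,
               c(ax[[1]][idx[[1]][1]], ax[[2]][idx[[2]][1]], ax[[3]][idx[[3]][1]]))
}
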