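#' Effective dose from CTDIvol
#'
#' Dose-length product `DLP = CTDIvol x scan length (cm)`; effective dose is
#' `DLP x k` with the body-region conversion factor `k` in mSv/(mGy cm)
#' (0.014 for the chest). Scan length is accepted in mm and converted.
#'
#' @param ctdivol volume CT dose index (mGy).
#' @param scan_length_mm scan length (mm).
#' @param k_factor conversion factor, mSv/(mGy cm).
#' @return list with `dlp` (mGy cm) and `effective_dose_msv` (reported to 2
#'   decimals).
#' @export
effective_dose <- function(ctdivol, scan_length_mm, k_factor = 0.014) {
  if (ctdivol < 0 || scan_length_mm < 0 || k_factor < 0)
    stop("dose inputs must be non-negative")
  dlp <- ctdivol * scan_length_mm / 10
  list(dlp = dlp, effective_dose_msv = round_half_away(dlp * k_factor, 2))
}

#' Pixel size from display field of view and matrix size
#'
#' `FoV / matrix`, reported to 2 decimals (the exact value is returned as an
#' attribute for grid arithmetic).
#'
#' @param fov_mm display field of view (mm).
#' @param matrix matrix size (> 0).
#' @return pixel size in mm (2 decimals), with attribute `exact`.
#' @export
pixel_size <- function(fov_mm, matrix) {
  if (matrix <= 0) stop("matrix size must be positive")
  exact <- fov_mm / matrix
  structure(round_half_away(exact, 2), exact = exact)
}

#' Nyquist frequency of a sampling pitch
#' @param spacing_mm sample spacing (mm, > 0).
#' @return `1 / (2 * spacing)` in cycle/mm.
#' @export
nyquist_frequency <- function(spacing_mm) {
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  1 / (2 * spacing_mm)
}

#' Model vessel CT number from per-reconstruction readings
#'
#' The mean of the per-reconstruction ROI CT-number readings, rounded to the
#' nearest HU; this average fixes the CT number assigned to the contrast
#' spaces of the digital model.
#'
#' @param readings numeric vector of mean CT numbers (HU).
#' @return integer-rounded HU.
#' @export
model_vessel_ct <- function(readings) {
  round_half_away(mean(readings), 0)
}
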