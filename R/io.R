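#' Read and write voxel volumes
#'
#' NIfTI (.nii / .nii.gz, via RNifti) is the primary volume format; MetaImage
#' (.mha, local-data, uncompressed) is provided as a secondary interchange
#' format. Spacing and origin round-trip through both.
#'
#' @param vol a `voxel_volume`.
#' @param path output file path.
#' @return `path`, invisibly (writers); a `voxel_volume` (readers).
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  # voxel-center origin via a plain scaling affine
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), sp, aff[1:3, 4])
}

#' @rdname write_volume_nifti
#' @export
write_volume_mha <- function(vol, path) {
  d <- dim(vol$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_FLOAT",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  org <- as.numeric(strsplit(hdr$Offset, " ")[[1]])
  stopifnot(hdr$ElementType == "MET_FLOAT", hdr$ElementDataFile == "LOCAL")
  vals <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  voxel_volume(array(vals, d), sp, org)
}

#' Serialize phantom ground-truth geometry to JSON
#'
#' Centerline points, diameter profiles, stenosis and stent parameters, and
#' the derived edge surfaces, in plain JSON for consumption outside R.
#'
#' @param truth a `phantom_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  vessels <- lapply(truth$vessels, function(v) {
    list(label = v$label,
         centerline_mm = unname(apply(v$centerline, 1, as.numeric, simplify = FALSE)),
         arc_length_mm = v$s,
         diameter_mm = v$diameter_mm,
         stenosis = v$stenosis)
  })
  obj <- list(
    ventricle = truth$ventricle,
    z_edge = truth$z_edge[c("point", "normal", "theta_deg", "bounds")],
    vessels = vessels,
    stent = if (!is.null(truth$stent))
      truth$stent[c("vessel_label", "s_start", "s_end", "strut_hu",
                    "strut_thickness_mm", "nominal_diameter_mm", "length_mm")],
    materials = truth$spec[c("contrast_hu", "soft_hu", "myocardium_hu",
                             "bone_hu", "stent_hu", "air_hu",
                             "iodine_mg_per_ml")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
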