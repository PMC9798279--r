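#' Volume grid container
#'
#' A minimal in-memory representation of a 3-D image: a numeric array of
#' voxel values (for grey-matter maps these are unitless modulated GM
#' densities) together with the voxel size in millimetres and the world
#' coordinate of the voxel-grid origin. All pipeline geometry checks compare
#' these three fields.
#'
#' @param values 3-D numeric (or logical) array.
#' @param voxel_size_mm positive voxel edge lengths in mm; a scalar is
#'   recycled to the three axes.
#' @param origin_mm world (mm) coordinate of the first voxel's centre. The
#'   default centres the grid so that the mid-grid point is at the origin,
#'   which puts the left/right midline at x = 0.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size_mm, origin_mm = NULL) {
  if (length(dim(values)) != 3L)
    stop_hippsbm("values must be a 3-D array", "value_error")
  if (any(dim(values) < 1L))
    stop_hippsbm("all grid dimensions must be >= 1", "value_error")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop_hippsbm("voxel sizes must be positive and finite", "value_error")
  if (is.numeric(values) && !all(is.finite(values)))
    stop_hippsbm("voxel values must be finite", "value_error")
  if (is.null(origin_mm))
    origin_mm <- -(dim(values) + 1) / 2 * voxel_size_mm + voxel_size_mm
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-5) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop_hippsbm(paste0("geometry mismatch between ", what,
                        " (dimensions, voxel size and origin must agree)"),
                 "geometry_error")
  invisible(TRUE)
}

## World (mm) coordinates of the voxel centres along each axis.
grid_axis_mm <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(i) grid$origin_mm[i] + (seq_len(d[i]) - 1) * grid$voxel_size_mm[i])
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file into a [volume_grid()]. Voxel sizes come
#' from the header `pixdim`; the origin is taken from the translation column
#' of the stored xform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_hippsbm(
                    paste0("cannot read NIfTI file '", path, "': ", conditionMessage(e)),
                    "format_error"))
  vals <- as.array(img)
  if (length(dim(vals)) > 3L) {
    if (all(dim(vals)[-(1:3)] == 1L)) dim(vals) <- dim(vals)[1:3]
    else stop_hippsbm("only 3-D volumes are supported", "format_error")
  }
  xf <- RNifti::xform(img)
  volume_grid(vals, RNifti::pixdim(img)[1:3], origin_mm = xf[1:3, 4])
}

#' Write a volume as NIfTI-1
#'
#' Values are stored as 32-bit floats (masks as 8-bit integers); voxel size
#' and origin are written into the header so that a write/read round trip
#' preserves geometry exactly and values to float32 precision.
#'
#' @param volume a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  vals <- volume$values
  is_mask <- is.logical(vals)
  storage.mode(vals) <- "double"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  aff <- diag(4)
  diag(aff)[1:3] <- volume$voxel_size_mm
  aff[1:3, 4] <- volume$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Read a NIfTI volume as a binary ROI mask
#'
#' @param path path to a NIfTI file; voxels with value > 0.5 become mask
#'   members.
#' @return a `volume_grid` with logical values.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$values <- v$values > 0.5
  if (!any(v$values))
    stop_hippsbm("mask contains no voxels", "value_error")
  v
}
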