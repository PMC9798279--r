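#' Gaussian kernel width conversion
#'
#' Converts a full width at half maximum in millimetres to the Gaussian
#' standard deviation in voxel units for a given voxel size:
#' sigma = FWHM / (2 * sqrt(2 * log(2))) / voxel_size.
#'
#' @param fwhm_mm full width at half maximum, mm (>= 0).
#' @param voxel_size_mm voxel edge length, mm (> 0).
#' @return standard deviation in voxels.
#' @examples
#' fwhm_to_sigma(3, 0.9)  # the 3 mm kernel on a 0.9 mm grid
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  if (any(fwhm_mm < 0)) stop_hippsbm("fwhm must be >= 0", "value_error")
  if (any(voxel_size_mm <= 0)) stop_hippsbm("voxel size must be > 0", "value_error")
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

## Dense 1-D convolution operator with constant (nearest) boundary
## extension: out-of-grid samples are replaced by the nearest edge sample,
## so the clipped kernel mass is accumulated on the edge rows. Rows sum to
## one exactly, hence constant volumes are preserved.
conv_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- pmin(pmax(seq_len(n) + o, 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + w[o + r + 1L]
  }
  M
}

#' Smooth a volume with a separable Gaussian kernel
#'
#' Filters along each axis with a 1-D Gaussian whose standard deviation is
#' [fwhm_to_sigma()] of that axis's voxel size, using constant (nearest)
#' boundary extension. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param volume a [volume_grid()].
#' @param fwhm_mm isotropic kernel full width at half maximum in mm.
#' @return the smoothed `volume_grid`.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop_hippsbm("fwhm_mm must be a single nonnegative number", "value_error")
  if (fwhm_mm == 0) return(volume)
  out <- volume
  out$values <- smooth_array(volume$values, fwhm_to_sigma(fwhm_mm, volume$voxel_size_mm))
  out
}

smooth_array <- function(vals, sigma_vox) {
  d <- dim(vals)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vals, perm)
    dp <- dim(v)
    m <- conv_matrix(dp[1], sigma_vox[ax]) %*% matrix(v, dp[1])
    dim(m) <- dp
    vals <- aperm(m, order(perm))
  }
  vals
}

#' Assemble the subjects-by-voxels data matrix
#'
#' Extracts the in-mask voxels of every subject volume into one matrix with
#' one row per subject and one column per mask voxel. The voxel order is
#' the fixed column-major grid raster (x fastest, then y, then z), recorded
#' in `voxel_index_map` so each column can be traced back to a grid
#' coordinate.
#'
#' @param volumes list of [volume_grid()] objects, one per subject, in the
#'   same order as the subject table.
#' @param mask an ROI mask `volume_grid` (logical values) with geometry
#'   identical to every volume.
#' @param subject_ids optional character vector of subject identifiers;
#'   defaults to `names(volumes)` or `sub-001`-style labels.
#' @return an object of class `data_matrix`: a list with `X` (N x V
#'   matrix), `voxel_index_map` (V x 3 integer matrix of grid indices),
#'   `subject_order`, and the mask geometry.
#' @export
apply_mask_and_stack <- function(volumes, mask, subject_ids = NULL) {
  if (!is.logical(mask$values))
    stop_hippsbm("mask values must be logical", "value_error")
  idx <- which(mask$values)
  if (length(idx) < 1L) stop_hippsbm("mask has no voxels", "value_error")
  n <- length(volumes)
  X <- matrix(NA_real_, n, length(idx))
  for (i in seq_len(n)) {
    check_same_geometry(volumes[[i]], mask, "volume and mask")
    X[i, ] <- volumes[[i]]$values[idx]
  }
  if (anyNA(X) || !all(is.finite(X)))
    stop_hippsbm("data matrix contains missing or non-finite values", "value_error")
  ids <- subject_ids %||% names(volumes) %||% sprintf("sub-%03d", seq_len(n))
  structure(list(X = X,
                 voxel_index_map = arrayInd(idx, dim(mask$values)),
                 subject_order = ids,
                 voxel_size_mm = mask$voxel_size_mm,
                 origin_mm = mask$origin_mm,
                 grid_shape = dim(mask$values)),
            class = "data_matrix")
}

#' Scatter an in-mask voxel vector back onto the grid
#'
#' Inverse of the masking step of [apply_mask_and_stack()]: places a
#' V-vector of in-mask values at the mask's voxels (same x-fastest order)
#' and zero elsewhere.
#'
#' @param values numeric vector with one entry per mask voxel.
#' @param mask the ROI mask `volume_grid`.
#' @return a `volume_grid` of the same geometry as the mask.
#' @export
scatter_to_grid <- function(values, mask) {
  idx <- which(mask$values)
  if (length(values) != length(idx))
    stop_hippsbm("value vector length must equal the mask voxel count", "shape_error")
  arr <- array(0, dim(mask$values))
  arr[idx] <- values
  volume_grid(arr, mask$voxel_size_mm, mask$origin_mm)
}

#' Voxel count of a region at a given isotropic resolution
#'
#' Number of whole voxels of edge `voxel_edge_mm` that fit into a region of
#' `total_volume_cc` cubic centimetres:
#' `floor(total_volume_cc * 1000 / voxel_edge_mm^3)`. For a 3 cc
#' hippocampus this gives 4115 voxels at 0.9 mm, 3000 at 1 mm, 375 at 2 mm
#' and 111 at 3 mm.
#'
#' @param total_volume_cc region volume in cc (> 0).
#' @param voxel_edge_mm isotropic voxel edge in mm (> 0).
#' @return integer voxel count.
#' @export
voxel_count <- function(total_volume_cc, voxel_edge_mm) {
  if (any(total_volume_cc <= 0) || any(voxel_edge_mm <= 0))
    stop_hippsbm("volume and voxel edge must be > 0", "value_error")
  as.integer(floor(total_volume_cc * 1000 / voxel_edge_mm^3 + 1e-9))
}
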