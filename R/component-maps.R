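#' Z-scale a source map
#'
#' Rescales a source's in-mask voxel values to zero mean and unit SD, the
#' conventional z-map display scale for SBM components. Affine transforms
#' of the input (`a * s + b`, `a > 0`) give the same z-map.
#'
#' @param source_row numeric vector of in-mask source values (>= 2 voxels).
#' @return z-scaled vector.
#' @export
zscale_map <- function(source_row) {
  if (length(source_row) < 2L)
    stop_hippsbm("need at least 2 voxels to z-scale", "value_error")
  s <- sd(source_row)
  if (s == 0) stop_hippsbm("zero-variance source cannot be z-scaled",
                           "degenerate_source_error")
  (source_row - mean(source_row)) / s
}

## 26-neighbourhood offsets in grid-index space.
neighbor_offsets_26 <- function() {
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  o[rowSums(o != 0) > 0, , drop = FALSE]
}

## Label the TRUE entries of `sel` (logical vector over mask voxels with
## grid coordinates `coords`) into 26-connected components. Returns an
## integer label per selected voxel (0 for unselected).
label_components <- function(sel, coords, grid_shape) {
  lbl_arr <- array(0L, grid_shape)
  pos <- coords[sel, , drop = FALSE]
  vox_id <- which(sel)
  lbl_arr[pos] <- seq_along(vox_id)  # row number within pos, 0 elsewhere
  offs <- neighbor_offsets_26()
  labels <- integer(length(vox_id))
  cur <- 0L
  for (start in seq_along(vox_id)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0L) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (n in seq_len(nrow(offs))) {
        nb <- pos[q, ] + offs[n, ]
        if (any(nb < 1L) || any(nb > grid_shape)) next
        row <- lbl_arr[nb[1], nb[2], nb[3]]
        if (row != 0L && labels[row] == 0L) {
          labels[row] <- cur
          queue <- c(queue, row)
        }
      }
    }
  }
  out <- integer(length(sel))
  out[vox_id] <- labels
  out
}

#' Threshold a z-map and extract suprathreshold clusters
#'
#' Applies the display threshold (`|z| > threshold`, default 3.0),
#' separately for positive and negative voxels, groups suprathreshold
#' voxels into 26-connected clusters, and reports every cluster of at
#' least `min_report_cc` cubic centimetres with its side (peak x relative
#' to the midline at x = 0 mm), volume, extreme z-value and peak
#' coordinate.
#'
#' @param z_map z-scaled in-mask voxel vector.
#' @param mask the ROI mask `volume_grid` the map lives on.
#' @param threshold z threshold (> 0).
#' @param min_report_cc minimum reported cluster volume in cc.
#' @return data.frame with columns `side`, `n_voxels`, `volume_cc`,
#'   `max_abs_z`, `peak_z`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `sign`;
#'   zero rows when nothing survives the threshold.
#' @export
threshold_and_cluster <- function(z_map, mask, threshold = 3, min_report_cc = 0.1) {
  if (threshold <= 0) stop_hippsbm("threshold must be > 0", "value_error")
  idx <- which(mask$values)
  if (length(z_map) != length(idx))
    stop_hippsbm("z_map length must equal the mask voxel count", "shape_error")
  coords <- arrayInd(idx, dim(mask$values))
  ax <- grid_axis_mm(mask)
  voxel_cc <- prod(mask$voxel_size_mm) / 1000
  rows <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) z_map > threshold else z_map < -threshold
    if (!any(sel)) next
    labels <- label_components(sel, coords, dim(mask$values))
    for (lab in seq_len(max(labels))) {
      members <- which(labels == lab)
      vol <- length(members) * voxel_cc
      if (vol < min_report_cc) next
      peak <- members[which.max(abs(z_map[members]))]
      pc <- coords[peak, ]
      x_mm <- ax[[1]][pc[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        side = if (x_mm < 0) "left" else "right",
        n_voxels = length(members),
        volume_cc = vol,
        max_abs_z = abs(z_map[peak]),
        peak_z = z_map[peak],
        peak_x_mm = x_mm,
        peak_y_mm = ax[[2]][pc[2]],
        peak_z_mm = ax[[3]][pc[3]],
        sign = if (sgn > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(side = character(), n_voxels = integer(),
                      volume_cc = numeric(), max_abs_z = numeric(),
                      peak_z = numeric(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$volume_cc), , drop = FALSE]
}

## Mask voxels lying on the boundary shell: at least one 26-neighbour is
## outside the mask (or outside the grid).
mask_boundary <- function(mask) {
  m <- mask$values
  d <- dim(m)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- array(TRUE, d)
  offs <- neighbor_offsets_26()
  for (n in seq_len(nrow(offs))) {
    o <- offs[n, ]
    shifted <- padded[(2:(d[1] + 1)) + o[1], (2:(d[2] + 1)) + o[2],
                      (2:(d[3] + 1)) + o[3], drop = FALSE]
    interior <- interior & shifted
  }
  m & !interior
}

#' Flag a component as a likely artifact
#'
#' Operationalises the visual "sharp edges at the brain boundary"
#' criterion as a statistic: the fraction of suprathreshold voxels lying
#' within one voxel of the mask boundary. The component is flagged when
#' the fraction strictly exceeds `edge_fraction`. The flag is advisory
#' only; exclusion from downstream statistics is a pipeline configuration
#' choice.
#'
#' @param z_map z-scaled in-mask voxel vector.
#' @param mask the ROI mask `volume_grid`.
#' @param threshold z threshold defining suprathreshold voxels.
#' @param edge_fraction boundary fraction above which the component is
#'   flagged (default 0.5).
#' @return list with `flag` (logical), `fraction` and `reason`.
#' @export
flag_artifact <- function(z_map, mask, threshold = 3, edge_fraction = 0.5) {
  idx <- which(mask$values)
  supra <- abs(z_map) > threshold
  if (!any(supra))
    return(list(flag = FALSE, fraction = NA_real_,
                reason = "no suprathreshold voxels"))
  boundary <- mask_boundary(mask)[idx]
  frac <- mean(boundary[supra])
  list(flag = frac > edge_fraction, fraction = frac,
       reason = sprintf("%.1f%% of suprathreshold voxels on the mask boundary (limit %.0f%%)",
                        100 * frac, 100 * edge_fraction))
}

#' Build per-component reports
#'
#' For every source of a decomposition: the z-map, its suprathreshold
#' cluster table and the artifact flag.
#'
#' @param decomposition an `ica_decomposition`.
#' @param mask the ROI mask `volume_grid`.
#' @param threshold z threshold (default 3.0).
#' @param min_report_cc minimum reported cluster volume, cc (default 0.1).
#' @param edge_fraction artifact boundary-fraction limit (default 0.5).
#' @return list of class `component_report` entries: `component`, `z_map`,
#'   `clusters` (data.frame), `artifact` (list).
#' @export
component_reports <- function(decomposition, mask, threshold = 3,
                              min_report_cc = 0.1, edge_fraction = 0.5) {
  lapply(seq_len(decomposition$K), function(k) {
    z <- zscale_map(decomposition$S[k, ])
    structure(list(component = k,
                   z_map = z,
                   clusters = threshold_and_cluster(z, mask, threshold, min_report_cc),
                   artifact = flag_artifact(z, mask, threshold, edge_fraction)),
              class = "component_report")
  })
}

#' Write cluster reports as one TSV table
#'
#' @param reports list from [component_reports()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_component_reports <- function(reports, path) {
  tabs <- lapply(reports, function(r) {
    if (nrow(r$clusters) == 0L) return(NULL)
    cbind(component = r$component, r$clusters,
          artifact_flag = r$artifact$flag)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), tabs))
  if (is.null(tab)) tab <- data.frame(component = integer())
  write.table(format(tab, digits = 8, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
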