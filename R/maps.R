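# Voxelwise prediction brain maps: per-region accuracies painted onto a label
# volume, averaged across parcellations, and compared across conditions.

#' Paint per-region prediction accuracies onto a label volume
#'
#' Every voxel of region i receives region i's mean prediction accuracy (over
#' random splits); background voxels stay unassigned (NA).
#'
#' @param rcp_means Numeric vector of per-region mean accuracies, one per
#'   region of the parcellation (names or positions 1..R).
#' @param label_volume A `label_volume`.
#'
#' @return A 3D double array of class `prediction_map` (NA = unassigned).
#' @export
rcp_map <- function(rcp_means, label_volume) {
  R <- attr(label_volume, "n_rois") %||% max(label_volume)
  if (length(rcp_means) != R || anyNA(rcp_means)) {
    abort("need one finite accuracy per region of the parcellation")
  }
  vol <- array(NA_real_, dim = dim(label_volume))
  fg <- label_volume > 0
  vol[fg] <- rcp_means[label_volume[fg]]
  structure(vol, class = "prediction_map")
}

#' Average prediction maps across parcellations
#'
#' Voxelwise arithmetic mean over the contributing maps; a voxel covered by
#' only some parcellations is averaged over the maps in which it is assigned.
#'
#' @param maps List of `prediction_map` arrays on a common grid.
#'
#' @return A `prediction_map` on the same grid.
#' @export
average_maps <- function(maps) {
  if (length(maps) == 0) abort("need at least one map")
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all maps must share one grid")
  }
  sums <- array(0, dim = dims[[1]])
  counts <- array(0L, dim = dims[[1]])
  for (m in maps) {
    ok <- !is.na(m)
    sums[ok] <- sums[ok] + m[ok]
    counts[ok] <- counts[ok] + 1L
  }
  out <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(array(out, dim = dims[[1]]), class = "prediction_map")
}

#' Correlate two prediction maps across voxels
#'
#' Pearson correlation over the assigned voxels, which must coincide between
#' the maps. With `zero_negatives = TRUE` every negative value in both maps is
#' set to zero first (negative accuracies mark unsuccessful prediction, whose
#' relative magnitude is not interpretable). If either map is constant after
#' that, the correlation is defined as 0 and flagged degenerate.
#'
#' @param map_a,map_b `prediction_map` arrays on the same grid with identical
#'   assigned-voxel masks.
#' @param zero_negatives Zero out negative values before correlating?
#'
#' @return Correlation (attribute `degenerate` = TRUE for constant maps).
#' @export
correlate_maps <- function(map_a, map_b, zero_negatives = FALSE) {
  if (!identical(dim(map_a), dim(map_b))) abort("maps are on different grids")
  mask_a <- !is.na(map_a)
  if (!identical(mask_a, !is.na(map_b))) abort("assigned-voxel masks differ")
  a <- map_a[mask_a]
  b <- map_b[mask_a]
  if (zero_negatives) {
    a <- pmax(a, 0)
    b <- pmax(b, 0)
  }
  pearson_r(a, b)
}

#' Plot a mid-axial slice of a prediction map
#'
#' @param map A `prediction_map`.
#' @param slice Which z-slice to show (default: middle).
#'
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = NULL) {
  d <- dim(map)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- map[cbind(df$x, df$y, slice)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "mean r", title = sprintf("axial slice %d", slice))
}
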