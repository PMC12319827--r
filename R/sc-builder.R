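# Build NOS-, FA- and MD-weighted structural connectomes from a streamline set,
# a parcellation label volume, and scalar volumes.

#' Construct a connectome object
#'
#' @param matrix Symmetric, zero-diagonal R x R numeric matrix.
#' @param weighting One of `"nos"`, `"fa"`, `"md"`.
#' @param parcellation_id Free-text parcellation identifier.
#'
#' @return The matrix with class `connectome` and metadata attributes.
#' @export
connectome <- function(matrix, weighting = c("nos", "fa", "md"),
                       parcellation_id = "unnamed") {
  weighting <- match.arg(weighting)
  if (!is_symmetric_matrix(matrix)) abort("connectome matrix must be symmetric")
  if (any(diag(matrix) != 0)) abort("connectome diagonal must be zero")
  if (any(matrix < 0)) abort("connectome entries must be nonnegative")
  structure(matrix, class = c("connectome", "matrix", "array"),
            weighting = weighting, parcellation_id = parcellation_id)
}

#' Look up the ROIs at a streamline's endpoints
#'
#' Returns the labels of the first and last voxel of the path, or `NULL` when
#' either endpoint lies in background (label 0). A streamline starting and
#' ending in the same region yields an equal pair; such self-connections only
#' ever touch the diagonal, which the builders zero.
#'
#' @param streamline Integer coordinate matrix (one voxel per row).
#' @param label_volume A `label_volume`.
#'
#' @return Integer vector `c(roi_i, roi_j)` or `NULL`.
#' @export
endpoint_rois <- function(streamline, label_volume) {
  d <- dim(label_volume)
  if (any(streamline < 1) || any(t(streamline) > d)) {
    abort("streamline coordinates out of volume bounds")
  }
  ends <- streamline[c(1, nrow(streamline)), , drop = FALSE]
  labs <- label_volume[ends]
  if (any(labs == 0L)) return(NULL)
  as.integer(labs)
}

# Endpoint pairs for a whole set, as a two-column matrix (i <= j, pooled
# unordered); self pairs and background-endpoint streamlines reported alongside.
endpoint_pair_table <- function(streamline_set, label_volume) {
  pairs <- lapply(streamline_set, endpoint_rois, label_volume = label_volume)
  dropped <- sum(vapply(pairs, is.null, logical(1)))
  keep <- !vapply(pairs, is.null, logical(1))
  ij <- if (any(keep)) do.call(rbind, pairs[keep]) else matrix(integer(), 0, 2)
  list(
    i = pmin(ij[, 1], ij[, 2]), j = pmax(ij[, 1], ij[, 2]),
    which = which(keep), n_background = dropped
  )
}

#' Build the NOS-weighted connectome
#'
#' Entry (i, j) counts the streamlines whose endpoints fall in regions i and j
#' (unordered, so the matrix is symmetric by construction). Self-connections
#' land on the diagonal, which is set to zero. Streamlines with an endpoint in
#' background are discarded (their count is kept in the `n_background_dropped`
#' attribute). Counts are not normalized by region size.
#'
#' @param streamline_set A `streamline_set` (may be empty).
#' @param label_volume A `label_volume` with at least two regions.
#' @param parcellation_id Identifier stored on the result.
#'
#' @return A `connectome` with `weighting = "nos"`.
#' @export
build_nos <- function(streamline_set, label_volume, parcellation_id = "unnamed") {
  R <- attr(label_volume, "n_rois") %||% max(label_volume)
  if (R < 2) abort("connectome construction needs at least two regions")
  tab <- endpoint_pair_table(streamline_set, label_volume)
  m <- matrix(0, R, R)
  if (length(tab$i) > 0) {
    for (k in seq_along(tab$i)) {
      m[tab$i[k], tab$j[k]] <- m[tab$i[k], tab$j[k]] + 1
    }
    m <- m + t(m)
  }
  diag(m) <- 0
  out <- connectome(m, "nos", parcellation_id)
  attr(out, "n_background_dropped") <- tab$n_background
  out
}

#' Mean scalar value along a streamline
#'
#' Averages the scalar volume over the distinct voxels the path passes through;
#' a voxel visited more than once is counted once.
#'
#' @param streamline Integer coordinate matrix.
#' @param scalar_volume 3D numeric array matching the grid.
#'
#' @return Scalar mean.
#' @export
streamline_mean_scalar <- function(streamline, scalar_volume) {
  d <- dim(scalar_volume)
  if (any(streamline < 1) || any(t(streamline) > d)) {
    abort("streamline coordinates out of volume bounds")
  }
  lin <- unique((streamline[, 3] - 1) * d[1] * d[2] + (streamline[, 2] - 1) * d[1] + streamline[, 1])
  mean(scalar_volume[lin])
}

#' Build a microstructurally weighted (FA or MD) connectome
#'
#' Entry (i, j) is the mean, over all streamlines whose endpoints fall in
#' regions i and j, of each streamline's mean scalar value along its path.
#' Pairs with no streamline get 0. Symmetry comes from pooling unordered
#' endpoint pairs; the diagonal is zeroed.
#'
#' @param streamline_set A `streamline_set`.
#' @param label_volume A `label_volume` with at least two regions.
#' @param scalar_volume 3D numeric array (FA or MD map).
#' @param weighting_tag `"fa"` or `"md"`.
#' @param parcellation_id Identifier stored on the result.
#'
#' @return A `connectome` with the requested weighting.
#' @export
build_microstructural <- function(streamline_set, label_volume, scalar_volume,
                                  weighting_tag = c("fa", "md"),
                                  parcellation_id = "unnamed") {
  weighting_tag <- match.arg(weighting_tag)
  R <- attr(label_volume, "n_rois") %||% max(label_volume)
  if (R < 2) abort("connectome construction needs at least two regions")
  tab <- endpoint_pair_table(streamline_set, label_volume)
  sums <- matrix(0, R, R)
  counts <- matrix(0, R, R)
  for (k in seq_along(tab$i)) {
    v <- streamline_mean_scalar(streamline_set[[tab$which[k]]], scalar_volume)
    sums[tab$i[k], tab$j[k]] <- sums[tab$i[k], tab$j[k]] + v
    counts[tab$i[k], tab$j[k]] <- counts[tab$i[k], tab$j[k]] + 1
  }
  m <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  m <- m + t(m)
  diag(m) <- 0
  out <- connectome(m, weighting_tag, parcellation_id)
  attr(out, "n_background_dropped") <- tab$n_background
  out
}
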