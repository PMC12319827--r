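# Feature classes (whole-brain edges, most-correlated edges, principal
# components, regional connectivity profiles) and the global min-max
# normalization. All data-dependent fitting is restricted to training subjects.

#' Upper-triangle edge indices in canonical order
#'
#' Row-major (i < j) enumeration of the upper triangle without the diagonal:
#' (1,2), (1,3), ..., (1,R), (2,3), ... This is the fixed column order of all
#' edgewise feature matrices in the package.
#'
#' @param n_rois Number of regions.
#'
#' @return A data frame with integer columns `i` and `j`, one row per edge.
#' @export
upper_tri_indices <- function(n_rois) {
  R <- check_count(n_rois, "n_rois", min = 2L)
  i <- rep(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R))
  data.frame(i = i, j = j)
}

# edge index of unordered pair (a, b), a != b, under the canonical order
edge_index <- function(i, j, n_rois) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  as.integer((a - 1) * n_rois - a * (a - 1) / 2 + (b - a))
}

#' Vectorize a connectome's upper triangle
#'
#' @param connectome Symmetric zero-diagonal matrix (a `connectome` or plain
#'   matrix).
#'
#' @return Numeric vector of length R(R-1)/2 in canonical edge order.
#' @export
vectorize_upper <- function(connectome) {
  m <- unclass(connectome)
  if (!is_symmetric_matrix(m)) abort("connectome must be a symmetric matrix")
  idx <- upper_tri_indices(nrow(m))
  m[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_upper()].
#'
#' @param edges Numeric vector of length R(R-1)/2.
#' @param n_rois Number of regions.
#'
#' @return An R x R symmetric matrix with zero diagonal.
#' @export
devectorize_upper <- function(edges, n_rois) {
  idx <- upper_tri_indices(n_rois)
  if (length(edges) != nrow(idx)) abort("edge vector length does not match n_rois")
  m <- matrix(0, n_rois, n_rois)
  m[cbind(idx$i, idx$j)] <- edges
  m + t(m)
}

#' Log10-transform skewed streamline counts
#'
#' Replaces strictly positive values by their base-10 logarithm and leaves
#' zeros untouched (absent edges stay 0; note the documented collision
#' log10(1) = 0). Intended for NOS features, whose raw distribution is heavily
#' right-skewed.
#'
#' @param features Nonnegative numeric vector or matrix.
#'
#' @return Transformed object of the same shape.
#' @export
log10_transform <- function(features) {
  if (any(features < 0)) abort("log10_transform requires nonnegative values")
  pos <- features > 0
  features[pos] <- log10(features[pos])
  features
}

#' Fit the global min-max normalizer on training features
#'
#' The normalizer holds a single scalar minimum and maximum taken over all
#' entries of the training feature matrix (not per column).
#'
#' @param train_feature_matrix Numeric matrix of training features.
#' @param per_feature Fit one (min, max) pair per column instead of globally.
#'   Off by default; the global scalar pair is the canonical behaviour.
#'
#' @return An object of class `minmax_normalizer`.
#' @export
fit_global_minmax <- function(train_feature_matrix, per_feature = FALSE) {
  x <- as.matrix(train_feature_matrix)
  if (per_feature) {
    mins <- apply(x, 2, min)
    maxs <- apply(x, 2, max)
    if (any(maxs <= mins)) abort("degenerate normalization: a feature column is constant")
  } else {
    mins <- min(x)
    maxs <- max(x)
    if (maxs <= mins) abort("degenerate normalization: all training values are equal")
  }
  structure(list(train_min = mins, train_max = maxs, per_feature = per_feature),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Pure affine scaling `(x - train_min) / (train_max - train_min)`. Training
#' values land in \[0,1\]; test values outside the training range are not
#' clipped.
#'
#' @param normalizer A `minmax_normalizer`.
#' @param features Numeric vector or matrix.
#'
#' @return Scaled features, same shape.
#' @export
apply_minmax <- function(normalizer, features) {
  rng <- normalizer$train_max - normalizer$train_min
  if (normalizer$per_feature) {
    sweep(sweep(as.matrix(features), 2, normalizer$train_min), 2, rng, "/")
  } else {
    (features - normalizer$train_min) / rng
  }
}

#' Select the edges most correlated with the target
#'
#' Computes each edge's Pearson correlation with the target over training
#' subjects only, ranks edges by absolute correlation (descending; ties broken
#' by ascending edge index), and returns the top k. Constant edges get
#' correlation 0.
#'
#' @param train_features Training subjects x edges matrix.
#' @param train_targets Training target vector.
#' @param k Number of edges to keep (<= number of columns).
#' @param rank_by `"absolute"` (default) or `"signed"` correlation ranking.
#'
#' @return An object of class `edge_selector` with elements `k`,
#'   `selected_indices` and the full `correlations` vector.
#' @export
select_corr_edges <- function(train_features, train_targets, k,
                              rank_by = c("absolute", "signed")) {
  rank_by <- match.arg(rank_by)
  x <- as.matrix(train_features)
  k <- check_count(k, "k")
  if (k > ncol(x)) abort("k exceeds the number of features")
  if (nrow(x) < 3) abort("edge selection needs at least 3 training subjects")
  r <- suppressWarnings(as.numeric(cor(x, train_targets)))
  r[!is.finite(r)] <- 0
  key <- if (rank_by == "absolute") abs(r) else r
  ord <- order(-key, seq_along(r))
  structure(list(k = k, selected_indices = ord[seq_len(k)], correlations = r),
            class = "edge_selector")
}

#' Fit a PCA basis on (normalized) training features
#'
#' Centers by the training mean and takes the k leading eigenvectors of the
#' training covariance, ordered by explained variance.
#'
#' @param train_features_normalized Training subjects x features matrix.
#' @param k Number of components, at most `min(n_train - 1, n_features)`.
#'
#' @return An object of class `pca_basis` with `components` (features x k,
#'   orthonormal columns), `center`, and `explained_variance` (descending).
#' @export
fit_pca <- function(train_features_normalized, k) {
  x <- as.matrix(train_features_normalized)
  k <- check_count(k, "k")
  if (k > min(nrow(x) - 1L, ncol(x))) {
    abort("k exceeds min(n_train - 1, n_features)")
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  structure(
    list(components = unname(fit$rotation[, seq_len(k), drop = FALSE]),
         center = unname(fit$center),
         explained_variance = unname(fit$sdev[seq_len(k)]^2)),
    class = "pca_basis"
  )
}

#' Project features onto a fitted PCA basis
#'
#' @param basis A `pca_basis`.
#' @param features Subjects x features matrix (same feature space as the fit).
#'
#' @return Subjects x k score matrix.
#' @export
project_pca <- function(basis, features) {
  x <- as.matrix(features)
  sweep(x, 2, basis$center) %*% basis$components
}

#' Extract a regional connectivity profile
#'
#' Returns the full row of the connectome for one region, including the zero
#' self-connection entry.
#'
#' @param connectome Symmetric R x R matrix.
#' @param roi_index Region index in 1..R.
#'
#' @return Numeric vector of length R.
#' @export
extract_rcp <- function(connectome, roi_index) {
  m <- unclass(connectome)
  roi_index <- check_count(roi_index, "roi_index")
  if (roi_index > nrow(m)) abort("roi_index out of range")
  m[roi_index, ]
}

# Column indices (into the edge matrix) of ROI r's row; entry r itself is the
# zero self-connection and is returned as index 0.
rcp_edge_columns <- function(roi_index, n_rois) {
  others <- setdiff(seq_len(n_rois), roi_index)
  cols <- integer(n_rois)
  cols[others] <- edge_index(roi_index, others, n_rois)
  cols
}

#' Pipeline configuration for one prediction run
#'
#' @param feature_class `"whole"`, `"corr"`, `"pca"`, or `"rcp"`.
#' @param weighting Connectome weighting feeding the features; NOS edges are
#'   log10-transformed before any normalization.
#' @param k Number of selected edges / components (corr and pca classes).
#' @param roi Region index (rcp class).
#' @param alpha_grid Ridge penalties evaluated in the inner loop.
#' @param feature_grid Optional vector of feature-selection cases (`k` values
#'   for corr/pca, region indices for rcp). When supplied, the feature case is
#'   optimized in the inner CV loop together with alpha.
#' @param rank_by Edge-ranking rule for the corr class.
#' @param per_feature_minmax Use per-column min-max instead of the global
#'   scalar pair.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_class = c("whole", "corr", "pca", "rcp"),
                            weighting = c("nos", "fa", "md"),
                            k = NULL, roi = NULL,
                            alpha_grid = ridge_alpha_grid(),
                            feature_grid = NULL,
                            rank_by = c("absolute", "signed"),
                            per_feature_minmax = FALSE) {
  feature_class <- match.arg(feature_class)
  weighting <- match.arg(weighting)
  rank_by <- match.arg(rank_by)
  if (feature_class %in% c("corr", "pca") && is.null(k) && is.null(feature_grid)) {
    abort("corr/pca classes need `k` or a `feature_grid`")
  }
  if (feature_class == "rcp" && is.null(roi) && is.null(feature_grid)) {
    abort("rcp class needs `roi` or a `feature_grid`")
  }
  structure(list(feature_class = feature_class, weighting = weighting,
                 k = k, roi = roi, alpha_grid = alpha_grid,
                 feature_grid = feature_grid, rank_by = rank_by,
                 per_feature_minmax = per_feature_minmax),
            class = "pipeline_config")
}

# Resolve the feature-selection parameter for a config (fixed mode).
feature_param_of <- function(config) {
  switch(config$feature_class,
    whole = NA_integer_,
    corr = config$k, pca = config$k, rcp = config$roi
  )
}

# Accept either a connectome_population or a subjects x edges matrix and
# return the prepared (weighting-transformed) edge matrix.
as_prepared_edges <- function(edges, weighting) {
  if (inherits(edges, "connectome_population")) {
    edges <- edge_matrix(edges, weighting)
  }
  prepare_edges(edges, weighting)
}

# Apply the weighting-specific transform (log10 for NOS) once; marked so
# repeated calls on the same matrix are no-ops.
prepare_edges <- function(edges, weighting) {
  if (isTRUE(attr(edges, "prepared"))) return(edges)
  n_rois <- attr(edges, "n_rois")
  X <- if (weighting == "nos") log10_transform(edges) else edges
  attr(X, "n_rois") <- n_rois
  attr(X, "prepared") <- TRUE
  X
}

# Core per-class fit on already-sliced (and already log-transformed) train and
# test matrices. Everything data-dependent is fitted on `tr` only.
fit_feature_class <- function(config, tr, te, train_targets, param, n_rois) {
  pf <- config$per_feature_minmax
  switch(config$feature_class,
    whole = {
      nz <- fit_global_minmax(tr, per_feature = pf)
      list(train = apply_minmax(nz, tr), test = apply_minmax(nz, te),
           transformers = list(normalizer = nz))
    },
    corr = {
      if (is.null(train_targets)) abort("corr class needs train_targets")
      sel <- select_corr_edges(tr, train_targets, param, rank_by = config$rank_by)
      tr_s <- tr[, sel$selected_indices, drop = FALSE]
      te_s <- te[, sel$selected_indices, drop = FALSE]
      nz <- fit_global_minmax(tr_s, per_feature = pf)
      list(train = apply_minmax(nz, tr_s), test = apply_minmax(nz, te_s),
           transformers = list(normalizer = nz, selector = sel))
    },
    pca = {
      nz <- fit_global_minmax(tr, per_feature = pf)
      tr_n <- apply_minmax(nz, tr)
      te_n <- apply_minmax(nz, te)
      basis <- fit_pca(tr_n, param)
      list(train = project_pca(basis, tr_n), test = project_pca(basis, te_n),
           transformers = list(normalizer = nz, basis = basis))
    },
    rcp = {
      if (is.null(n_rois)) abort("edge matrix lacks an n_rois attribute")
      cols <- rcp_edge_columns(param, n_rois)
      pick <- function(m) {
        out <- matrix(0, nrow(m), length(cols))
        nzc <- cols > 0
        out[, nzc] <- m[, cols[nzc], drop = FALSE]
        out
      }
      tr_s <- pick(tr)
      te_s <- pick(te)
      nz <- fit_global_minmax(tr_s, per_feature = FALSE)
      list(train = apply_minmax(nz, tr_s), test = apply_minmax(nz, te_s),
           transformers = list(normalizer = nz, roi = param))
    }
  )
}

#' Build train/test feature matrices for one feature class
#'
#' Enforces the order of operations of the prediction pipeline: NOS edges are
#' log10-transformed first; for the PCA class the normalization (fitted on the
#' training subjects over all edges) is applied to the vectorized connectome
#' before the PCA is fitted; for the whole-brain, corr and rcp classes the
#' features are extracted/selected first and the normalizer is fitted on the
#' selected training columns only. Nothing is ever fitted on test subjects.
#'
#' @param config A `pipeline_config` with a fixed feature case.
#' @param edges Subjects x edges matrix of raw edge values (one weighting),
#'   with attribute `n_rois`; or a `connectome_population` (the configured
#'   weighting is extracted).
#' @param train_indices,test_indices Disjoint subject index vectors.
#' @param train_targets Target values for the training subjects (corr class).
#' @param feature_param Optional override of the feature case (k or roi).
#'
#' @return List with `train`, `test` (matrices) and `transformers` (fitted
#'   normalizer plus selector or basis).
#' @export
build_features <- function(config, edges, train_indices, test_indices,
                           train_targets = NULL, feature_param = NULL) {
  if (inherits(edges, "connectome_population")) {
    edges <- edge_matrix(edges, config$weighting)
  }
  if (length(intersect(train_indices, test_indices)) > 0) {
    abort("train and test indices overlap")
  }
  X <- prepare_edges(edges, config$weighting)
  param <- feature_param %||% feature_param_of(config)
  fit_feature_class(config,
                    X[train_indices, , drop = FALSE],
                    X[test_indices, , drop = FALSE],
                    train_targets, param, attr(X, "n_rois"))
}
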