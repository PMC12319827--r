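# Repeated nested 5-fold cross-validation: split schemes, inner hyperparameter
# selection, repeated runs, and permutation baselines.

#' Pearson correlation between predictions and observations
#'
#' Standard Pearson correlation; when either vector is constant (correlation
#' undefined, e.g. under very strong shrinkage) the value is defined as 0 and
#' the result carries a `degenerate` attribute.
#'
#' @param yhat,y Numeric vectors of equal length >= 2.
#'
#' @return Correlation in \[-1, 1\] (attribute `degenerate` = TRUE when a
#'   vector was constant).
#' @export
pearson_r <- function(yhat, y) {
  if (length(yhat) != length(y) || length(y) < 2) {
    abort("pearson_r needs two equal-length vectors of length >= 2")
  }
  if (sd(yhat) == 0 || sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(yhat, y)
}

#' Build a repeated nested cross-validation split scheme
#'
#' For each of `n_repeats` repeats, subjects are shuffled into `n_folds`
#' near-equal outer folds; within every outer fold the remaining (training)
#' subjects are shuffled into `n_folds` inner folds. Per-repeat child seeds are
#' derived arithmetically from the master seed, so extending the number of
#' repeats never perturbs earlier ones, and the same scheme object can be
#' shared across pipelines so all consume identical fold memberships.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param master_seed Integer master seed.
#' @param n_repeats Number of repeated random splits.
#' @param n_folds Outer (and inner) fold count.
#'
#' @return An object of class `split_scheme`.
#' @export
make_splits <- function(n_subjects, master_seed, n_repeats = 100L, n_folds = 5L) {
  n <- check_count(n_subjects, "n_subjects", min = 10L)
  n_repeats <- check_count(n_repeats, "n_repeats")
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  repeats <- lapply(seq_len(n_repeats), function(r) {
    local_seed(derive_seed(master_seed, r), {
      outer <- sample(rep_len(seq_len(n_folds), n))
      inner <- lapply(seq_len(n_folds), function(f) {
        n_tr <- sum(outer != f)
        sample(rep_len(seq_len(n_folds), n_tr))
      })
      list(outer = outer, inner = inner)
    })
  })
  structure(list(n_subjects = n, n_folds = n_folds, n_repeats = n_repeats,
                 master_seed = as.integer(master_seed), repeats = repeats),
            class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme> %d subjects, %d x %d-fold (master seed %d)\n",
              x$n_subjects, x$n_repeats, x$n_folds, x$master_seed))
  invisible(x)
}

# Score one fitted feature representation over the alpha grid on a held-out
# inner fold. One SVD of the centered training features serves every alpha.
score_alphas <- function(train, test, y_tr, y_va, alpha_grid) {
  sv <- svd(scale(train, center = TRUE, scale = FALSE))
  mu_x <- colMeans(train)
  mu_y <- mean(y_tr)
  yc <- y_tr - mu_y
  vapply(alpha_grid, function(alpha) {
    beta <- ridge_beta_from_svd(sv, yc, alpha)
    pred <- drop(sweep(test, 2, mu_x) %*% beta) + mu_y
    as.numeric(pearson_r(pred, y_va))
  }, numeric(1))
}

# Mean inner-fold correlations for every (feature case, alpha) combination.
# Features are refitted on each inner-training set so no inner-validation
# subject influences selection, normalization, or the PCA basis. The corr and
# pca classes exploit that their feature cases are nested (the |r| ranking
# does not depend on k; leading principal components are shared by all k), so
# the expensive fit happens once per inner fold.
inner_grid_scores <- function(config, X, y, train_idx, inner_assignment,
                              feature_grid, alpha_grid) {
  n_folds <- max(inner_assignment)
  n_rois <- attr(X, "n_rois")
  scores <- array(0, dim = c(length(feature_grid), length(alpha_grid), n_folds))
  multi <- length(feature_grid) > 1 && !anyNA(feature_grid)
  for (f in seq_len(n_folds)) {
    itr <- train_idx[inner_assignment != f]
    iva <- train_idx[inner_assignment == f]
    tr <- X[itr, , drop = FALSE]
    te <- X[iva, , drop = FALSE]
    y_tr <- y[itr]
    y_va <- y[iva]
    if (multi && config$feature_class == "corr") {
      sel_all <- select_corr_edges(tr, y_tr, max(feature_grid),
                                   rank_by = config$rank_by)
      for (p in seq_along(feature_grid)) {
        idx <- sel_all$selected_indices[seq_len(feature_grid[p])]
        nz <- fit_global_minmax(tr[, idx, drop = FALSE],
                                per_feature = config$per_feature_minmax)
        scores[p, , f] <- score_alphas(apply_minmax(nz, tr[, idx, drop = FALSE]),
                                       apply_minmax(nz, te[, idx, drop = FALSE]),
                                       y_tr, y_va, alpha_grid)
      }
    } else if (multi && config$feature_class == "pca") {
      nz <- fit_global_minmax(tr, per_feature = config$per_feature_minmax)
      tr_n <- apply_minmax(nz, tr)
      te_n <- apply_minmax(nz, te)
      basis <- fit_pca(tr_n, max(feature_grid))
      s_tr <- project_pca(basis, tr_n)
      s_te <- project_pca(basis, te_n)
      for (p in seq_along(feature_grid)) {
        kk <- seq_len(feature_grid[p])
        scores[p, , f] <- score_alphas(s_tr[, kk, drop = FALSE],
                                       s_te[, kk, drop = FALSE],
                                       y_tr, y_va, alpha_grid)
      }
    } else {
      for (p in seq_along(feature_grid)) {
        param <- feature_grid[p]
        fb <- fit_feature_class(config, tr, te, y_tr,
                                if (is.na(param)) feature_param_of(config) else param,
                                n_rois)
        scores[p, , f] <- score_alphas(fb$train, fb$test, y_tr, y_va, alpha_grid)
      }
    }
  }
  apply(scores, c(1, 2), mean)
}

#' Select hyperparameters in the inner cross-validation loop
#'
#' Evaluates every combination of feature-selection case and ridge penalty by
#' refitting on the inner-training folds and scoring Pearson r on the held-out
#' inner fold, averaged over inner folds. Ties are broken toward the larger
#' alpha (stronger regularization) and then the smaller feature parameter.
#'
#' @param config A `pipeline_config`.
#' @param edges Subjects x edges matrix (or `connectome_population`).
#' @param y Full target vector.
#' @param train_idx Outer-training subject indices.
#' @param inner_assignment Inner fold id per outer-training subject (aligned
#'   with `train_idx`).
#' @param alpha_grid Ridge penalties to evaluate.
#' @param feature_grid Feature cases to evaluate, or `NULL` for alpha-only
#'   selection at the config's fixed feature case.
#'
#' @return List with `alpha`, `feature_param` (NA in alpha-only mode for the
#'   whole-brain class), and `mean_inner_r`.
#' @export
inner_select <- function(config, edges, y, train_idx, inner_assignment,
                         alpha_grid = config$alpha_grid,
                         feature_grid = config$feature_grid) {
  if (length(alpha_grid) == 0) abort("alpha grid must be non-empty")
  edges <- as_prepared_edges(edges, config$weighting)
  fgrid <- feature_grid %||% feature_param_of(config)
  mean_r <- inner_grid_scores(config, edges, y, train_idx, inner_assignment,
                              fgrid, alpha_grid)
  best <- which(mean_r == max(mean_r), arr.ind = TRUE)
  # ties: larger alpha first, then smaller feature parameter
  ord <- order(-alpha_grid[best[, 2]], fgrid[best[, 1]])
  pick <- best[ord[1], , drop = TRUE]
  list(alpha = alpha_grid[pick[2]], feature_param = fgrid[pick[1]],
       mean_inner_r = mean_r[pick[1], pick[2]])
}

#' Run one repeat of the nested cross-validation
#'
#' For each outer fold: hyperparameters (ridge alpha, and the feature case
#' when `config$feature_grid` is set) are chosen by [inner_select()] on the
#' outer-training subjects, features are rebuilt on the full outer-training
#' set, the model is refitted and the held-out fold is scored by Pearson r.
#' The five fold correlations are averaged into one result. Deterministic
#' given its inputs.
#'
#' @param config A `pipeline_config`.
#' @param edges Subjects x edges matrix (or `connectome_population`).
#' @param y Target vector.
#' @param repeat_assignment One element of a `split_scheme`'s `repeats` list.
#'
#' @return Mean test-fold correlation (scalar); attribute `fold_r` holds the
#'   per-fold values.
#' @export
run_nested_cv <- function(config, edges, y, repeat_assignment) {
  edges <- as_prepared_edges(edges, config$weighting)
  outer <- repeat_assignment$outer
  n_folds <- max(outer)
  fold_r <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(outer != f)
    te <- which(outer == f)
    sel <- inner_select(config, edges, y, tr, repeat_assignment$inner[[f]])
    fb <- build_features(config, edges, tr, te,
                         train_targets = y[tr],
                         feature_param = if (is.na(sel$feature_param)) NULL else sel$feature_param)
    model <- fit_ridge(fb$train, y[tr], sel$alpha)
    fold_r[f] <- as.numeric(pearson_r(predict(model, fb$test), y[te]))
  }
  structure(mean(fold_r), fold_r = fold_r)
}

new_cv_distribution <- function(r, pipeline_id) {
  structure(
    list(results = tibble::tibble(split = seq_along(r), r = as.numeric(r)),
         mean_r = mean(r), pipeline_id = pipeline_id),
    class = "cv_distribution"
  )
}

#' Run the repeated nested cross-validation
#'
#' Executes [run_nested_cv()] once per repeat of the split scheme, yielding the
#' distribution of mean test correlations over random data splits.
#'
#' @param config A `pipeline_config`.
#' @param edges Subjects x edges matrix (or `connectome_population`).
#' @param y Target vector.
#' @param split_scheme A `split_scheme` matching `length(y)`.
#' @param pipeline_id Identifier stored on the result.
#'
#' @return An object of class `cv_distribution`.
#' @export
run_repeated <- function(config, edges, y, split_scheme, pipeline_id = "pipeline") {
  if (split_scheme$n_subjects != length(y)) {
    abort("split scheme does not match the number of subjects")
  }
  edges <- as_prepared_edges(edges, config$weighting)
  r <- vapply(split_scheme$repeats, function(rep_assign) {
    as.numeric(run_nested_cv(config, edges, y, rep_assign))
  }, numeric(1))
  new_cv_distribution(r, pipeline_id)
}

#' Permutation-null distribution of prediction accuracy
#'
#' For each repeat of the scheme the targets are shuffled across subjects
#' (repeat-specific permutation derived from `perm_seed`) before the nested
#' cross-validation, breaking any subject-level link between connectomes and
#' target while preserving both marginals and the fold structure.
#'
#' @inheritParams run_repeated
#' @param perm_seed Integer seed for the per-repeat permutations.
#'
#' @return An object of class `cv_distribution`.
#' @export
permutation_baseline <- function(config, edges, y, split_scheme, perm_seed,
                                 pipeline_id = "permutation") {
  if (split_scheme$n_subjects != length(y)) {
    abort("split scheme does not match the number of subjects")
  }
  edges <- as_prepared_edges(edges, config$weighting)
  r <- vapply(seq_along(split_scheme$repeats), function(i) {
    y_perm <- local_seed(derive_seed(perm_seed, i), sample(y))
    as.numeric(run_nested_cv(config, edges, y_perm, split_scheme$repeats[[i]]))
  }, numeric(1))
  new_cv_distribution(r, pipeline_id)
}

#' @export
print.cv_distribution <- function(x, ...) {
  cat(sprintf("<cv_distribution> %s: %d splits, mean r = %.4f (sd %.4f)\n",
              x$pipeline_id, nrow(x$results), x$mean_r, sd(x$results$r)))
  invisible(x)
}

#' Tidy a cross-validation distribution
#'
#' @param x A `cv_distribution`.
#' @param ... Unused.
#'
#' @return Tibble with one row per random split (`pipeline_id`, `split`, `r`).
#' @method tidy cv_distribution
#' @export
tidy.cv_distribution <- function(x, ...) {
  dplyr::mutate(x$results, pipeline_id = x$pipeline_id, .before = 1)
}

#' Summarize a cross-validation distribution
#'
#' @param x A `cv_distribution`.
#' @param threshold Accuracy threshold for the "promising" fraction.
#' @param ... Unused.
#'
#' @return One-row tibble with mean, sd, and the fraction of splits above the
#'   threshold.
#' @method glance cv_distribution
#' @export
glance.cv_distribution <- function(x, threshold = 0.2, ...) {
  tibble::tibble(
    pipeline_id = x$pipeline_id, n_splits = nrow(x$results),
    mean_r = x$mean_r, sd_r = sd(x$results$r),
    frac_above = mean(x$results$r > threshold)
  )
}

#' Histogram of a cross-validation distribution
#'
#' @param object A `cv_distribution`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot cv_distribution
#' @export
autoplot.cv_distribution <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_r, linetype = 2) +
    ggplot2::labs(
      x = "mean test correlation r (per random split)", y = "splits",
      title = object$pipeline_id,
      subtitle = sprintf("mean r = %.3f over %d splits", object$mean_r,
                         nrow(object$results))
    )
}
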