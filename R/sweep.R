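# Pipeline-grid enumeration, feature-selection case grids, best-of selection,
# summary statistics, and the selection-optimism audit.

FIXED_FEATURE_GRID <- c(1L, 2L, 3L, 4L, 5L, 10L, 15L, 20L, 30L, 40L,
                        50L, 60L, 70L, 80L, 90L, 100L, 150L, 200L)

#' Define a pipeline configuration space
#'
#' @param parcellations Character vector of parcellation identifiers.
#' @param weightings Connectome weightings.
#' @param groups Subject groups.
#' @param feature_classes Feature classes.
#' @param targets Prediction targets.
#'
#' @return A list of class `config_space`.
#' @export
config_space <- function(parcellations,
                         weightings = c("nos", "md", "fa"),
                         groups = c("mixed", "female", "male"),
                         feature_classes = c("whole", "corr", "pca", "rcp"),
                         targets = c("O", "C", "E", "A", "N")) {
  factors <- list(parcellation = parcellations, weighting = weightings,
                  group = groups, feature_class = feature_classes,
                  target = targets)
  if (any(lengths(factors) == 0)) abort("every factor list must be non-empty")
  structure(factors, class = "config_space")
}

#' Enumerate all pipelines of a configuration space
#'
#' Deterministic Cartesian product over (parcellation x weighting x group x
#' feature class x target) in stable lexicographic order with unique ids.
#'
#' @param space A `config_space`.
#'
#' @return A tibble with one row per pipeline and a `pipeline_id` column.
#' @export
enumerate_pipelines <- function(space) {
  grid <- tidyr::expand_grid(
    parcellation = space$parcellation, weighting = space$weighting,
    group = space$group, feature_class = space$feature_class,
    target = space$target
  )
  dplyr::mutate(grid,
    pipeline_id = paste(.data$parcellation, .data$weighting, .data$group,
                        .data$feature_class, .data$target, sep = "_"),
    .before = 1
  )
}

#' Feature-selection cases for a feature class
#'
#' The corr and pca classes evaluate the fixed feature-count grid
#' \{1, 2, 3, 4, 5, 10, ..., 200\} with the region count appended (so they
#' match the regional-profile class's feature dimension); values above the
#' available feature count are dropped and a value duplicated by the appended
#' region count is marked rather than evaluated twice. The rcp class has one
#' case per region; the whole-brain class has a single case.
#'
#' @param feature_class `"whole"`, `"corr"`, `"pca"`, or `"rcp"`.
#' @param n_rois Region count of the parcellation.
#' @param n_features Available feature count (defaults to the edge count
#'   R(R-1)/2).
#'
#' @return A tibble with columns `case` (ordinal), `param` (k or region
#'   index, NA for whole-brain), and `duplicate`.
#' @export
feature_grid_for <- function(feature_class, n_rois,
                             n_features = n_rois * (n_rois - 1) / 2) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  feature_class <- match.arg(feature_class, c("whole", "corr", "pca", "rcp"))
  if (feature_class == "whole") {
    return(tibble::tibble(case = 1L, param = NA_integer_, duplicate = FALSE))
  }
  if (feature_class == "rcp") {
    return(tibble::tibble(case = seq_len(n_rois), param = seq_len(n_rois),
                          duplicate = FALSE))
  }
  grid <- c(FIXED_FEATURE_GRID[FIXED_FEATURE_GRID <= n_features],
            min(n_rois, n_features))
  tibble::tibble(
    case = seq_along(grid), param = as.integer(grid),
    duplicate = duplicated(grid)
  )
}

#' Pick the best feature-selection case post hoc
#'
#' Selects the case whose distribution has the largest mean over random
#' splits; ties go to the smallest case index. Because the choice uses the
#' test-set results themselves, the returned distribution is an optimistic
#' (post-hoc) upper bound, and is flagged as such.
#'
#' @param case_results Long tibble with columns `case`, `split`, `r` (one row
#'   per feature case and random split).
#'
#' @return List with `best_case`, `mean_r`, the winning `distribution` tibble
#'   (split, r), and `post_hoc = TRUE`.
#' @export
best_of_selection <- function(case_results) {
  if (nrow(case_results) == 0) abort("case_results is empty")
  means <- case_results |>
    dplyr::summarise(mean_r = mean(.data$r), .by = "case") |>
    dplyr::arrange(dplyr::desc(.data$mean_r), .data$case)
  best <- means$case[1]
  list(
    best_case = best, mean_r = means$mean_r[1],
    distribution = dplyr::filter(case_results, .data$case == best)[c("split", "r")],
    per_case_means = means, post_hoc = TRUE
  )
}

#' Cohen's d between two result distributions
#'
#' `(mean_a - mean_b) / s_pooled` with the usual pooled standard deviation.
#'
#' @param dist_a,dist_b Numeric vectors.
#'
#' @return Scalar effect size.
#' @export
cohens_d <- function(dist_a, dist_b) {
  na <- length(dist_a)
  nb <- length(dist_b)
  if (na == 0 || nb == 0) abort("both distributions must be non-empty")
  sp2 <- ((na - 1) * var(dist_a) + (nb - 1) * var(dist_b)) / (na + nb - 2)
  if (!is.finite(sp2) || sp2 <= 0) abort("pooled variance must be positive")
  (mean(dist_a) - mean(dist_b)) / sqrt(sp2)
}

#' Fraction of results above an accuracy threshold
#'
#' @param result_table Tibble with an `r` column.
#' @param threshold Accuracy threshold (results must be strictly greater).
#' @param group_by Optional column name(s) to break the fraction down by.
#'
#' @return Tibble with one row per group level and a `frac_above` column.
#' @export
fraction_above <- function(result_table, threshold = 0.2, group_by = NULL) {
  if (nrow(result_table) == 0) abort("result table is empty")
  result_table |>
    dplyr::summarise(
      n = dplyr::n(), frac_above = mean(.data$r > threshold),
      .by = dplyr::all_of(group_by)
    )
}

#' Run every feature-selection case of one pipeline
#'
#' Convenience driver used by sweeps and the optimism audit: runs the repeated
#' nested CV once per feature case (fixed-case mode).
#'
#' @param config A `pipeline_config` (its `k`/`roi` is overridden per case).
#' @param edges Subjects x edges matrix (or `connectome_population`).
#' @param y Target vector.
#' @param split_scheme A `split_scheme`.
#' @param cases Tibble from [feature_grid_for()]; duplicated cases are
#'   evaluated once and their results reused.
#'
#' @return Long tibble with columns `case`, `param`, `split`, `r`.
#' @export
run_feature_cases <- function(config, edges, y, split_scheme, cases) {
  edges <- as_prepared_edges(edges, config$weighting)
  ran <- list()
  purrr::pmap(cases, function(case, param, duplicate) {
    key <- as.character(param)
    dist <- if (duplicate && !is.null(ran[[key]])) {
      ran[[key]]
    } else {
      cfg <- config
      if (cfg$feature_class %in% c("corr", "pca")) cfg$k <- param
      if (cfg$feature_class == "rcp") cfg$roi <- param
      d <- run_repeated(cfg, edges, y, split_scheme,
                        pipeline_id = sprintf("%s_case%d", cfg$feature_class, case))
      ran[[key]] <<- d
      d
    }
    dplyr::mutate(dist$results, case = case, param = param, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Audit selection-induced optimism
#'
#' Runs two protocols on identical data and splits: (A) post-hoc best-of
#' selection over per-case repeated runs, and (B) in-loop selection of the
#' feature case as an inner-CV hyperparameter alongside alpha. Reports
#' `mean(A) - mean(B)` with a seeded percentile-bootstrap confidence interval
#' over the paired per-split differences. A positive gap with a CI excluding
#' zero demonstrates the optimism of choosing the best configuration on the
#' test results themselves.
#'
#' @param config A `pipeline_config` for a feature class with more than one
#'   selection case.
#' @param edges Subjects x edges matrix (or `connectome_population`).
#' @param y Target vector.
#' @param split_scheme A `split_scheme`.
#' @param cases Tibble from [feature_grid_for()].
#' @param boot_n Bootstrap resamples.
#' @param boot_seed Seed for the bootstrap.
#' @param conf_level CI coverage.
#'
#' @return An object of class `optimism_audit` with the gap, its CI, and both
#'   protocol distributions.
#' @export
optimism_audit <- function(config, edges, y, split_scheme, cases,
                           boot_n = 2000L, boot_seed = 1L, conf_level = 0.95) {
  edges <- as_prepared_edges(edges, config$weighting)
  case_results <- run_feature_cases(config, edges, y, split_scheme, cases)
  best <- best_of_selection(dplyr::select(case_results, -"param"))

  cfg_inner <- config
  cfg_inner$feature_grid <- cases$param[!cases$duplicate]
  inner <- run_repeated(cfg_inner, edges, y, split_scheme,
                        pipeline_id = paste0(config$feature_class, "_inner_select"))

  diffs <- best$distribution$r - inner$results$r
  boot_means <- local_seed(boot_seed, {
    vapply(seq_len(boot_n), function(b) {
      mean(diffs[sample.int(length(diffs), replace = TRUE)])
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  structure(
    list(
      gap = mean(diffs),
      ci = unname(quantile(boot_means, c(a, 1 - a))),
      conf_level = conf_level,
      post_hoc = best, inner = inner, case_results = case_results
    ),
    class = "optimism_audit"
  )
}

#' @export
print.optimism_audit <- function(x, ...) {
  cat(sprintf(
    "<optimism_audit> post-hoc mean r = %.4f, in-loop mean r = %.4f\n  gap = %.4f, %d%% bootstrap CI [%.4f, %.4f]\n",
    x$post_hoc$mean_r, x$inner$mean_r, x$gap, round(100 * x$conf_level),
    x$ci[1], x$ci[2]
  ))
  invisible(x)
}

#' Glance at an optimism audit
#'
#' @param x An `optimism_audit`.
#' @param ... Unused.
#'
#' @return One-row tibble with the two protocol means, the gap, and its CI.
#' @method glance optimism_audit
#' @export
glance.optimism_audit <- function(x, ...) {
  tibble::tibble(
    post_hoc_mean_r = x$post_hoc$mean_r, inner_mean_r = x$inner$mean_r,
    gap = x$gap, ci_lower = x$ci[1], ci_upper = x$ci[2]
  )
}

#' Paired comparison plot for an optimism audit
#'
#' @param object An `optimism_audit`.
#' @param ... Unused.
#'
#' @return A ggplot object contrasting the two protocols' distributions.
#' @method autoplot optimism_audit
#' @export
autoplot.optimism_audit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$post_hoc$distribution, protocol = "post-hoc best-of"),
    dplyr::mutate(object$inner$results, protocol = "in-loop selection")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protocol, y = .data$r)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(y = "mean test correlation r", x = NULL,
                  title = sprintf("selection optimism gap = %.3f", object$gap))
}
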