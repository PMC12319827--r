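# Synthetic-data generators: parcellations, scalar maps, streamlines, cohorts,
# connectome populations, and targets with planted edge signal. Every generator
# is deterministic given its arguments (including the seed).

#' Generator configuration for a synthetic study
#'
#' Bundles the knobs of the synthetic-data module. Defaults emulate the data
#' properties the pipeline is designed for: heavily right-skewed integer
#' streamline counts, bounded microstructural weightings (FA in \[0,1\],
#' MD > 0) that share most of their edgewise structure, Likert-derived integer
#' trait scores in \[0,48\], and a continuous cognition composite.
#'
#' @param grid_shape Integer vector of length 3: voxel grid dimensions.
#' @param n_rois Number of parcellation regions.
#' @param n_subjects Number of subjects.
#' @param fa_md_coupling Share of edgewise variance common to the FA- and
#'   MD-weighted connectomes, in \[0,1\]. At the default 0.95 the per-subject
#'   correlation between vectorized FA and MD matrices is close to 1.
#' @param nos_log_mean,nos_log_sd Mean and SD of the log10 streamline-count
#'   distribution across edges.
#' @param effect_r2 Population variance in the target explained by the planted
#'   edge signal, in \[0,1\].
#' @param seed Integer master seed.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(grid_shape = c(10L, 10L, 10L), n_rois = 20L,
                             n_subjects = 200L, fa_md_coupling = 0.95,
                             nos_log_mean = 1.5, nos_log_sd = 0.5,
                             effect_r2 = 0, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  cfg <- list(
    grid_shape = as.integer(grid_shape),
    n_rois = check_count(n_rois, "n_rois"),
    n_subjects = check_count(n_subjects, "n_subjects"),
    fa_md_coupling = check_unit_interval(fa_md_coupling, "fa_md_coupling"),
    nos_log_mean = as.numeric(nos_log_mean),
    nos_log_sd = as.numeric(nos_log_sd),
    effect_r2 = check_unit_interval(effect_r2, "effect_r2"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "generator_config")
}

# Ellipsoidal foreground mask: convex, so seeded Voronoi regions stay connected.
foreground_mask <- function(grid_shape) {
  d <- as.integer(grid_shape)
  ax <- pmax((d - 1) / 2, 0.5)
  ctr <- (d + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  r2 <- ((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
    ((idx[, 3] - ctr[3]) / ax[3])^2
  array(r2 <= 1, dim = d)
}

#' Generate a synthetic parcellation label volume
#'
#' Partitions the foreground (an ellipsoidal "brain" mask inside the grid) into
#' `n_rois` connected regions by nearest-seed-voxel (Voronoi) assignment from
#' randomly placed seed voxels. Background voxels carry label 0.
#'
#' @param grid_shape Integer vector of length 3.
#' @param n_rois Number of regions; must not exceed the foreground voxel count.
#' @param seed Integer seed.
#'
#' @return A 3D integer array of class `label_volume` with attribute `n_rois`.
#' @export
make_parcellation <- function(grid_shape, n_rois, seed) {
  n_rois <- check_count(n_rois, "n_rois")
  mask <- foreground_mask(grid_shape)
  fg <- which(mask)
  if (n_rois > length(fg)) {
    abort(sprintf("n_rois (%d) exceeds foreground voxel count (%d)", n_rois, length(fg)))
  }
  coords <- arrayInd(fg, dim(mask))
  centers <- local_seed(seed, sort(sample(length(fg), n_rois)))
  cc <- coords[centers, , drop = FALSE]
  # nearest seeded center, ties to the lowest label index
  lab <- integer(length(fg))
  best <- rep(Inf, length(fg))
  for (r in seq_len(n_rois)) {
    d2 <- (coords[, 1] - cc[r, 1])^2 + (coords[, 2] - cc[r, 2])^2 + (coords[, 3] - cc[r, 3])^2
    upd <- d2 < best
    lab[upd] <- r
    best[upd] <- d2[upd]
  }
  vol <- array(0L, dim = dim(mask))
  vol[fg] <- lab
  structure(vol, class = "label_volume", n_rois = n_rois)
}

#' Generate coupled FA and MD scalar volumes
#'
#' FA is drawn per voxel from a Beta distribution (so it stays in \[0,1\]); MD
#' is a decreasing affine function of FA plus Gaussian noise, truncated to stay
#' positive, so the voxelwise FA-MD correlation is strongly negative (about
#' -0.85 at the default noise level). MD is on the 1e-3 mm^2/s scale typical of
#' parenchyma.
#'
#' @param label_volume A `label_volume` (used for grid shape; values are drawn
#'   for every voxel).
#' @param seed Integer seed.
#' @param md_noise_sd SD of the MD noise term, on the same 1e-3 mm^2/s scale.
#'
#' @return A list with 3D double arrays `fa` and `md`.
#' @export
make_scalar_volumes <- function(label_volume, seed, md_noise_sd = 0.08) {
  d <- dim(label_volume)
  n <- prod(d)
  local_seed(seed, {
    fa <- array(rbeta(n, 2, 2), dim = d)
    md <- array(pmax(1.2 - 0.6 * fa + rnorm(n, sd = md_noise_sd), 0.05) * 1e-3, dim = d)
    list(fa = fa, md = md)
  })
}

# Straight-line rasterization between two voxels (inclusive), rounded to the
# grid; consecutive duplicates collapsed. Endpoints are preserved exactly.
rasterize_segment <- function(from, to) {
  n_steps <- max(abs(to - from)) + 1L
  t <- seq(0, 1, length.out = max(n_steps, 2L))
  path <- round(outer(t, to - from) + rep(from, each = length(t)))
  keep <- c(TRUE, rowSums(abs(diff(path))) > 0)
  storage.mode(path) <- "integer"
  path[keep, , drop = FALSE]
}

#' Generate a synthetic streamline set
#'
#' Draws pairs of distinct labeled (foreground) voxels and connects them by
#' straight-line rasterization. Both endpoints therefore always lie in labeled
#' voxels and every path has at least two voxels.
#'
#' @param label_volume A `label_volume`.
#' @param n_streamlines Number of streamlines (>= 0).
#' @param seed Integer seed.
#'
#' @return A list of integer coordinate matrices (one row per voxel), of class
#'   `streamline_set`.
#' @export
make_streamlines <- function(label_volume, n_streamlines, seed) {
  n_streamlines <- check_count(n_streamlines, "n_streamlines", min = 0L)
  fg <- which(label_volume > 0)
  if (length(fg) < 2) abort("label volume has fewer than two labeled voxels")
  coords <- arrayInd(fg, dim(label_volume))
  paths <- local_seed(seed, {
    lapply(seq_len(n_streamlines), function(i) {
      ends <- sample(nrow(coords), 2L)
      rasterize_segment(coords[ends[1], ], coords[ends[2], ])
    })
  })
  structure(paths, class = "streamline_set", grid_shape = dim(label_volume))
}

# Items whose recorded responses are inversely keyed and reversed (4 - x)
# before summation. The inventory itself does not fix which items these are
# for the synthetic instrument; the mask is arbitrary but frozen.
REVERSED_ITEMS <- c(2L, 5L, 8L, 11L)
TRAITS <- c("O", "C", "E", "A", "N")

#' Score trait items
#'
#' Sums 12 Likert items (0-4) after reversing the inversely keyed ones, giving
#' an integer total in \[0,48\].
#'
#' @param responses Integer vector of 12 recorded responses in 0..4.
#' @param reversed Indices of inversely keyed items.
#'
#' @return Integer trait total.
#' @export
score_trait_items <- function(responses, reversed = REVERSED_ITEMS) {
  stopifnot(length(responses) == 12, all(responses %in% 0:4))
  scored <- responses
  scored[reversed] <- 4L - scored[reversed]
  sum(scored)
}

#' Generate a synthetic cohort
#'
#' Each subject gets, per trait, a latent normal score driving 12 Likert item
#' responses (0-4); trait totals are item sums after reversal of the inversely
#' keyed items, hence integers in \[0,48\]. A continuous cognition composite is
#' drawn on the 100 +/- 15 scale. Sexes are balanced when requested.
#'
#' @param n_subjects Number of subjects (>= 2; even when `balanced_sex`).
#' @param balanced_sex Should female and male counts be equal?
#' @param seed Integer seed.
#'
#' @return A tibble of class `cohort` with columns `subject_id`, `sex`,
#'   the five trait totals `O`, `C`, `E`, `A`, `N`, and `cognition`. Recorded
#'   item responses are kept in the `items` attribute (subjects x traits x 12)
#'   and the reversal mask in `reversed_items`.
#' @export
make_cohort <- function(n_subjects, balanced_sex = TRUE, seed = 1L) {
  n <- check_count(n_subjects, "n_subjects", min = 2L)
  if (balanced_sex && n %% 2 != 0) {
    abort("balanced_sex requires an even number of subjects")
  }
  local_seed(seed, {
    sex <- if (balanced_sex) {
      sample(rep(c("female", "male"), each = n / 2))
    } else {
      sample(c("female", "male"), n, replace = TRUE)
    }
    items <- array(0L, dim = c(n, 5, 12), dimnames = list(NULL, TRAITS, NULL))
    scores <- matrix(0L, n, 5, dimnames = list(NULL, TRAITS))
    for (t in seq_along(TRAITS)) {
      z <- rnorm(n)
      scored <- matrix(
        pmin(pmax(round(2 + 0.9 * z + rnorm(n * 12, sd = 0.9)), 0), 4),
        n, 12
      )
      storage.mode(scored) <- "integer"
      recorded <- scored
      recorded[, REVERSED_ITEMS] <- 4L - recorded[, REVERSED_ITEMS]
      items[, t, ] <- recorded
      scores[, t] <- rowSums(scored)
    }
    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = sex,
      O = scores[, "O"], C = scores[, "C"], E = scores[, "E"],
      A = scores[, "A"], N = scores[, "N"],
      cognition = 100 + 15 * rnorm(n)
    )
    structure(cohort, class = c("cohort", class(cohort)),
              items = items, reversed_items = REVERSED_ITEMS)
  })
}

#' Simulate a population of weighted connectomes
#'
#' Draws, for each subject, a symmetric zero-diagonal NOS-, FA- and MD-weighted
#' connectome over `n_rois` regions. NOS edges are rounded log-normal (heavily
#' right-skewed nonnegative integers). FA and MD edges share a latent edgewise
#' factor whose weight is `fa_md_coupling`, so their vectorized matrices are
#' strongly correlated within subject; both also carry stable per-edge
#' population means so the population has low-rank structure across subjects.
#' FA and MD are zeroed on edges with no streamlines (NOS = 0).
#'
#' @param cohort A `cohort` (its row count sets the number of subjects).
#' @param n_rois Number of regions (>= 2).
#' @param config A `generator_config` (coupling, NOS marginal, seed).
#'
#' @return A list of class `connectome_population` with 3D arrays `nos`, `fa`,
#'   `md` of shape `R x R x n_subjects` and the `n_rois` element.
#' @export
simulate_connectomes <- function(cohort, n_rois, config = generator_config()) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  n <- nrow(cohort)
  e <- n_rois * (n_rois - 1L) / 2L
  cpl <- config$fa_md_coupling
  local_seed(config$seed, {
    # per-edge population means (shared across subjects)
    mu_nos <- rnorm(e, config$nos_log_mean, config$nos_log_sd)
    mu_lat <- rnorm(e)
    nos_e <- matrix(0L, n, e)
    fa_e <- matrix(0, n, e)
    md_e <- matrix(0, n, e)
    for (i in seq_len(n)) {
      log_nos <- mu_nos + rnorm(e, sd = 0.3)
      nos_i <- as.integer(round(10^log_nos))
      u <- mu_lat + rnorm(e, sd = 0.5) # shared microstructural latent
      g_fa <- sqrt(cpl) * u + sqrt(1 - cpl) * rnorm(e, sd = sqrt(1.25))
      g_md <- sqrt(cpl) * u + sqrt(1 - cpl) * rnorm(e, sd = sqrt(1.25))
      fa_i <- pmin(pmax(0.45 + 0.10 * g_fa, 0), 1)
      md_i <- pmax(0.8 + 0.15 * g_md, 0.05) * 1e-3
      absent <- nos_i == 0L
      fa_i[absent] <- 0
      md_i[absent] <- 0
      nos_e[i, ] <- nos_i
      fa_e[i, ] <- fa_i
      md_e[i, ] <- md_i
    }
    structure(
      list(
        nos = edge_rows_to_array(nos_e, n_rois),
        fa = edge_rows_to_array(fa_e, n_rois),
        md = edge_rows_to_array(md_e, n_rois),
        n_rois = n_rois, n_subjects = n
      ),
      class = "connectome_population"
    )
  })
}

# subjects x edges matrix -> R x R x subjects array of symmetric, zero-diagonal
# matrices (row-major upper-triangle edge order).
edge_rows_to_array <- function(edge_rows, n_rois) {
  idx <- upper_tri_indices(n_rois)
  arr <- array(0, dim = c(n_rois, n_rois, nrow(edge_rows)))
  for (i in seq_len(nrow(edge_rows))) {
    m <- matrix(0, n_rois, n_rois)
    m[cbind(idx$i, idx$j)] <- edge_rows[i, ]
    arr[, , i] <- m + t(m)
  }
  arr
}

#' Extract the subjects-by-edges matrix of one weighting
#'
#' @param population A `connectome_population`.
#' @param weighting One of `"nos"`, `"fa"`, `"md"`.
#'
#' @return A numeric matrix (subjects x upper-triangle edges, row-major order)
#'   with attribute `n_rois`.
#' @export
edge_matrix <- function(population, weighting = c("nos", "fa", "md")) {
  weighting <- match.arg(weighting)
  arr <- population[[weighting]]
  R <- population$n_rois
  idx <- upper_tri_indices(R)
  n <- dim(arr)[3]
  out <- matrix(0, n, nrow(idx))
  for (i in seq_len(n)) out[i, ] <- arr[, , i][cbind(idx$i, idx$j)]
  attr(out, "n_rois") <- R
  out
}

#' Plant a linear edge-to-target signal into a cohort
#'
#' Replaces the named target with a standardized linear combination of the
#' given connectome edges (Gaussian weights drawn from `seed`) scaled so the
#' population variance explained equals `effect_r2`, plus independent Gaussian
#' noise. Trait targets are mapped affinely to the 0-48 scale and rounded to
#' integers (preserving the instrument's granularity) unless `discretize =
#' FALSE`; cognition stays continuous on the 100 +/- 15 scale. For the NOS
#' weighting the combination is formed on log10-transformed edges, the scale on
#' which the prediction model consumes them.
#'
#' @param connectomes A `connectome_population`.
#' @param cohort A `cohort`.
#' @param target_name One of `"O"`, `"C"`, `"E"`, `"A"`, `"N"`, `"cognition"`.
#' @param signal_edges Upper-triangle edge indices carrying signal (non-empty).
#' @param effect_r2 Variance explained by the signal, in \[0,1\].
#' @param seed Integer seed (weights and noise).
#' @param weighting Weighting whose edges carry the signal.
#' @param discretize Round trait targets to the integer 0-48 scale? Defaults to
#'   `TRUE` for traits and is ignored for cognition.
#'
#' @return The cohort with the target column replaced; the planted combination
#'   is recorded in the `planted_signal` attribute.
#' @export
plant_signal <- function(connectomes, cohort, target_name, signal_edges,
                         effect_r2, seed, weighting = "nos", discretize = TRUE) {
  effect_r2 <- check_unit_interval(effect_r2, "effect_r2")
  if (length(signal_edges) == 0) abort("signal_edges must be non-empty")
  if (!target_name %in% c(TRAITS, "cognition")) {
    abort("target_name must be a trait (O, C, E, A, N) or 'cognition'")
  }
  X <- edge_matrix(connectomes, weighting)
  if (any(signal_edges < 1 | signal_edges > ncol(X))) {
    abort("signal_edges out of range")
  }
  if (weighting == "nos") X <- log10_transform(X)
  n <- nrow(cohort)
  local_seed(seed, {
    w <- rnorm(length(signal_edges))
    s <- as.numeric(X[, signal_edges, drop = FALSE] %*% w)
    s_sd <- sd(s)
    s_std <- if (s_sd > 0) (s - mean(s)) / s_sd else rep(0, n)
    z <- sqrt(effect_r2) * s_std + sqrt(1 - effect_r2) * rnorm(n)
    new_target <- if (target_name == "cognition") {
      100 + 15 * z
    } else if (discretize) {
      as.integer(pmin(pmax(round(24 + 7 * z), 0), 48))
    } else {
      24 + 7 * z
    }
    cohort[[target_name]] <- new_target
    attr(cohort, "planted_signal") <- list(
      target = target_name, edges = signal_edges, weights = w,
      combination = s_std, effect_r2 = effect_r2, weighting = weighting
    )
    cohort
  })
}
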