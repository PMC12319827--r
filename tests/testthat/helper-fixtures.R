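# Shared fixtures, built in code at test time.

# Small study: cohort + connectome population + split scheme.
small_study <- function(n_subjects = 60, n_rois = 10, seed = 101,
                        n_repeats = 3) {
  cohort <- make_cohort(n_subjects, balanced_sex = TRUE, seed = seed)
  config <- generator_config(n_rois = n_rois, n_subjects = n_subjects,
                             seed = seed + 1)
  population <- simulate_connectomes(cohort, n_rois, config)
  scheme <- make_splits(n_subjects, master_seed = seed + 2,
                        n_repeats = n_repeats)
  list(cohort = cohort, population = population, scheme = scheme,
       config = config)
}

# Hand-crafted 5-ROI toy volume on a 5x5x1 grid: voxel (x, y, 1) with x <= 5
# and y <= 5; label = x for y <= 2, 0 (background) for y >= 3 except
# label 5 at (5, 5, 1). Used for exact SC-builder checks.
toy_label_volume <- function() {
  vol <- array(0L, dim = c(5L, 5L, 1L))
  vol[, 1, 1] <- 1:5
  vol[, 2, 1] <- 1:5
  structure(vol, class = "label_volume", n_rois = 5L)
}

# A streamline as a coordinate matrix from literal voxel rows.
sl <- function(...) {
  m <- do.call(rbind, list(...))
  storage.mode(m) <- "integer"
  m
}

# Numerical ridge oracle: minimize the penalized least-squares objective
# directly with BFGS (analytic gradient), independent of the closed form.
ridge_oracle <- function(X, y, alpha) {
  X <- as.matrix(X)
  k <- ncol(X)
  obj <- function(par) {
    beta <- par[seq_len(k)]
    b <- par[k + 1]
    resid <- y - drop(X %*% beta) - b
    sum(resid^2) + alpha * sum(beta^2)
  }
  grad <- function(par) {
    beta <- par[seq_len(k)]
    b <- par[k + 1]
    resid <- y - drop(X %*% beta) - b
    c(-2 * drop(crossprod(X, resid)) + 2 * alpha * beta, -2 * sum(resid))
  }
  fit <- optim(rep(0, k + 1), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(coefficients = fit$par[seq_len(k)], intercept = fit$par[k + 1])
}
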