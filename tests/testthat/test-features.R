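test_that("upper-triangle vectorization uses row-major order and round-trips", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 5
  m[1, 3] <- m[3, 1] <- 7
  m[2, 3] <- m[3, 2] <- 9
  expect_equal(vectorize_upper(m), c(5, 7, 9))
  expect_equal(devectorize_upper(c(5, 7, 9), 3), m)
  # R = 70 regions give the canonical 2,415 edge features
  expect_identical(nrow(upper_tri_indices(70)), 2415L)
  expect_error(vectorize_upper(matrix(1:9, 3)), "symmetric")
  # random round-trip
  v <- rnorm(45)
  expect_equal(vectorize_upper(devectorize_upper(v, 10)), v)
  # edge_index agrees with the enumeration
  idx <- upper_tri_indices(10)
  expect_identical(cbpm:::edge_index(idx$i, idx$j, 10L), seq_len(45L))
})

test_that("log10 transform rescales positives and leaves zeros", {
  expect_equal(log10_transform(c(1000, 0, 1, 10)), c(3, 0, 0, 1))
  expect_error(log10_transform(c(-1, 2)), "nonnegative")
})

test_that("global min-max normalization is one scalar pair over the training set", {
  tr <- matrix(c(2, 4, 6, 10), 2)
  nz <- fit_global_minmax(tr)
  expect_equal(nz$train_min, 2)
  expect_equal(nz$train_max, 10)
  expect_equal(apply_minmax(nz, 6), 0.5)
  expect_equal(apply_minmax(nz, c(2, 10)), c(0, 1))
  # test values outside the training range are not clipped
  expect_equal(apply_minmax(nz, 12), 1.25)
  # globality: only the multiset of values matters, not the column layout
  nz_col <- fit_global_minmax(matrix(c(2, 4, 6, 10), 4, 1))
  expect_equal(nz_col[c("train_min", "train_max")],
               nz[c("train_min", "train_max")])
  expect_error(fit_global_minmax(matrix(3, 2, 2)), "degenerate")
})

test_that("edge selection ranks by absolute training correlation", {
  y <- c(1, 2, 3, 10)
  x <- cbind(e1 = y, e2 = rep(5, 4), e3 = c(2, 1, 2.5, 2.2))
  sel <- select_corr_edges(x, y, k = 1)
  expect_identical(sel$selected_indices, 1L)
  expect_equal(sel$correlations[2], 0) # constant edge
  # exhaustive case: all edges, ordered by |r|
  sel_all <- select_corr_edges(x, y, k = 3)
  expect_identical(sel_all$selected_indices,
                   order(-abs(sel_all$correlations), 1:3))
  # brute-force agreement on a larger random instance
  withr::with_seed(42, {
    X <- matrix(rnorm(50 * 20), 50)
    yy <- rnorm(50)
    brute <- apply(X, 2, function(col) cor(col, yy))
    sel_b <- select_corr_edges(X, yy, k = 7)
    expect_identical(sel_b$selected_indices,
                     order(-abs(brute), seq_along(brute))[1:7])
  })
  # signed variant ranks by raw correlation
  sel_s <- select_corr_edges(cbind(a = -y, b = y * 0.5 + rnorm(4, sd = .1)),
                             y, k = 1, rank_by = "signed")
  expect_identical(sel_s$selected_indices, 2L)
  expect_error(select_corr_edges(x, y, k = 9), "exceeds")
})

test_that("PCA basis is train-centered, orthonormal, variance-ordered", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 8), 30)
    basis <- fit_pca(X, k = 8)
    expect_equal(crossprod(basis$components), diag(8))
    expect_true(all(diff(basis$explained_variance) <= 1e-12))
    # variances sum to total training variance
    expect_equal(sum(basis$explained_variance),
                 sum(apply(X, 2, var)))
    # projecting the training mean gives zero scores
    expect_equal(as.numeric(project_pca(basis, rbind(colMeans(X), colMeans(X)))[1, ]),
                 rep(0, 8))
    # full-rank reconstruction
    scores <- project_pca(basis, X)
    rec <- scores %*% t(basis$components) +
      matrix(basis$center, 30, 8, byrow = TRUE)
    expect_equal(rec, X)
    # rank-1 data: one component carries everything
    d1 <- outer(rnorm(20), c(1, 2, 3))
    b1 <- fit_pca(d1, k = 1)
    expect_equal(sum(b1$explained_variance), sum(apply(d1, 2, var)))
    expect_error(fit_pca(X, k = 30), "exceeds")
  })
})

test_that("regional connectivity profiles keep the zero self-entry", {
  m <- devectorize_upper(c(5, 7, 9), 3)
  expect_equal(extract_rcp(m, 2), c(5, 0, 9))
  expect_equal(extract_rcp(m, 2), m[, 2]) # row = column under symmetry
  expect_error(extract_rcp(m, 4), "out of range")
})

test_that("build_features enforces the order of operations per feature class", {
  study <- small_study(n_subjects = 40, n_rois = 6, seed = 31)
  pop <- study$population
  tr <- 1:30
  te <- 31:40
  y <- study$cohort$cognition

  # whole-brain on R = 3: R(R-1)/2 columns
  small_pop <- simulate_connectomes(make_cohort(20, TRUE, seed = 1), 3,
                                    generator_config(n_rois = 3, n_subjects = 20, seed = 2))
  fb3 <- build_features(pipeline_config("whole", "nos"), small_pop, 1:15, 16:20)
  expect_identical(ncol(fb3$train), 3L)

  # corr class: the normalizer sees only the selected training columns
  X <- matrix(runif(20 * 5, 0, 100), 20)
  yy <- rnorm(20)
  X[, 2] <- yy + rnorm(20, sd = 0.05)       # strongly correlated
  X[, 4] <- -yy + rnorm(20, sd = 0.05)      # strongly anticorrelated
  X[, 2] <- 0.1 + 0.8 * (X[, 2] - min(X[, 2])) / diff(range(X[, 2]))
  X[, 4] <- 0.1 + 0.8 * (X[, 4] - min(X[, 4])) / diff(range(X[, 4]))
  attr(X, "n_rois") <- 5L
  cfg_corr <- pipeline_config("corr", "fa", k = 2)
  fb <- build_features(cfg_corr, X, 1:16, 17:20, train_targets = yy[1:16])
  expect_setequal(fb$transformers$selector$selected_indices, c(2L, 4L))
  sel_cols <- X[1:16, fb$transformers$selector$selected_indices]
  expect_equal(fb$transformers$normalizer$train_min, min(sel_cols))
  expect_equal(fb$transformers$normalizer$train_max, max(sel_cols))
  expect_lt(fb$transformers$normalizer$train_max, 1) # unselected [0,100] ignored

  # PCA class: normalizer fitted on the full vectorized SC before the basis
  cfg_pca <- pipeline_config("pca", "nos", k = 3)
  fbp <- build_features(cfg_pca, pop, tr, te)
  edges_tr <- log10_transform(edge_matrix(pop, "nos"))[tr, ]
  expect_equal(fbp$transformers$normalizer$train_min, min(edges_tr))
  expect_equal(fbp$transformers$normalizer$train_max, max(edges_tr))
  expect_identical(ncol(fbp$train), 3L)

  # rcp class: R columns incl. the constant self column
  cfg_rcp <- pipeline_config("rcp", "md", roi = 4)
  fbr <- build_features(cfg_rcp, pop, tr, te)
  expect_identical(ncol(fbr$train), 6L)
  expect_true(all(fbr$train[, 4] == fbr$train[1, 4])) # self column constant

  # normalized training values always land in [0,1] (PCA scores are projections
  # of normalized data, not themselves bounded)
  for (f in list(fb, fbr)) {
    expect_true(all(f$train >= -1e-12 & f$train <= 1 + 1e-12))
  }

  expect_error(build_features(cfg_rcp, pop, 1:10, 5:12), "overlap")
})

test_that("no fitted transformer state depends on test subjects", {
  study <- small_study(n_subjects = 50, n_rois = 8, seed = 41)
  pop <- study$population
  y <- study$cohort$O
  tr <- 1:40
  te <- 41:50
  edges <- edge_matrix(pop, "nos")
  # mutate test-set connectomes and targets
  edges_mut <- edges
  edges_mut[te, ] <- edges_mut[te, ] * 3 + 11
  attr(edges_mut, "n_rois") <- attr(edges, "n_rois")
  y_mut <- y
  y_mut[te] <- rev(y[te]) + 40

  for (cfg in list(pipeline_config("whole", "nos"),
                   pipeline_config("corr", "nos", k = 5),
                   pipeline_config("pca", "nos", k = 4),
                   pipeline_config("rcp", "nos", roi = 2))) {
    a <- build_features(cfg, edges, tr, te, train_targets = y[tr])
    b <- build_features(cfg, edges_mut, tr, te, train_targets = y_mut[tr])
    expect_identical(a$transformers, b$transformers,
                     label = paste("transformers for", cfg$feature_class))
    expect_identical(a$train, b$train)
  }
})
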