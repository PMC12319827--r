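test_that("parcellations cover the foreground with connected non-empty labels", {
  vol <- make_parcellation(c(10, 10, 10), n_rois = 5, seed = 1)
  fg <- vol[vol > 0]
  expect_setequal(unique(fg), 1:5)
  expect_true(all(tabulate(fg, 5) > 0))
  # identity case: a single region claims every foreground voxel
  vol1 <- make_parcellation(c(6, 6, 6), n_rois = 1, seed = 4)
  expect_true(all(vol1[vol1 > 0] == 1L))
  # determinism
  expect_identical(vol, make_parcellation(c(10, 10, 10), n_rois = 5, seed = 1))
  # six-connected components: each label forms one connected region
  for (r in 1:5) {
    vox <- which(vol == r, arr.ind = TRUE)
    visited <- rep(FALSE, nrow(vox))
    queue <- 1L
    visited[1] <- TRUE
    while (length(queue) > 0) {
      cur <- vox[queue[1], ]
      queue <- queue[-1]
      adj <- which(!visited &
                     abs(vox[, 1] - cur[1]) + abs(vox[, 2] - cur[2]) +
                     abs(vox[, 3] - cur[3]) == 1)
      visited[adj] <- TRUE
      queue <- c(queue, adj)
    }
    expect_true(all(visited), label = sprintf("region %d connected", r))
  }
  expect_error(make_parcellation(c(3, 3, 3), n_rois = 1000, seed = 1),
               "exceeds foreground")
})

test_that("scalar volumes are bounded and anticorrelated voxelwise", {
  vol <- make_parcellation(c(10, 10, 10), n_rois = 5, seed = 2)
  maps <- make_scalar_volumes(vol, seed = 3)
  expect_true(all(maps$fa >= 0 & maps$fa <= 1))
  expect_true(all(maps$md > 0))
  expect_lt(cor(as.vector(maps$fa), as.vector(maps$md)), -0.5)
  expect_identical(maps, make_scalar_volumes(vol, seed = 3))
})

test_that("streamlines are in-label, in-bounds paths of length >= 2", {
  vol <- make_parcellation(c(8, 8, 8), n_rois = 4, seed = 5)
  set <- make_streamlines(vol, 100, seed = 6)
  expect_length(set, 100)
  for (p in set) {
    expect_gte(nrow(p), 2)
    expect_true(all(p >= 1) && all(t(p) <= dim(vol)))
    ends <- p[c(1, nrow(p)), , drop = FALSE]
    expect_true(all(vol[ends] > 0))
  }
  expect_identical(set, make_streamlines(vol, 100, seed = 6))
  empty <- structure(array(0L, c(3, 3, 3)), class = "label_volume", n_rois = 0L)
  expect_error(make_streamlines(empty, 5, seed = 1), "fewer than two labeled")
})

test_that("cohorts have balanced sexes and item-consistent trait scores", {
  cohort <- make_cohort(426, balanced_sex = TRUE, seed = 7)
  expect_identical(sum(cohort$sex == "female"), 213L)
  for (trait in c("O", "C", "E", "A", "N")) {
    expect_true(all(cohort[[trait]] >= 0 & cohort[[trait]] <= 48))
  }
  items <- attr(cohort, "items")
  expect_true(all(items %in% 0:4))
  # scores equal item sums after reversal of the inversely keyed items
  rescored <- vapply(seq_len(nrow(cohort)), function(i) {
    score_trait_items(items[i, "O", ], attr(cohort, "reversed_items"))
  }, numeric(1))
  expect_equal(cohort$O, as.integer(rescored))
  # all-max scored responses with no reversal give the ceiling of 48
  expect_identical(score_trait_items(rep(4L, 12), reversed = integer()), 48L)
  expect_error(make_cohort(11, balanced_sex = TRUE, seed = 1), "even number")
  expect_identical(cohort, make_cohort(426, balanced_sex = TRUE, seed = 7))
})

test_that("simulated connectomes are symmetric, integer-NOS, and FA/MD coupled", {
  study <- small_study(n_subjects = 100, n_rois = 30, seed = 11)
  pop <- study$population
  for (i in c(1, 50, 100)) {
    for (w in c("nos", "fa", "md")) {
      m <- pop[[w]][, , i]
      expect_equal(m, t(m))
      expect_true(all(diag(m) == 0))
      expect_true(all(m >= 0))
    }
    expect_true(all(pop$nos[, , i] == round(pop$nos[, , i])))
    expect_true(all(pop$fa[, , i] <= 1))
  }
  # coupling 0.95 => strongly correlated FA/MD edge vectors within subject
  per_subject_cor <- vapply(seq_len(pop$n_subjects), function(i) {
    cor(vectorize_upper(pop$fa[, , i]), vectorize_upper(pop$md[, , i]))
  }, numeric(1))
  expect_gt(median(per_subject_cor), 0.8)
})

test_that("planted signal hits the requested variance explained", {
  study <- small_study(n_subjects = 400, n_rois = 10, seed = 21, n_repeats = 1)
  pop <- study$population
  edges <- log10_transform(edge_matrix(pop, "nos"))

  # effect_r2 = 0: target independent of the connectomes
  c0 <- plant_signal(pop, study$cohort, "cognition", 1:10, 0, seed = 31)
  s <- attr(c0, "planted_signal")$combination
  expect_lt(abs(cor(c0$cognition, s)), 0.15)

  # noiseless limit, rounding disabled: perfect correlation
  c1 <- plant_signal(pop, study$cohort, "O", 1:10, 1, seed = 32,
                     discretize = FALSE)
  expect_equal(cor(c1$O, attr(c1, "planted_signal")$combination), 1)

  # effect_r2 = 0.25 at n = 400: sample R^2 close to nominal across seeds
  hits <- vapply(1:100, function(sd) {
    ci <- plant_signal(pop, study$cohort, "cognition", 1:10, 0.25, seed = sd)
    si <- attr(ci, "planted_signal")$combination
    r2 <- cor(ci$cognition, si)^2
    r2 >= 0.15 && r2 <= 0.35
  }, logical(1))
  expect_gte(sum(hits), 95)

  # monotone population R^2 in effect_r2
  r2_at <- vapply(c(0, 0.1, 0.25, 0.5), function(e) {
    ci <- plant_signal(pop, study$cohort, "cognition", 1:10, e, seed = 33)
    cor(ci$cognition, attr(ci, "planted_signal")$combination)^2
  }, numeric(1))
  expect_true(all(diff(r2_at) > 0))

  expect_error(plant_signal(pop, study$cohort, "O", integer(), 0.2, seed = 1),
               "non-empty")
  expect_error(plant_signal(pop, study$cohort, "O", 1:3, 1.2, seed = 1),
               "\\[0, 1\\]")
})
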