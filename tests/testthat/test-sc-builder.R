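test_that("endpoint lookup follows the labels and the background rule", {
  vol <- toy_label_volume()
  expect_identical(endpoint_rois(sl(c(3, 1, 1), c(4, 2, 1)), vol), c(3L, 4L))
  # background endpoint: no pair
  expect_null(endpoint_rois(sl(c(1, 1, 1), c(1, 2, 1), c(1, 3, 1)), vol))
  # both endpoints in one region: an (equal) self pair
  expect_identical(endpoint_rois(sl(c(2, 1, 1), c(2, 2, 1)), vol), c(2L, 2L))
  expect_error(endpoint_rois(sl(c(0, 1, 1), c(1, 1, 1)), vol), "out of")
})

test_that("NOS/FA/MD builders match hand-computed references exactly", {
  vol <- toy_label_volume()
  fa_vol <- array(0, dim = dim(vol))
  fa_vol[1, 1, 1] <- 0.2
  fa_vol[2, 1, 1] <- 0.4
  fa_vol[1, 2, 1] <- 0.4
  fa_vol[2, 2, 1] <- 0.6
  fa_vol[4, 1, 1] <- 0.1
  fa_vol[5, 1, 1] <- 0.3
  fa_vol[5, 2, 1] <- 0.5
  set <- structure(list(
    sl(c(1, 1, 1), c(2, 1, 1)),                 # regions 1-2, mean FA 0.3
    sl(c(1, 2, 1), c(2, 2, 1)),                 # regions 1-2, mean FA 0.5
    sl(c(3, 1, 1), c(3, 2, 1)),                 # self-connection in region 3
    sl(c(1, 1, 1), c(1, 2, 1), c(1, 3, 1)),     # ends in background: dropped
    sl(c(4, 1, 1), c(5, 1, 1), c(5, 2, 1))      # regions 4-5, mean FA 0.3
  ), class = "streamline_set")

  nos <- build_nos(set, vol)
  expected_nos <- matrix(0, 5, 5)
  expected_nos[1, 2] <- expected_nos[2, 1] <- 2
  expected_nos[4, 5] <- expected_nos[5, 4] <- 1
  expect_equal(unclass(nos), expected_nos, ignore_attr = TRUE)
  expect_identical(attr(nos, "n_background_dropped"), 1L)
  # bookkeeping: counted pairs + self + background = total streamlines
  expect_identical(sum(nos) / 2 + 1 + 1, 5)

  fa <- build_microstructural(set, vol, fa_vol, "fa")
  expected_fa <- matrix(0, 5, 5)
  expected_fa[1, 2] <- expected_fa[2, 1] <- 0.4  # mean of 0.3 and 0.5
  expected_fa[4, 5] <- expected_fa[5, 4] <- 0.3  # single streamline
  expect_equal(unclass(fa), expected_fa, ignore_attr = TRUE)

  md <- build_microstructural(set, vol, fa_vol * 1e-3, "md")
  expect_equal(unclass(md), expected_fa * 1e-3, ignore_attr = TRUE)

  # empty set: all-zero matrix
  empty <- structure(list(), class = "streamline_set")
  expect_true(all(build_nos(empty, vol) == 0))
})

test_that("streamline means count revisited voxels once", {
  vol <- toy_label_volume()
  scalar <- array(0, dim = dim(vol))
  scalar[1, 1, 1] <- 0.1
  scalar[2, 1, 1] <- 0.5
  # two-voxel path
  expect_equal(streamline_mean_scalar(sl(c(1, 1, 1), c(2, 1, 1)), scalar), 0.3)
  # revisiting path: count-once gives 0.3, not the per-visit 0.2333...
  revisit <- sl(c(1, 1, 1), c(2, 1, 1), c(1, 1, 1))
  expect_equal(streamline_mean_scalar(revisit, scalar), 0.3)
  expect_false(isTRUE(all.equal(streamline_mean_scalar(revisit, scalar),
                                mean(c(0.1, 0.5, 0.1)))))
  # constant volume gives the constant
  expect_equal(streamline_mean_scalar(revisit, array(0.7, dim(vol))), 0.7)
})

test_that("NOS counts ignore region size and commute with relabeling", {
  vol <- toy_label_volume()
  set <- make_streamlines(vol, 40, seed = 9)
  nos <- build_nos(set, vol)

  # doubling region 1's voxel count without touching any streamline
  bigger <- vol
  bigger[1, 4, 1] <- 1L
  bigger[1, 5, 1] <- 1L
  expect_equal(unclass(build_nos(set, bigger)), unclass(nos),
               ignore_attr = TRUE)

  # permutation equivariance: relabeled volume gives P %*% M %*% t(P)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  relabeled <- vol
  relabeled[vol > 0] <- perm[vol[vol > 0]]
  attr(relabeled, "n_rois") <- 5L
  nos_perm <- build_nos(set, relabeled)
  expect_equal(unclass(nos_perm)[perm, perm], unclass(nos),
               ignore_attr = TRUE)
})

test_that("builders always emit symmetric zero-diagonal nonnegative matrices", {
  vol <- make_parcellation(c(8, 8, 8), 5, seed = 14)
  maps <- make_scalar_volumes(vol, seed = 15)
  set <- make_streamlines(vol, 200, seed = 16)
  for (b in list(build_nos(set, vol),
                 build_microstructural(set, vol, maps$fa, "fa"),
                 build_microstructural(set, vol, maps$md, "md"))) {
    m <- unclass(b)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
})

test_that("connectome round-trips through the text format", {
  vol <- toy_label_volume()
  set <- make_streamlines(vol, 30, seed = 17)
  nos <- build_nos(set, vol, parcellation_id = "toy5")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(nos, path)
  back <- read_connectome(path)
  expect_equal(unclass(back), unclass(nos), ignore_attr = TRUE)
  expect_identical(attr(back, "weighting"), "nos")
  expect_identical(attr(back, "parcellation_id"), "toy5")

  sl_path <- withr::local_tempfile(fileext = ".txt")
  write_streamlines(set, sl_path)
  expect_equal(unclass(read_streamlines(sl_path)), unclass(set),
               ignore_attr = TRUE)

  vol_path <- withr::local_tempfile(fileext = ".txt")
  write_volume(vol, vol_path)
  expect_equal(unclass(read_volume(vol_path, label = TRUE)), unclass(vol),
               ignore_attr = TRUE)
})
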