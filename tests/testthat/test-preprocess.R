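# Normalization, resampling, stacking, one-hot encoding.

test_that("min-max normalization follows the rescaling formula", {
  r <- minmax_normalize(c(2, 4, 6))
  expect_equal(r$volume, c(0, 0.5, 1))
  expect_equal(r$params$x_min, 2)
  expect_equal(r$params$x_max, 6)

  set.seed(1)
  v <- array(stats::rnorm(5^3, mean = 30, sd = 9), c(5, 5, 5))
  out <- minmax_normalize(v)$volume
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  expect_warning(r0 <- minmax_normalize(array(7, c(2, 2, 2))), "constant")
  expect_true(all(r0$volume == 0))
})

test_that("z-score normalization gives zero mean, unit population sd", {
  r <- zscore_normalize(c(1, 3))
  expect_equal(r$volume, c(-1, 1))
  set.seed(2)
  v <- stats::runif(300, 10, 50)
  out <- zscore_normalize(v)$volume
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sqrt(mean((out - mean(out))^2)) - 1), 1e-6)
  expect_true(all(zscore_normalize(rep(4, 10))$volume == 0))
})

test_that("resampling hits the BraTS target shape and is identity at source shape", {
  co <- tiny_cohort(n = 1L, shape = c(60L, 60L, 39L))
  ph <- generate_phantom(co$cfg, 1L)
  small <- resize_volume(ph$volumes$flair, c(32, 32, 32))
  expect_identical(dim(small), c(32L, 32L, 32L))

  v <- array(stats::rnorm(8 * 7 * 6), c(8, 7, 6))
  expect_identical(resize_volume(v, c(8, 7, 6)), v)
  expect_error(resize_volume(matrix(1, 3, 3), c(2, 2, 2)), "3D")
})

test_that("full-size 240x240x155 volumes resample to 128 cubed", {
  cfg <- phantom_config(shape = c(240L, 240L, 155L), n_subjects = 1L,
                        noise_sd = 0, seed = 11L)
  ph <- generate_phantom(cfg, 1L)
  out <- resize_volume(ph$volumes$t1ce, c(128, 128, 128))
  expect_identical(dim(out), c(128L, 128L, 128L))
  lab <- resize_volume(ph$mask, c(128, 128, 128), kind = "label")
  expect_identical(dim(lab), c(128L, 128L, 128L))
  expect_true(all(unique(as.integer(lab)) %in% unique(as.integer(ph$mask))))
})

test_that("trilinear resampling approximately preserves mean intensity", {
  # smooth phantom: noiseless ellipsoids
  cfg <- phantom_config(shape = c(48L, 48L, 48L), n_subjects = 1L,
                        noise_sd = 0, seed = 3L)
  ph <- generate_phantom(cfg, 1L)
  for (m in c("flair", "t2")) {
    v <- ph$volumes[[m]]
    out <- resize_volume(v, c(32, 32, 32))
    expect_lt(abs(mean(out) - mean(v)) / mean(v), 0.05)
  }
})

test_that("nearest-neighbour label resampling never invents labels", {
  set.seed(4)
  lab <- array(sample(0:3, 20^3, replace = TRUE, prob = c(.9, .03, .04, .03)),
               c(20, 20, 20))
  for (target in list(c(13, 9, 20), c(32, 32, 32), c(5, 5, 5))) {
    out <- resize_volume(lab, target, kind = "label")
    expect_identical(dim(out), as.integer(target))
    expect_true(all(unique(as.integer(out)) %in% unique(as.integer(lab))))
  }
})

test_that("modality stacking uses the fixed channel order", {
  vols <- lapply(c(t1 = 1, t1ce = 2, t2 = 3, flair = 4), function(k)
    array(k + stats::rnorm(4^3, sd = .1), c(4, 4, 4)))
  x <- stack_modalities(vols)
  expect_identical(dim(x), c(4L, 4L, 4L, 4L))
  expect_equal(x[, , , 1], vols$t1)
  expect_equal(x[, , , 4], vols$flair)
  expect_error(stack_modalities(vols[c("t1", "t2", "flair")]), "t1ce")
  vols$t2 <- array(0, c(4, 4, 5))
  expect_error(stack_modalities(vols), "differ")
})

test_that("one-hot encoding is exact and inverts through argmax", {
  m <- array(c(0L, 1L, 2L, 3L, 3L, 0L, 2L, 1L), c(2, 2, 2))
  oh <- one_hot_encode(m)
  expect_identical(dim(oh), c(2L, 2L, 2L, 4L))
  expect_true(all(apply(oh, 1:3, sum) == 1))
  expect_equal(oh[2, 2, 1, ], c(0, 0, 0, 1)) # voxel labelled 3
  expect_identical(decode_one_hot(oh), m)

  z <- array(0L, c(3, 3, 3))
  ohz <- one_hot_encode(z)
  expect_true(all(ohz[, , , 1] == 1) && all(ohz[, , , 2:4] == 0))
  expect_error(one_hot_encode(array(4L, c(2, 2, 2)), n_classes = 4L), "outside")
})

test_that("preprocess_subject runs resize -> normalize -> stack and encodes labels", {
  co <- tiny_cohort(n = 1L, shape = c(24L, 24L, 20L))
  sub <- read_subject(brats_subject_record(co$dir, co$ids[1L]))
  pp <- preprocess_subject(sub, target_shape = c(16L, 16L, 16L))
  expect_identical(dim(pp$x), c(16L, 16L, 16L, 4L))
  # minmax after resizing guarantees the unit range per channel
  for (c in 1:4) {
    expect_equal(min(pp$x[, , , c]), 0)
    expect_equal(max(pp$x[, , , c]), 1)
  }
  expect_true(all(pp$mask %in% 0:3))
  expect_identical(decode_one_hot(pp$y), pp$mask)
})
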