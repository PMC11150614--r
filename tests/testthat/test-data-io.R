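# NetPBM round trips, dataset layouts and split rules, patch sampling,
# rotation augmentation, pyramid downsampling, thresholding.

test_that("NetPBM round trip preserves 8-bit images exactly", {
  set.seed(61)
  img <- array(sample(0:255, 16 * 12 * 3, TRUE) / 255, dim = c(16, 12, 3))
  grey <- matrix(sample(0:255, 15 * 9, TRUE) / 255, 15, 9)
  for (ascii in c(FALSE, TRUE)) {
    p1 <- tempfile(fileext = ".ppm"); p2 <- tempfile(fileext = ".pgm")
    write_pnm(img, p1, ascii = ascii)
    write_pnm(grey, p2, ascii = ascii)
    expect_equal(read_pnm(p1), img, tolerance = 1e-12)
    expect_equal(read_pnm(p2), grey, tolerance = 1e-12)
  }
})

test_that("record round trip preserves mask bits exactly", {
  rec <- generate_phantom(phantom_spec(seed = 2, height = 48L, width = 48L))
  root <- tempfile()
  write_record(rec, root)
  got <- load_dataset(dataset_spec("phantom", root))
  expect_length(got, 1)
  expect_identical(got[[1]]$mask, rec$mask)
  expect_identical(got[[1]]$fov, rec$fov)
  expect_lt(max(abs(got[[1]]$image - rec$image)), 1 / 254)  # 8-bit quantisation
})

write_fake_dataset <- function(n, root, hw = 40L) {
  for (i in seq_len(n)) {
    rec <- generate_phantom(phantom_spec(seed = 1000 + i, height = hw, width = hw))
    rec$id <- sprintf("im%03d", i)
    write_record(rec, root)
  }
  root
}

test_that("canonical split rules per dataset", {
  root <- write_fake_dataset(40, tempfile())
  drive <- load_dataset(dataset_spec("drive", root))
  expect_equal(sum(vapply(drive, function(r) r$split, "") == "train"), 20)
  expect_equal(sum(vapply(drive, function(r) r$split, "") == "test"), 20)

  root2 <- write_fake_dataset(28, tempfile())
  chase <- load_dataset(dataset_spec("chasedb1", root2))
  ids <- vapply(chase, function(r) r$id, "")
  spl <- vapply(chase, function(r) r$split, "")
  expect_equal(sum(spl == "test"), 8)
  expect_identical(sort(ids[spl == "test"]), sort(ids)[21:28])

  root3 <- write_fake_dataset(20, tempfile())
  half <- load_dataset(dataset_spec("stare", root3, stare_scheme = "half"))
  expect_equal(sum(vapply(half, function(r) r$split, "") == "test"), 10)
  loo <- load_dataset(dataset_spec("stare", root3, stare_scheme = "loo",
                                   stare_fold = 0))
  spl3 <- vapply(loo, function(r) r$split, "")
  expect_equal(sum(spl3 == "test"), 1)
  expect_equal(sum(spl3 == "train"), 19)
  expect_equal(spl3[1], "test")
})

test_that("HRF records are downsampled twice (4x total)", {
  root <- write_fake_dataset(18, tempfile(), hw = 64L)
  hrf <- load_dataset(dataset_spec("hrf", root))
  spl <- vapply(hrf, function(r) r$split, "")
  expect_equal(sum(spl == "train"), 15)
  expect_equal(sum(spl == "test"), 3)
  expect_equal(dim(hrf[[1]]$image), c(16, 16, 3))
  expect_true(all(hrf[[1]]$mask %in% c(0L, 1L)))
})

test_that("missing masks are a hard error naming the id", {
  root <- write_fake_dataset(3, tempfile())
  file.remove(file.path(root, "masks", "im002.pgm"))
  expect_error(load_dataset(dataset_spec("phantom", root)), "im002")
})

test_that("train/validation split sizes, disjointness and determinism", {
  recs <- lapply(1:20, function(i) list(id = sprintf("r%02d", i)))
  sp <- split_train_val(recs, 0.1, seed = 3)
  expect_length(sp$train, 18); expect_length(sp$val, 2)
  expect_length(intersect(vapply(sp$train, `[[`, "", "id"),
                          vapply(sp$val, `[[`, "", "id")), 0)
  sp2 <- split_train_val(recs, 0.1, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_val(recs, 0), class = "vn_input_error")
})

test_that("patch sampling is uniform over valid top-left corners", {
  rec <- list(image = array(0, dim = c(40, 40, 3)), mask = matrix(0L, 40, 40),
              fov = NULL)
  # 40 - 33 + 1 = 8 positions per axis -> 64 equally likely cells
  counts <- matrix(0, 8, 8)
  vesselnet:::with_seed(99, {
    for (i in 1:10000) {
      p <- sample_patch(rec, 33)
      counts[p$y0, p$x0] <- counts[p$y0, p$x0] + 1
    }
  })
  expect_true(all(counts > 0))
  pv <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(pv, 0.01)
  # boundary: patch of the full image size
  pf <- vesselnet:::with_seed(1, sample_patch(rec, 40))
  expect_equal(c(pf$y0, pf$x0), c(1, 1))
  expect_error(sample_patch(rec, 41), class = "vn_input_error")
})

test_that("rotation keeps masks binary and is near-invertible on a disc", {
  disc <- vesselnet:::fov_disc(64, 64, 0.6)
  img <- array(rep(disc / 2 + 0.25, 3), dim = c(64, 64, 3))
  r0 <- vesselnet:::rotate_raster(disc, 0, "nearest")
  expect_identical(r0, disc)
  vesselnet:::with_seed(7, {
    for (i in 1:5) {
      aug <- augment_rotation(img, disc)
      expect_true(all(aug$mask %in% c(0, 1)))
      expect_true(abs(aug$angle) <= 20)
    }
  })
  fwd <- vesselnet:::rotate_raster(disc, 20, "nearest")
  back <- vesselnet:::rotate_raster(fwd, -20, "nearest")
  iou <- sum(back & disc) / sum(back | disc)
  expect_gte(iou, 0.95)
})

test_that("downsampling halves dimensions and re-binarises masks", {
  rec <- list(image = array(runif(100 * 88 * 3), dim = c(100, 88, 3)),
              mask = matrix(rep(c(0L, 1L), length.out = 100 * 88), 100, 88),
              fov = NULL)
  d2 <- downsample_record(rec, times = 2)
  expect_equal(dim(d2$image), c(25, 22, 3))      # same arithmetic as 3504 -> 876
  expect_true(all(d2$mask %in% c(0L, 1L)))
  d0 <- downsample_record(rec, times = 0)
  expect_identical(d0, rec)
})

test_that("thresholding conventions", {
  p <- matrix(c(0.4, 0.5, 0.6, 0.1), 2)
  expect_equal(threshold_map(p, 0.5), matrix(c(0L, 1L, 1L, 0L), 2))
  expect_true(all(threshold_map(p, 0) == 1))
  expect_true(all(threshold_map(p, 0.99) == 0))
})
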