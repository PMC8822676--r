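test_that("in-plane resampling lands exactly on a 1 mm grid", {
  # identity at 1 mm
  vol <- toy_volume(c(30, 30, 2), spacing = c(1, 1))
  vol$voxels[] <- rnorm(length(vol$voxels))
  expect_identical(resample_inplane(vol)$voxels, vol$voxels)
  # constant image stays constant, dimensions scale by the spacing
  vol2 <- toy_volume(c(100, 100, 1), spacing = c(2, 2), hu = 77)
  out <- resample_inplane(vol2)
  expect_equal(dim(out$voxels)[1:2], c(200, 200))
  expect_equal(out$pixel_spacing, c(1, 1))
  expect_true(all(out$voxels == 77))
  # bilinear interpolation reproduces a linear ramp
  vol3 <- toy_volume(c(50, 40, 1), spacing = c(1.6, 1.3))
  ramp <- outer(seq_len(50) - 1, seq_len(40) - 1,
                function(r, c) 3 + 0.7 * r + 1.9 * c)
  vol3$voxels[, , 1] <- ramp
  out3 <- resample_inplane(vol3)
  d3 <- dim(out3$voxels)
  # expected: same affine function sampled at 1 mm, i.e. r/1.6, c/1.3 steps
  expected <- outer(seq_len(d3[1]) - 1, seq_len(d3[2]) - 1,
                    function(r, c) 3 + 0.7 * r / 1.6 + 1.9 * c / 1.3)
  interior <- out3$voxels[1:(49 * 1.6), 1:(39 * 1.3), 1] -
    expected[1:(49 * 1.6), 1:(39 * 1.3)]
  expect_lt(max(abs(interior)), 1e-6)
  # applying twice equals once (idempotence at 1 mm)
  expect_identical(resample_inplane(out3)$voxels, out3$voxels)
  # nonpositive spacing rejected
  bad <- vol3; bad$pixel_spacing <- c(0, 1)
  expect_error(resample_inplane(bad), "positive")
})

test_that("mask resampling is nearest-neighbor and stays binary", {
  m <- array(FALSE, c(20, 20, 1))
  m[6:10, 6:10, 1] <- TRUE # 10 mm square at 2 mm spacing
  out <- resample_mask_inplane(m, c(2, 2))
  expect_type(out, "logical")
  expect_equal(dim(out)[1:2], c(40, 40))
  # area preserved within a one-pixel ring: 100 mm^2, ring <= perimeter
  expect_lt(abs(sum(out) - 100), 4 * 10 + 4)
  expect_equal(sum(resample_mask_inplane(array(FALSE, c(8, 8, 1)), c(2, 2))), 0)
})

test_that("center_crop takes the central window and pads with air", {
  img <- matrix(rnorm(256^2), 256, 256)
  expect_identical(center_crop(img), img)
  big <- matrix(as.numeric(seq_len(512^2)), 512, 512)
  out <- center_crop(big)
  expect_identical(out, big[129:384, 129:384]) # offsets floor((512-256)/2)
  small <- matrix(5, 200, 200)
  out2 <- center_crop(small)
  expect_equal(dim(out2), c(256, 256))
  expect_true(all(out2[1:28, ] == -1000))
  expect_true(all(out2[29:228, 29:228] == 5))
  expect_true(all(out2[229:256, ] == -1000))
})

test_that("window normalization maps the W/L interval onto [0, 1]", {
  tissue <- window_preset("tissue")
  expect_equal(window_normalize(-160, tissue), 0)
  expect_equal(window_normalize(240, tissue), 1)
  expect_equal(window_normalize(40, tissue), 0.5)
  bone <- window_preset("bone")
  expect_equal(window_normalize(1400, bone), 1)  # L + W/2
  expect_equal(window_normalize(-600, bone), 0)  # L - W/2
  expect_equal(window_normalize(-2000, tissue), 0) # clamp below
  expect_equal(window_normalize(-2000, bone), 0)
  expect_error(window_preset(width = -1, level = 0), "positive")
  # monotone nondecreasing; invariant to shifting data and level together
  hu <- seq(-1200, 2000, by = 7)
  v <- window_normalize(hu, tissue)
  expect_true(all(diff(v) >= 0))
  shifted <- window_normalize(hu + 100, window_preset(width = 400, level = 140))
  expect_equal(shifted, v)
})

test_that("slice selection keeps positives plus every 20th empty slice", {
  lab <- array(FALSE, c(4, 4, 100))
  lab[2, 2, 41:50] <- TRUE # organ on slices 41..50 (1-based)
  idx <- select_training_slices(lab)
  # oracle: enumerate the empty-slice list and take positions 1, 21, 41, ...
  empty <- setdiff(1:100, 41:50)
  expect_equal(idx, sort(c(41:50, empty[seq(1, length(empty), by = 20)])))
  expect_length(idx, 15)
  # organ everywhere: all slices, nothing subsampled
  lab2 <- array(TRUE, c(2, 2, 30))
  expect_equal(select_training_slices(lab2), 1:30)
  # all-empty volume: empty selection plus the exclusion signal
  lab3 <- array(FALSE, c(2, 2, 10))
  out <- select_training_slices(lab3)
  expect_length(out, 0)
  expect_true(attr(out, "organ_absent"))
})

test_that("empty-slice count always equals ceil(n_empty / 20)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    lab <- array(FALSE, c(2, 2, n))
    pos <- sort(sample(n, sample(1:min(8, n), 1)))
    lab[1, 1, pos] <- TRUE
    idx <- select_training_slices(lab)
    expect_true(all(pos %in% idx))          # superset of positives
    expect_true(all(idx %in% seq_len(n)))   # subset of all slices
    expect_equal(sum(!(idx %in% pos)), ceiling((n - length(pos)) / 20))
  }
})

make_toy_patient <- function(id, d = c(40, 40, 6), organ_slices = 2:4) {
  vol <- toy_volume(d, spacing = c(1.2, 1.2), hu = 40)
  vol$patient_id <- id
  mask <- array(FALSE, d)
  mask[15:25, 15:25, organ_slices] <- TRUE
  vol$voxels[mask] <- 200
  list(ct = vol, ss = structure_set(list(stem = mask), vol), id = id)
}

test_that("dataset split is at patient granularity with no leakage", {
  pts <- lapply(sprintf("P%02d", 1:20), make_toy_patient)
  ds <- build_dataset(pts, organ_config("stem"), size = 64)
  train_ids <- unique(vapply(ds$train, `[[`, "", "patient_id"))
  val_ids <- unique(vapply(ds$validation, `[[`, "", "patient_id"))
  expect_length(val_ids, 3)  # ceil(0.15 * 20)
  expect_length(train_ids, 17)
  expect_length(intersect(train_ids, val_ids), 0)
  # last patients (stable order) form the validation set
  expect_setequal(val_ids, sprintf("P%02d", 18:20))
  # sample invariants: 64 x 64 images in [0,1], binary labels
  s <- ds$train[[1]]
  expect_equal(dim(s$image), c(64, 64))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_type(s$label, "logical")
})

test_that("patients lacking the organ are excluded; <2 eligible rejects", {
  pts <- lapply(sprintf("P%02d", 1:5), make_toy_patient)
  # empty the organ for one patient
  pts[[2]]$ss$rois$stem$mask[] <- FALSE
  ds <- build_dataset(pts, organ_config("stem"), size = 64)
  ids <- unique(vapply(c(ds$train, ds$validation), `[[`, "", "patient_id"))
  expect_false("P02" %in% ids)
  expect_length(ids, 4)
  expect_error(build_dataset(pts[1:2], organ_config("stem"), size = 64),
               "at least 2")
})
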