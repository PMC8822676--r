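test_that("stored pixel values are rescaled into HU on read", {
  # slope 1, intercept -2048 storage: writing integer HU recovers it exactly
  vol <- toy_volume(c(16, 16, 3))
  vol$voxels[] <- sample(-1000:2000, length(vol$voxels), replace = TRUE)
  td <- withr::local_tempdir()
  oarseg:::write_ct_series(vol, td)
  back <- read_ct_series(td)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$pixel_spacing, vol$pixel_spacing)
})

test_that("slices are sorted by patient z regardless of filename order", {
  vol <- toy_volume(c(12, 12, 3))
  for (s in 1:3) vol$voxels[, , s] <- s * 100
  td <- withr::local_tempdir()
  paths <- oarseg:::write_ct_series(vol, td)
  # shuffle: rename so filename order disagrees with z order
  shuffled <- file.path(td, c("b.dcm", "c.dcm", "a.dcm"))
  file.rename(paths, shuffled)
  back <- read_ct_series(td)
  # oracle: expected order is ascending z, independent of names
  expect_equal(back$slice_positions, sort(vol$slice_positions))
  expect_equal(as.vector(back$voxels[1, 1, ]), c(100, 200, 300))
  expect_equal(back$sop_instance_uids, vol$sop_instance_uids)
})

test_that("a 512 x 512 matrix with 2.5 mm slices is reproduced verbatim", {
  vol <- ct_volume(
    voxels = array(0, c(512, 512, 2)),
    pixel_spacing = c(0.977, 0.977), slice_thickness = 2.5,
    slice_positions = c(0, 2.5), origin = c(-250, -250, 0),
    sop_instance_uids = c("1.9.1", "1.9.2"), series_uid = "1.9.0",
    frame_of_reference_uid = "1.9.5", study_uid = "1.9.6", patient_id = "P")
  td <- withr::local_tempdir()
  oarseg:::write_ct_series(vol, td)
  back <- read_ct_series(td)
  expect_equal(dim(back$voxels), c(512, 512, 2))
  expect_equal(back$slice_thickness, 2.5)
  expect_equal(diff(back$slice_positions), 2.5)
})

test_that("malformed series are rejected with informative errors", {
  vol <- toy_volume(c(12, 12, 3))
  td <- withr::local_tempdir()
  oarseg:::write_ct_series(vol, td)
  # mixed series identifiers
  other <- vol
  other$series_uid <- "9.9.9"
  other$sop_instance_uids <- sprintf("9.9.9.%d", 1:3)
  td2 <- withr::local_tempdir()
  oarseg:::write_ct_series(vol, td2)
  f <- oarseg:::write_ct_series(other, withr::local_tempdir())
  file.copy(f[1], file.path(td2, "extra.dcm"))
  expect_error(read_ct_series(td2), "mixed series")
  # non-uniform gap rejected at volume construction
  expect_error(ct_volume(vol$voxels, vol$pixel_spacing, 2.5, c(0, 2.5, 5.2),
                         c(0, 0, 0), sop_instance_uids = vol$sop_instance_uids),
               "non-uniform")
  # ... and at read time if the files disagree on z
  vol4 <- vol
  vol4$slice_positions[3] <- 5.2 # bypasses the constructor deliberately
  td4 <- withr::local_tempdir()
  oarseg:::write_ct_series(vol4, td4)
  expect_error(read_ct_series(td4), "non-uniform")
  # fewer than 2 slices
  expect_error(read_ct_series(withr::local_tempdir()), "at least 2")
})

test_that("missing rescale metadata is rejected", {
  vol <- toy_volume(c(12, 12, 2))
  td <- withr::local_tempdir()
  paths <- oarseg:::write_ct_series(vol, td)
  # strip the rescale elements from one file by rewriting it without them
  raw <- oarseg:::dcm_read_file(paths[1])
  el <- raw$data
  el[["00281052"]] <- NULL
  el[["00281053"]] <- NULL
  ds <- raw(0)
  for (key in names(el)) {
    g <- strtoi(substr(key, 1, 4), 16L)
    e <- strtoi(substr(key, 5, 8), 16L)
    vr <- oarseg:::DCM_DICT[[key]]
    v <- el[[key]]
    if (vr == "OW") v <- v else if (vr == "UI" || vr == "CS" || vr == "LO" ||
                                    vr == "PN") v <- v
    ds <- c(ds, oarseg:::dcm_element(g, e, vr, v))
  }
  oarseg:::dcm_write_file(paths[1], oarseg:::UID_CT_IMAGE, "1.2.3.1", ds)
  expect_error(read_ct_series(td), "rescale")
})

test_that("contour rasterization matches the pixel-center even-odd oracle", {
  vol <- toy_volume(c(20, 20, 1), spacing = c(1, 1))
  # 10 mm square with corners at (0,0)...(10,10) mm on the 1 mm grid:
  # centers at integer mm, interior centers 1..10 -> hmm, oracle decides
  sq <- contour_polygon(1, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 0))
  mask <- contours_to_mask(list(sq), vol)
  oracle <- oracle_fill_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10), 20, 20)
  expect_identical(mask[, , 1], oracle)
  expect_equal(sum(mask), 100) # exactly 100 pixel centers inside
  # empty polygon list
  expect_equal(sum(contours_to_mask(list(), vol)), 0)
  # two disjoint squares union, areas additive
  sq2 <- contour_polygon(1, cbind(c(12, 17, 17, 12), c(12, 12, 17, 17), 0))
  m2 <- contours_to_mask(list(sq, sq2), vol)
  expect_equal(sum(m2), 100 + 25)
  lab <- oracle_label_components(m2)
  expect_equal(max(lab), 2)
})

test_that("rasterization equals the brute-force oracle on random convex polygons", {
  set.seed(101)
  vol <- toy_volume(c(48, 48, 1))
  for (i in 1:100) {
    p <- random_convex_polygon(48, 48)
    mask <- contours_to_mask(
      list(contour_polygon(1, cbind(p$x, p$y, 0))), vol)
    oracle <- oracle_fill_polygon(p$x, p$y, 48, 48)
    expect_identical(mask[, , 1], oracle)
  }
})

test_that("mask_to_contours traces boundaries that re-rasterize faithfully", {
  vol <- toy_volume(c(24, 24, 2))
  expect_length(mask_to_contours(array(FALSE, dim(vol$voxels)), vol), 0)
  # 10x10 filled square: shoelace area of the traced polygon ~ 100 mm^2
  mask <- array(FALSE, dim(vol$voxels))
  mask[6:15, 6:15, 1] <- TRUE
  polys <- mask_to_contours(mask, vol)
  expect_length(polys, 1)
  pts <- polys[[1]]$points
  n <- nrow(pts)
  area <- abs(sum(pts[, 1] * pts[c(2:n, 1), 2] - pts[c(2:n, 1), 1] * pts[, 2])) / 2
  expect_lt(abs(area - 100) / 100, 0.10)
  # two disjoint blobs -> two polygons
  mask[3:5, 18:21, 1] <- TRUE
  expect_length(mask_to_contours(mask, vol), 2)
  # interior hole is filled, not emitted
  donut <- array(FALSE, dim(vol$voxels))
  donut[5:15, 5:15, 2] <- TRUE
  donut[9:11, 9:11, 2] <- FALSE
  polys <- mask_to_contours(donut, vol)
  expect_length(polys, 1)
  refilled <- contours_to_mask(polys, vol)
  expect_true(all(refilled[5:15, 5:15, 2])) # hole filled on export
})

test_that("RTSTRUCT round trip preserves names, numbers and masks", {
  set.seed(7)
  vol <- toy_volume(c(40, 40, 4))
  rois <- list(stem = random_blob(c(40, 40, 4), r_range = c(7, 9), min_px = 100),
               gland = random_blob(c(40, 40, 4), r_range = c(7, 9), min_px = 100))
  ss <- structure_set(rois, vol)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ss, vol, f)
  back <- read_rtstruct(f, vol)
  expect_equal(names(back$rois), names(ss$rois))
  expect_equal(vapply(back$rois, `[[`, 0L, "roi_number"),
               vapply(ss$rois, `[[`, 0L, "roi_number"))
  for (nm in names(rois))
    expect_gte(dsc(ss$rois[[nm]]$mask, back$rois[[nm]]$mask), 0.99)
})

test_that("a spherical ROI's rasterized volume matches the analytic volume", {
  vol <- toy_volume(c(64, 64, 24), spacing = c(1, 1), thickness = 1)
  r <- 10
  grid <- expand.grid(r = 1:64, c = 1:64, s = 1:24)
  inside <- ((grid$r - 32)^2 + (grid$c - 32)^2 + (grid$s - 12)^2) <= r^2
  mask <- array(FALSE, c(64, 64, 24))
  mask[cbind(grid$r, grid$c, grid$s)[inside, ]] <- TRUE
  ss <- structure_set(list(sphere = mask), vol)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ss, vol, f)
  back <- read_rtstruct(f, vol)
  vol_mm3 <- sum(back$rois$sphere$mask) # 1 mm^3 voxels
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
})

test_that("frame-of-reference mismatches are rejected", {
  vol <- toy_volume(c(20, 20, 2))
  mask <- array(FALSE, dim(vol$voxels)); mask[8:12, 8:12, 1] <- TRUE
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(structure_set(list(a = mask), vol), vol, f)
  other <- vol
  other$frame_of_reference_uid <- "7.7.7"
  expect_error(read_rtstruct(f, other), "frame of reference")
})

test_that("degenerate structure sets still write valid files", {
  vol <- toy_volume(c(20, 20, 2))
  f <- withr::local_tempfile(fileext = ".dcm")
  expect_warning(write_rtstruct(structure_set(list(), vol), vol, f), "zero ROIs")
  expect_warning(back <- read_rtstruct(f, vol), NA) # parses, no ROIs
  expect_length(back$rois, 0)
  # single-pixel ROI is emitted (round-trip fidelity exempt at this size)
  tiny <- array(FALSE, dim(vol$voxels)); tiny[10, 10, 1] <- TRUE
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(structure_set(list(dot = tiny), vol), vol, f2)
  back2 <- read_rtstruct(f2, vol)
  expect_true("dot" %in% names(back2$rois))
})
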