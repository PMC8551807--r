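test_that("gray/HU calibration maps the two anchor points and inverts", {
  expect_equal(hu_to_gray(-1024), 0)
  expect_equal(hu_to_gray(0), 1024)
  expect_equal(hu_to_gray(120), 1144)
  hu <- seq(-1024, 4145, length.out = 101)
  expect_equal(gray_to_hu(hu_to_gray(hu)), hu)
  expect_error(hu_to_gray(-2000), class = "osteo_range_error")
  expect_error(gray_to_hu(-1), class = "osteo_range_error")
})

test_that("volumes round-trip through NIfTI and MetaImage", {
  set.seed(11)
  vol <- density_volume(array(runif(8^3, 0, 5000), c(8, 8, 8)),
                        spacing = c(0.5, 0.5, 0.7))
  for (ext in c(".nii.gz", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(vol, path)
    back <- load_volume(path)
    expect_equal(back$grid, vol$grid, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    unlink(path)
  }
  zero <- density_volume(array(0, c(4, 4, 4)))
  p <- tempfile(fileext = ".mha")
  write_volume(zero, p)
  back <- load_volume(p)
  expect_true(all(back$grid == 0))
  expect_equal(back$spacing, c(1, 1, 1))
  unlink(p)
})

test_that("malformed inputs raise format errors naming the problem", {
  expect_error(density_volume(matrix(0, 4, 4)), class = "osteo_format_error")
  expect_error(density_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               class = "osteo_format_error")
  # a 2D image on disk is rejected on read
  img <- RNifti::asNifti(matrix(0, 8, 8))
  p <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(load_volume(p), class = "osteo_format_error")
  unlink(p)
  # MetaImage header missing DimSize
  p2 <- tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 3",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), p2)
  expect_error(load_volume(p2), "DimSize", class = "osteo_format_error")
  unlink(p2)
  expect_error(load_volume(tempfile()), class = "osteo_io_error")
  expect_error(load_volume(tempdir(), format = "dicom_dir"),
               class = "osteo_format_error")
})

test_that("threshold segmentation recovers a uniform cube and errors when empty", {
  grid <- array(0, c(12, 12, 12))
  grid[4:9, 4:9, 4:9] <- 2000
  vol <- density_volume(grid)
  m <- segment_bone(vol, lower = 1300, upper = 5169, close_radius = 0)
  expect_equal(m$voxel_count, 6^3)
  expect_true(all(m$mask[4:9, 4:9, 4:9]))
  expect_error(segment_bone(vol, lower = 5000, upper = 5169),
               class = "osteo_segmentation_empty")
  expect_error(segment_bone(vol, lower = 2000, upper = 1000),
               class = "osteo_format_error")
})

test_that("closing includes an interior air voxel (brute-force 3x3x3 check)", {
  grid <- array(0, c(12, 12, 12))
  grid[4:9, 4:9, 4:9] <- 2000
  grid[6, 6, 6] <- 0   # one interior air voxel
  vol <- density_volume(grid)
  m0 <- segment_bone(vol, 1300, 5169, close_radius = 0)
  expect_false(m0$mask[6, 6, 6])
  m1 <- segment_bone(vol, 1300, 5169, close_radius = 1)
  # brute force: dilation with the 6-neighbour ball reaches the cavity from
  # all sides, erosion keeps it because all its ball neighbours are filled
  expect_true(m1$mask[6, 6, 6])
  # closing must not grow the outer hull
  expect_equal(m1$voxel_count, 6^3)
})

test_that("segmentation is idempotent at radius 0 and monotone in the threshold", {
  set.seed(7)
  vol <- density_volume(array(runif(10^3, 0, 3000), c(10, 10, 10)))
  m1 <- segment_bone(vol, 1000, 5169, close_radius = 0)
  vol2 <- density_volume(array(as.numeric(m1$mask) * 2000, dim(m1$mask)))
  m2 <- segment_bone(vol2, 1000, 5169, close_radius = 0)
  expect_equal(m2$mask, m1$mask)
  lowers <- seq(200, 2800, by = 200)
  counts <- vapply(lowers, function(lo)
    segment_bone(vol, lo, 5169, close_radius = 0)$voxel_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hole filling and largest-component filters work as opt-ins", {
  grid <- array(0, c(14, 14, 14))
  grid[3:8, 3:8, 3:8] <- 2000     # big cube with a cavity
  grid[5:6, 5:6, 5:6] <- 0
  grid[11:12, 11:12, 11:12] <- 2000  # small separate blob
  vol <- density_volume(grid)
  plain <- segment_bone(vol, 1300, 5169, close_radius = 0)
  expect_false(plain$mask[5, 5, 5])
  filled <- segment_bone(vol, 1300, 5169, close_radius = 0, fill_holes = TRUE)
  expect_true(all(filled$mask[5:6, 5:6, 5:6]))
  largest <- segment_bone(vol, 1300, 5169, close_radius = 0,
                          keep_largest = TRUE)
  expect_false(any(largest$mask[11:12, 11:12, 11:12]))
  expect_true(all(largest$mask[3:8, 3:8, 3:8] ==
                    plain$mask[3:8, 3:8, 3:8]))
})
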