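test_that("NIfTI round-trip preserves voxels, spacing, origin and masks", {
  dir <- withr::local_tempdir()
  vol <- rand_volume(16L, seed = 11, spacing = c(1.0, 1.0, 2.35))
  vol$origin <- c(-12.5, 3, 40.25)
  for (ext in c(".nii", ".nii.gz")) {
    p <- file.path(dir, paste0("vol", ext))
    write_volume(vol, p)
    back <- read_volume(p)
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  }
  m <- box_mask(16L, 4L, 10L)
  pm <- file.path(dir, "mask.nii")
  write_volume(m, pm)
  backm <- read_volume(pm, mask = TRUE)
  expect_s3_class(backm, "mask_volume")
  expect_identical(sum(backm$voxels), sum(m$voxels))

  fld <- rand_field(8L, seed = 2)
  pf <- file.path(dir, "field.nii.gz")
  write_field(fld, pf)
  backf <- read_field(pf)
  expect_identical(backf$u, fld$u)

  expect_error(read_volume(file.path(dir, "nothing.nii")))
  writeLines("not a nifti at all, just text padding to some length",
             file.path(dir, "bad.nii"))
  expect_error(read_volume(file.path(dir, "bad.nii")))
})

test_that("volume constructors enforce their invariants", {
  expect_error(image_volume(array(1, c(2, 2))), "3D")
  expect_error(image_volume(array(c(1, NaN), c(2, 2, 2))), "finite")
  expect_error(image_volume(array(1, c(1, 4, 4))), ">= 2")
  expect_error(image_volume(array(1, c(4, 4, 4)), spacing = c(1, 0, 1)), "> 0")
  expect_error(mask_volume(array(0.5, c(2, 2, 2))), "0 or 1")
  expect_error(intensity_window(5, 5), "degenerate")
  expect_error(cube_grid(4), ">= 8")
})

test_that("normalize_intensity matches the windowing formula and inverts", {
  w <- intensity_window(-1024, 2000)
  v <- image_volume(array(c(-1024, 2000, 488, 3000, -2000, 0, 100, -50),
                          c(2, 2, 2)))
  n <- normalize_intensity(v, w)
  expect_equal(n$voxels[1, 1, 1], 0)
  expect_equal(n$voxels[2, 1, 1], 1)
  expect_equal(n$voxels[1, 2, 1], (488 + 1024) / 3024)
  # outliers are retained outside [0, 1]
  expect_gt(n$voxels[2, 2, 1], 1)
  expect_lt(n$voxels[1, 1, 2], 0)
  back <- denormalize_intensity(n, w)
  expect_equal(back$voxels, v$voxels, tolerance = 1e-9)
})

test_that("estimate_window matches a sort-and-interpolate percentile oracle", {
  v <- image_volume(array(0:999, c(10, 10, 10)))
  w <- estimate_window(list(v), 0, 100)
  expect_equal(c(w$imin, w$imax), c(0, 999))

  # pooled values 0..1000 over two volumes, percentiles (1, 99)
  vals <- 0:1000
  v1 <- image_volume(array(vals[1:500], c(5, 10, 10)))
  v2 <- image_volume(array(vals[501:1001], c(5, 10, 10)), spacing = 2)
  w2 <- estimate_window(list(v1, v2), 1, 99)
  pooled <- sort(c(v1$voxels, v2$voxels))
  interp <- function(p) {
    h <- (length(pooled) - 1) * p / 100
    lo <- floor(h)
    pooled[lo + 1] * (1 - (h - lo)) + pooled[lo + 2] * (h - lo)
  }
  expect_equal(w2$imin, interp(1), tolerance = 1e-12)
  expect_equal(w2$imax, interp(99), tolerance = 1e-12)

  expect_error(estimate_window(list(image_volume(array(7, c(4, 4, 4))))),
               "degenerate")
  expect_error(estimate_window(list(), 1, 99), "at least one")
  expect_error(estimate_window(list(v), 50, 40))
})

test_that("mask_centroid averages 0-based foreground coordinates", {
  m <- array(0, c(8, 8, 8))
  m[4, 5, 6] <- 1  # 0-based (3, 4, 5)
  expect_equal(unname(mask_centroid(mask_volume(m))), c(3, 4, 5))

  m2 <- array(0, c(8, 8, 8))
  m2[1, 1, 1] <- 1; m2[3, 1, 1] <- 1
  expect_equal(unname(mask_centroid(mask_volume(m2))), c(1, 0, 0))

  m3 <- array(0, c(8, 8, 8))
  m3[1, 1, 1] <- 1; m3[2, 1, 1] <- 1; m3[1, 2, 1] <- 1
  expect_equal(unname(mask_centroid(mask_volume(m3))), c(1 / 3, 1 / 3, 0))

  expect_error(mask_centroid(mask_volume(array(0, c(4, 4, 4)))), "empty")

  # equivariance under integer translation
  base <- box_mask(12L, 3L, 5L)
  shifted <- array(0, c(12, 12, 12))
  shifted[5:7, 6:8, 4:6] <- 1
  expect_equal(mask_centroid(mask_volume(shifted)),
               mask_centroid(base) + c(2, 3, 1))
})

test_that("crop_to_cube resamples, fills with the in-bounds mean, errors off-grid", {
  const7 <- image_volume(array(7, c(20, 20, 20)))
  g <- cube_grid(8, 1)
  inside <- crop_to_cube(const7, c(10, 10, 10), g)
  expect_true(all(inside$voxels == 7))
  expect_equal(inside$spacing, rep(1, 3))
  expect_identical(dim(inside$voxels), c(8L, 8L, 8L))

  half_out <- crop_to_cube(const7, c(1, 10, 10), g)
  expect_true(all(abs(half_out$voxels - 7) < 1e-12))

  expect_error(crop_to_cube(const7, c(200, 200, 200), g), "outside")

  # grid-aligned identity crop is an exact sub-block copy
  v <- rand_volume(16L, seed = 5)
  ctr <- c(7.5, 7.5, 7.5)  # 0-based center of block 4..11 (1-based 5:12)
  sub <- crop_to_cube(v, ctr, cube_grid(8, 1))
  expect_equal(sub$voxels, v$voxels[5:12, 5:12, 5:12], tolerance = 1e-9)

  # masks resample nearest and fill background
  m <- box_mask(16L, 5L, 12L)
  subm <- crop_to_cube(m, ctr, cube_grid(8, 1))
  expect_s3_class(subm, "mask_volume")
  expect_equal(subm$voxels, m$voxels[5:12, 5:12, 5:12])
})

test_that("atlas_bundle shares one grid, defaults ms_mask, caches maps", {
  img <- rand_volume(8L, seed = 1)
  tm <- box_mask(8L)
  b <- atlas_bundle(img, tm)
  expect_identical(b$ms_mask$voxels, tm$voxels)
  expect_s3_class(b$distance_map, "distance_map")
  expect_s3_class(b$weight_map, "weight_map")
  expect_error(atlas_bundle(img, box_mask(10L)), "share one grid")
  ms <- box_mask(8L, 2L, 7L)
  b2 <- atlas_bundle(img, tm, ms_mask = ms)
  expect_identical(b2$ms_mask$voxels, ms$voxels)
})
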