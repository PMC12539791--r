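test_that("pull_back warps correctly on constructed fields", {
  s <- 8L
  g <- cube_grid(s, 1)
  vol <- rand_volume(s, seed = 3)
  expect_equal(pull_back(vol, zero_field(g))$voxels, vol$voxels)

  # shifted-pair recovery: B(x) = A(x - 1) along x, u = +1 recovers A
  A <- rand_volume(s, seed = 4)
  B <- A
  B$voxels[2:s, , ] <- A$voxels[1:(s - 1), , ]
  u <- array(0, c(s, s, s, 3)); u[, , , 1] <- 1
  rec <- pull_back(B, displacement_field(u, g))
  expect_equal(rec$voxels[1:(s - 1), , ], A$voxels[1:(s - 1), , ],
               tolerance = 1e-12)

  # linear ramp under constant displacement: closed form on the interior
  ramp <- image_volume(array(rep(0:(s - 1), times = s * s), c(s, s, s)))
  uc <- array(0, c(s, s, s, 3)); uc[, , , 1] <- 0.7
  w <- pull_back(ramp, displacement_field(uc, g))
  expect_equal(w$voxels[2:(s - 2), , ],
               ramp$voxels[2:(s - 2), , ] + 0.7, tolerance = 1e-9)

  expect_error(pull_back(rand_volume(10L), zero_field(g)), "match")
})

test_that("transform_points interpolates the field", {
  s <- 8L
  g <- cube_grid(s, 1)
  pts <- rbind(c(1, 2, 3), c(4.5, 2.25, 6))
  expect_equal(transform_points(pts, zero_field(g)), pts)

  uc <- array(0, c(s, s, s, 3))
  uc[, , , 1] <- 1; uc[, , , 2] <- -2; uc[, , , 3] <- 0.5
  expect_equal(transform_points(pts, displacement_field(uc, g)),
               sweep(pts, 2, c(1, -2, 0.5), "+"))

  # midpoint between two voxels averages their displacements
  u <- array(0, c(s, s, s, 3))
  u[3, 3, 3, 1] <- 2
  u[4, 3, 3, 1] <- 4
  mapped <- transform_points(c(2.5, 2, 2), displacement_field(u, g))
  expect_equal(mapped[1, ], c(2.5 + 3, 2, 2))
})

test_that("transform_points and pull_back are consistent on grid points", {
  s <- 8L
  vol <- rand_volume(s, seed = 9)
  fld <- random_smooth_field(cube_grid(s, 1), amplitude = 1.5,
                             smoothness = 2, seed = 4)
  w <- pull_back(vol, fld)
  pts <- as.matrix(expand.grid(x = 1:4, y = 2:4, z = 3:5))  # 0-based interior
  mapped <- transform_points(pts, fld)
  direct <- atlaswarp:::cpp_sample_trilinear(vol$voxels, dim(vol$voxels),
                                             mapped, 0L)
  expect_equal(as.numeric(direct), unname(w$voxels[pts + 1]),
               tolerance = 1e-6)
})

test_that("extract_surface builds closed meshes with the right topology", {
  mcube <- array(0, c(8, 8, 8)); mcube[2:6, 2:6, 2:6] <- 1
  mesh <- extract_surface(mask_volume(mcube))
  edges <- unique(t(apply(rbind(mesh$faces[, 1:2], mesh$faces[, 2:3],
                                mesh$faces[, c(1, 3)]), 1, sort)))
  chi <- nrow(mesh$vertices) - nrow(edges) + nrow(mesh$faces)
  expect_identical(chi, 2L)  # genus-0 closed surface

  # symmetric cube: vertex centroid at the cube center
  expect_equal(unname(colMeans(mesh$vertices)), c(3, 3, 3), tolerance = 1e-6)

  # two disjoint voxels -> two connected components (via vertex sharing)
  m2 <- array(0, c(8, 8, 8)); m2[2, 2, 2] <- 1; m2[6, 6, 6] <- 1
  mesh2 <- extract_surface(mask_volume(m2))
  comp <- seq_len(nrow(mesh2$vertices))
  repeat {
    new <- comp
    for (f in seq_len(nrow(mesh2$faces))) {
      ids <- mesh2$faces[f, ]
      new[ids] <- min(new[ids])
    }
    if (identical(new, comp)) break
    comp <- new
  }
  expect_identical(length(unique(comp)), 2L)

  expect_error(extract_surface(mask_volume(array(0, c(4, 4, 4)))), "empty")
})

test_that("transfer_mask moves the mask with the deformation", {
  s <- 16L
  g <- cube_grid(s, 1)
  m <- box_mask(s, 6L, 10L)
  out0 <- transfer_mask(m, zero_field(g))
  expect_equal(out0$voxels, m$voxels)
  expect_equal(dice(out0, m), 1)

  # constant u = +2 along x: transferred mask = atlas mask shifted +2
  u <- array(0, c(s, s, s, 3)); u[, , , 1] <- 2
  out <- transfer_mask(m, displacement_field(u, g))
  shifted <- array(0, c(s, s, s)); shifted[8:12, 6:10, 6:10] <- 1
  expect_equal(out$voxels, shifted)

  # round trip on a smooth small-amplitude field keeps Dice high
  s2 <- 32L
  blob <- array(0, c(s2, s2, s2))
  ax <- seq_len(s2) - 1
  r2 <- outer(outer((ax - 15.5)^2, (ax - 15.5)^2, "+"), (ax - 15.5)^2, "+")
  blob[r2 <= 8^2] <- 1
  bm <- mask_volume(blob)
  fld <- random_smooth_field(cube_grid(s2, 1), amplitude = 2,
                             smoothness = 6, seed = 8)
  fwd <- transfer_mask(bm, fld)
  inv <- invert_field(fld, iters = 30, tol = 0.01)
  back <- transfer_mask(fwd, inv, iters = 30, tol = 0.01)
  expect_gte(dice(back, bm), 0.95)
})

test_that("random_smooth_field is seeded, bounded and diffeomorphic-ish", {
  g <- cube_grid(32L, 1)
  z <- random_smooth_field(g, amplitude = 0, smoothness = 6, seed = 1)
  expect_true(all(z$u == 0))

  f1 <- random_smooth_field(g, amplitude = 3, smoothness = 6, seed = 5)
  f2 <- random_smooth_field(g, amplitude = 3, smoothness = 6, seed = 5)
  f3 <- random_smooth_field(g, amplitude = 3, smoothness = 6, seed = 6)
  expect_identical(f1$u, f2$u)
  expect_false(identical(f1$u, f3$u))

  mag <- sqrt(rowSums(matrix(f1$u, ncol = 3)^2))
  expect_equal(max(mag), 3, tolerance = 1e-9)

  # min over voxels of det(I + grad u) stays positive at default scales
  J <- array(0, c(32, 32, 32, 3, 3))
  for (c in 1:3) for (axis in 1:3)
    J[, , , c, axis] <- atlaswarp:::central_diff(f1$u[, , , c], axis)
  detJ <- (1 + J[, , , 1, 1]) * ((1 + J[, , , 2, 2]) * (1 + J[, , , 3, 3]) -
            J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * (1 + J[, , , 3, 3]) -
            J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
            (1 + J[, , , 2, 2]) * J[, , , 3, 1])
  expect_gt(min(detJ), 0)

  expect_error(random_smooth_field(g, amplitude = -1), ">= 0")
  expect_error(random_smooth_field(g, amplitude = 1, smoothness = 0), "> 0")
})

test_that("grad_map matches a brute-force oracle and its invariants", {
  s <- 8L
  g <- cube_grid(s, 1)
  cst <- displacement_field(array(2.5, c(s, s, s, 3)), g)
  expect_true(all(grad_map(cst) == 0))

  ramp <- array(0, c(s, s, s, 3))
  ramp[, , , 1] <- rep(0:(s - 1), times = s * s)
  gm <- grad_map(displacement_field(ramp, g))
  expect_true(all(abs(gm[2:(s - 1), , ] - 1) < 1e-12))

  fld <- rand_field(s, seed = 12)
  expect_equal(grad_map(fld), oracle_grad_map(fld$u), tolerance = 1e-9)
  expect_true(all(grad_map(fld) >= 0))
})
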