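test_that("point-mass and closed-form cuboid inertia are recovered", {
  # single voxel: zero tensor in the point-mass model
  g <- array(0, c(5, 5, 5)); g[3, 3, 3] <- 2048
  vol <- density_volume(g)
  mp <- mass_properties(vol, bone_mask(g > 0))
  expect_equal(mp$total_mass, 2)
  expect_equal(mp$inertia_tensor, matrix(0, 3, 3))
  # 10 mm cube at 0.25 mm: specific moments near a^2/6 = 16.667; the exact
  # point-mass lattice value is (a^2 - h^2)/6
  ph <- make_phantom(phantom_spec(
    phantom_primitive("cuboid", size = c(5, 5, 5), density_gray = 1024),
    voxel_size = 0.25))
  mp <- mass_properties(ph$volume, ph$mask)
  spec_m <- mp$principal_moments / mp$total_mass
  expect_equal(spec_m, rep((10^2 - 0.25^2) / 6, 3), tolerance = 1e-10)
  expect_rel_equal(spec_m, rep(10^2 / 6, 3), tol = 1e-3)
  # the voxel self-moment correction recovers the continuum value exactly
  mp2 <- mass_properties(ph$volume, ph$mask, self_moment = TRUE)
  expect_equal(mp2$principal_moments / mp2$total_mass, rep(100 / 6, 3),
               tolerance = 1e-10)
})

test_that("ellipsoid principal moments converge to the closed form", {
  ph <- make_phantom(phantom_spec(
    phantom_primitive("ellipsoid", size = c(30, 10, 8)), voxel_size = 0.5))
  mp <- mass_properties(ph$volume, ph$mask)
  expect_rel_equal(mp$principal_moments / mp$total_mass,
                   c(32.8, 192.8, 200.0), tol = 0.01)
  expect_equal(mp$com, c(0, 0, 0), tolerance = 1e-9)
  # gray and uniform weighting coincide on a constant-density phantom
  mpu <- mass_properties(ph$volume, ph$mask, weighting = "uniform")
  expect_equal(mp$principal_moments / mp$total_mass,
               mpu$principal_moments / mpu$total_mass, tolerance = 1e-12)
})

test_that("mass-property invariants hold across phantoms", {
  specs <- list(
    phantom_primitive("sphere", size = 7),
    phantom_primitive("ellipsoid", size = c(12, 6, 4)),
    phantom_primitive("cuboid", size = c(10, 4, 3)),
    phantom_primitive("cylinder", size = c(4, 3, 12)))
  for (pr in specs) {
    ph <- make_phantom(phantom_spec(pr, voxel_size = 0.5))
    mp <- mass_properties(ph$volume, ph$mask)
    lam <- mp$principal_moments
    expect_true(all(lam >= 0))
    expect_true(all(lam <= sum(lam) - lam + 1e-9))  # triangle inequality
    expect_equal(mp$inertia_tensor, t(mp$inertia_tensor))
    expect_equal(crossprod(mp$principal_axes), diag(3), tolerance = 1e-10)
    expect_equal(det(mp$principal_axes), 1, tolerance = 1e-10)
  }
})

test_that("principal frame recovers a known rotation and flags degeneracy", {
  fake_props <- function(I) {
    ev <- eigen(I, symmetric = TRUE)
    ord <- order(ev$values)
    vecs <- ev$vectors[, ord]
    if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
    structure(list(total_mass = 1, com = c(0, 0, 0), inertia_tensor = I,
                   principal_moments = ev$values[ord], principal_axes = vecs,
                   weighting = "uniform"), class = "mass_properties")
  }
  # already-diagonal tensor: fallback labeling is z, x, y by moment order
  fr <- principal_frame(fake_props(diag(c(1, 2, 3))))
  expect_equal(abs(fr$rotation["z", ]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(fr$rotation["x", ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(abs(fr$rotation["y", ]), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(fr$axis_moments), c(2, 3, 1))
  # pre-rotating the body rotates the recovered frame accordingly
  R <- quaternion_rotation_for_test(c(0.2, -0.4, 0.3, 0.8))
  fr0 <- principal_frame(fake_props(diag(c(1, 2, 3))))
  fr1 <- principal_frame(fake_props(R %*% diag(c(1, 2, 3)) %*% t(R)))
  agreement <- abs(fr1$rotation %*% R %*% t(fr0$rotation))
  expect_equal(agreement, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)  # up to sign flips
  # sphere: all moments equal, no references -> degeneracy error
  expect_error(principal_frame(fake_props(diag(c(2, 2, 2)))),
               class = "osteo_degeneracy_error")
  # with references the labeling follows them
  fr2 <- principal_frame(fake_props(diag(c(1, 2, 3))),
                         anatomical_refs = rbind(c(0, 0, 1), c(0, 1, 0),
                                                 c(1, 0, 0)))
  expect_equal(fr2$labeling, "reference")
  expect_equal(fr2$rotation["x", ], c(0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(fr2$axis_moments), c(3, 2, 1))
})

test_that("body-frame transform centers the COM and diagonalizes the tensor", {
  ph <- make_phantom(phantom_spec(
    phantom_primitive("cuboid", size = c(9, 4, 3),
                      orientation = quaternion_rotation_for_test(c(1, 2, 3, 4)),
                      center = c(5, -3, 2)),
    voxel_size = 0.5))
  mp <- mass_properties(ph$volume, ph$mask)
  fr <- principal_frame(mp)
  # the COM maps to the origin
  expect_equal(as.numeric(to_body_frame(mp$com, fr)), c(0, 0, 0),
               tolerance = 1e-9)
  # transformed voxel cloud has (near) zero products of inertia
  idx <- which(ph$mask$mask)
  pts <- to_body_frame(osteoinertia:::voxel_centers(ph$volume, idx), fr)
  off <- crossprod(pts) - diag(diag(crossprod(pts)))
  expect_lt(max(abs(off)), 1e-6 * max(mp$principal_moments))
  # round trip: frame then inverse is the identity
  p0 <- matrix(rnorm(30), 10, 3)
  expect_equal(from_body_frame(to_body_frame(p0, fr), fr), p0,
               tolerance = 1e-10)
  # applying the frame twice is not a projection
  expect_false(isTRUE(all.equal(to_body_frame(to_body_frame(p0, fr), fr),
                                to_body_frame(p0, fr))))
})
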