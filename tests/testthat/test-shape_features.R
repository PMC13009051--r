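test_that("mesh volume and area are exact on hand-built meshes", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1.0)
  expect_equal(mesh_area(cube), 6.0)

  # scaling laws: volume ~ s^3, area ~ s^2
  cube2 <- surface_mesh(cube$vertices * 2, cube$faces)
  expect_equal(mesh_volume(cube2), 8.0)
  expect_equal(mesh_area(cube2), 24.0)

  # single right triangle: area only; open meshes refuse a volume
  tri <- surface_mesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
  expect_equal(mesh_area(tri), 0.5)
  expect_error(mesh_volume(tri), "not closed")
})

test_that("mesh volume/area converge on the analytic sphere (icosphere oracle)", {
  ic <- icosphere(10, subdiv = 4)
  expect_lt(abs(mesh_volume(ic) / (4 / 3 * pi * 1000) - 1), 0.01)
  expect_lt(abs(mesh_area(ic) / (4 * pi * 100) - 1), 0.01)
})

test_that("extract_mesh yields closed, accurate surfaces across scales", {
  # smallest valid input: one voxel
  one <- segmentation_mask(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)))
  m1 <- extract_mesh(one)
  expect_gt(mesh_area(m1), 0)
  expect_gt(mesh_volume(m1), 0)   # mesh_volume errors if not closed

  # digital ball r = 20 at 1 mm: mesh volume within 2% of analytic
  b20 <- make_ball(20, spacing = 1)
  mb <- extract_mesh(b20)
  expect_lt(abs(mesh_volume(mb) / (4 / 3 * pi * 20^3) - 1), 0.02)

  # same physical ball sampled at 0.5 mm: same physical volume within 2%
  b05 <- make_ball(20, spacing = 0.5)
  mh <- extract_mesh(b05)
  expect_lt(abs(mesh_volume(mh) / (4 / 3 * pi * 20^3) - 1), 0.02)

  expect_error(extract_mesh(b20, smooth_sigma = -1), ">= 0")
})

test_that("surface regularity and sphericity match closed forms", {
  # sphere: exactly 1 for any radius
  for (r in c(0.3, 1, 7, 120)) {
    tv <- 4 / 3 * pi * r^3; ts <- 4 * pi * r^2
    expect_equal(surface_regularity(tv, ts), 1.0, tolerance = 1e-12)
    expect_equal(sphericity(tv, ts), 1.0, tolerance = 1e-12)
  }
  # cube of side a
  for (a in c(1, 3.7)) {
    expect_equal(surface_regularity(a^3, 6 * a^2), sqrt(pi / 6), tolerance = 1e-12)
    expect_equal(sphericity(a^3, 6 * a^2), (36 * pi)^(1 / 3) / 6, tolerance = 1e-12)
  }
  expect_equal(sqrt(pi / 6), 0.7236, tolerance = 1e-4)
  expect_equal((36 * pi)^(1 / 3) / 6, 0.8060, tolerance = 1e-4)

  expect_error(surface_regularity(-1, 5), "> 0")
  expect_error(surface_regularity(1, 0), "> 0")
  expect_error(sphericity(0, 5), "> 0")
})

test_that("SR is scale-invariant and equals sphericity^1.5 to machine precision", {
  set.seed(19)
  for (i in 1:50) {
    v <- runif(1, 0.1, 5000); a <- runif(1, 0.1, 3000)
    s <- runif(1, 0.01, 100)
    expect_equal(surface_regularity(s^3 * v, s^2 * a), surface_regularity(v, a),
                 tolerance = 1e-12)
    expect_lt(abs(sphericity(v, a)^1.5 / surface_regularity(v, a) - 1), 1e-12)
  }
})

test_that("axis eigenvalues recover continuous-ellipsoid ratios and symmetries", {
  # solid ellipsoid with semi-axes (a,b,c): covariance eigenvalues a^2/5, b^2/5, c^2/5
  e <- make_ellipsoid(c(20, 10, 5), spacing = 1)
  ev <- axis_eigenvalues(e)
  expect_lt(abs(sqrt(ev[2] / ev[1]) / 0.5 - 1), 0.03)
  expect_lt(abs(sqrt(ev[3] / ev[1]) / 0.25 - 1), 0.03)

  # digital ball: all three equal within 2%
  evb <- axis_eigenvalues(make_ball(12))
  expect_lt(evb[1] / evb[3] - 1, 0.02)

  # axis permutation (90-degree rotation) leaves the sorted spectrum unchanged
  ev2 <- axis_eigenvalues(segmentation_mask(aperm(e$voxels, c(3, 1, 2)),
                                            spacing = e$spacing))
  expect_equal(ev, ev2, tolerance = 1e-9)

  expect_error(axis_eigenvalues(segmentation_mask(array(c(1L, rep(0L, 7)), c(2, 2, 2)))),
               "at least 2")
})

test_that("elongation and flatness follow the inverse square-root-ratio convention", {
  expect_equal(elongation(c(4, 1, 1)), 0.5)
  expect_equal(flatness(c(4, 1, 1)), 0.5)
  expect_equal(elongation(c(2, 2, 2)), 1.0)
  expect_equal(flatness(c(9, 4, 0)), 0.0)
  expect_error(elongation(c(0, 0, 0)), "lambda_major")
  expect_error(flatness(c(1, 2, 3)), "descending")
})

test_that("compute_features composes the pipeline correctly", {
  fb <- compute_features(make_ball(20))
  expect_gte(fb$surface_regularity, 0.97)
  expect_gte(fb$sphericity, 0.97)
  expect_equal(fb$elongation, 1, tolerance = 0.02)

  fe <- compute_features(make_ellipsoid(c(20, 10, 5)))
  expect_lt(abs(fe$elongation / 0.5 - 1), 0.03)
  expect_lt(abs(fe$flatness / 0.25 - 1), 0.03)
  expect_lt(fe$sphericity, 1)

  # the ^1.5 identity holds on the record itself (same mesh for both)
  expect_lt(abs(fb$sphericity^1.5 / fb$surface_regularity - 1), 1e-12)

  # perturbation strictly lowers SR at fixed seed
  f0 <- compute_features(make_perturbed_ball(perturbed_ball_spec(15, 0, seed = 3)))
  f4 <- compute_features(make_perturbed_ball(perturbed_ball_spec(15, 0.4, seed = 3)))
  expect_lt(f4$surface_regularity, f0$surface_regularity)
})

test_that("SR of digital balls converges to 1 with radius", {
  srs <- vapply(c(5, 10, 20, 40),
                function(r) compute_features(make_ball(r))$surface_regularity, 1)
  expect_true(all(diff(srs) > -0.005))  # non-decreasing within discretization noise
  expect_gt(srs[4], 0.99)
})

test_that("mesh volume and voxel-count volume agree as mutual oracles", {
  for (r in c(10, 20)) {
    b <- make_ball(r)
    expect_lt(abs(mesh_volume(extract_mesh(b)) / mask_volume(b) - 1), 0.05)
  }
  # also for an irregular phantom
  p <- make_perturbed_ball(perturbed_ball_spec(12, 0.3, seed = 5))
  expect_lt(abs(mesh_volume(extract_mesh(p)) / mask_volume(p) - 1), 0.05)
})
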