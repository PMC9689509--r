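test_that("pinhole projection follows the calibrated model", {
  cam <- camera_intrinsics(1000, 1000, 500, 500, 1001, 1001)
  expect_equal(project(c(0, 0, 2), cam), c(500, 500))
  expect_equal(project(c(0.1, 0, 2), cam), c(550, 500))
  expect_error(project(c(0, 0, -1), cam), "behind camera")
})

test_that("triangulation matches the rectified closed form", {
  cam <- camera_intrinsics(1000, 1000, 320, 240, 640, 480)
  rig <- stereo_rig(cam, cam,
                    rigid_transform(diag(3), c(-0.1, 0, 0)), 2.0)
  # disparity d = f b / Z: Z = 2 m -> d = 50 px on the same row
  p <- triangulate(c(320 + 25, 240), c(320 - 25, 240), rig)
  expect_equal(p[3], 2.0, tolerance = 1e-9)
  # closed-form sensitivity: one pixel moved by +0.5 px changes depth by
  # f b / d - f b / (d + 0.5)
  p2 <- triangulate(c(320 + 25.5, 240), c(320 - 25, 240), rig)
  expect_equal(p[3] - p2[3], 1000 * 0.1 / 50 - 1000 * 0.1 / 50.5,
               tolerance = 1e-9)
  expect_error(triangulate(c(320, 240), c(320, 240), rig), "degenerate")
})

test_that("project and triangulate are mutual inverses on a random rig", {
  set.seed(42)
  for (i in 1:10) {
    # small random vergence/tilt keeps both cameras looking forward
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- rotation_about_axis(stats::runif(1, -8, 8), ax)
    t <- drop(R %*% c(-stats::runif(1, 0.05, 0.4), 0, 0))
    cam <- camera_intrinsics(900, 950, 160, 120, 320, 240)
    rig <- stereo_rig(cam, cam, rigid_transform(R, t), 2.4)
    pt <- c(stats::runif(1, -0.2, 0.2), stats::runif(1, -0.2, 0.2),
            stats::runif(1, 1.5, 3))
    pl <- project(pt, rig$left)
    pr <- project(pt, rig$right, rig$right_from_left)
    expect_lt(max(abs(triangulate(pl, pr, rig) - pt)), 1e-6)
  }
})

test_that("reverse rotation is the exact inverse isometry", {
  set.seed(7)
  pts <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(reverse_rotate(pts, 0), pts)
  ax <- c(0, 0, 1); apnt <- c(0.1, -0.2, 0)
  rot <- reverse_rotate(pts, -73.4, apnt, ax)    # forward rotation by +73.4
  back <- reverse_rotate(rot, 73.4, apnt, ax)
  expect_lt(max(abs(back - pts)), 1e-9)
  # isometry: pairwise distances preserved
  expect_lt(max(abs(dist(rot) - dist(pts))), 1e-9)
  # distance to the axis preserved
  r0 <- sqrt((pts[, 1] - 0.1)^2 + (pts[, 2] + 0.2)^2)
  r1 <- sqrt((rot[, 1] - 0.1)^2 + (rot[, 2] + 0.2)^2)
  expect_lt(max(abs(r0 - r1)), 1e-9)
  expect_error(reverse_rotate(pts, 10, axis_dir = c(0, 0, 2)), "invalid axis")
})

test_that("rigid transform validation rejects improper rotations", {
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "orthonormal")
})

test_that("calibration files round-trip through YAML", {
  rig <- make_default_rig(1100, 320, 240, 0.3, 2.4, verged = TRUE)
  path <- tempfile(fileext = ".yml")
  write_calibration(rig, path)
  rig2 <- read_calibration(path)
  expect_equal(rig2$left$fx, rig$left$fx)
  expect_equal(rig2$right_from_left$R, rig$right_from_left$R,
               tolerance = 1e-12)
  expect_equal(rig2$right_from_left$t, rig$right_from_left$t,
               tolerance = 1e-12)
  expect_equal(rig2$D, rig$D)
})

test_that("the verged default rig converges on the shooting distance", {
  rig <- make_default_rig(verged = TRUE)
  # the point D ahead of the left camera projects to both principal points
  target <- c(0, 0, rig$D)
  pl <- project(target, rig$left)
  pr <- project(target, rig$right, rig$right_from_left)
  expect_equal(pl, c(rig$left$cx, rig$left$cy), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pr, c(rig$right$cx, rig$right$cy), tolerance = 1e-6,
               ignore_attr = TRUE)
})
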