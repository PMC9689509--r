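test_that("rendering is deterministic for a fixed seed", {
  sc <- default_scene_objects()
  v1 <- render_view(sc$model, sc$layout, sc$rig, 0, seed = 5, noise_sigma = 2)
  v2 <- render_view(sc$model, sc$layout, sc$rig, 0, seed = 5, noise_sigma = 2)
  expect_identical(v1$left, v2$left)
  expect_identical(v1$right, v2$right)
})

test_that("a session delivers four stereo pairs with masks and truth", {
  ses <- cached_session(seed = 1)
  expect_length(ses$views, 4)
  for (v in ses$views) {
    expect_equal(dim(v$left), c(240, 320, 3))
    expect_equal(dim(v$right), c(240, 320, 3))
    expect_true(is.logical(v$mask_left) && is.logical(v$mask_right))
    expect_true(any(v$mask_left) && any(v$mask_right))
  }
  expect_error(generate_measurement_session(ses$model, ses$layout, ses$rig,
                                            angles = 0), "insufficient")
})

test_that("ground-truth girth matches analytic circumference", {
  # circle: exactly 2 pi r
  r <- 30 * 0.025 / (2 * pi)
  circ <- body_segment_model(r, r)
  expect_equal(circ$perimeter, 2 * pi * r, tolerance = 1e-9)
  # ellipse: adaptive quadrature of the arc-length integral
  ax <- ellipse_axes_for_girth(0.75, 0.8)
  m <- body_segment_model(ax[1], ax[2])
  q <- 4 * stats::integrate(function(t)
    sqrt(ax[1]^2 * sin(t)^2 + ax[2]^2 * cos(t)^2), 0, pi / 2,
    rel.tol = 1e-13)$value
  expect_equal(m$perimeter, q, tolerance = 1e-6)
  expect_error(body_segment_model(0.1, 0.1), "even integer")
})

test_that("each rendered view contains one red and one cyan marker blob", {
  ses <- cached_session(seed = 1)
  for (v in ses$views) for (img in list(v$left, v$right)) {
    for (col in c("red", "cyan")) {
      set <- extract_marker_set(img, col)
      expect_gt(set$n, 10)
      # a single compact blob: extent bounded by the projected diameter
      expect_lt(diff(range(set$x)), 15)
      expect_lt(diff(range(set$y)), 15)
    }
  }
})

test_that("rendered marker pixels classify to their intended colours", {
  ses <- cached_session(seed = 1)
  v <- ses$views[[1]]
  red <- extract_marker_set(v$left, "red")
  gm <- v$gt$markers
  gr <- gm[gm$color == "red" & gm$front, ]
  expect_equal(nrow(gr), 1)
  expect_lt(sqrt((mean(red$x) - gr$lx)^2 + (mean(red$y) - gr$ly)^2), 1.5)
  # no checkerboard pixel classifies as a marker colour: the red and cyan
  # sets stay within the marker footprint radius of the marker centre
  rad_px <- 1.2 * ses$layout$radius * ses$rig$left$fx / (ses$rig$D - 0.2) + 2
  expect_true(all(sqrt((red$x - gr$lx)^2 + (red$y - gr$ly)^2) < rad_px))
})

test_that("analytic corner projections coincide with response maxima", {
  ses <- cached_session(seed = 1)
  v <- ses$views[[1]]
  resp <- shi_tomasi_response(v$left)
  g <- v$gt$corners
  g <- g[g$cos_left > 0.5 & abs(g$row) <= 1, ]
  for (i in seq_len(nrow(g))) {
    x0 <- round(g$lx[i]); y0 <- round(g$ly[i])
    patch <- resp[y0 + 1 + (-3:3), x0 + 1 + (-3:3)]
    peak <- which(patch == max(patch), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(peak - 4)), 1.5)     # peak within ~1 px of the corner
  }
})

test_that("view rectangles tile all corner columns exactly once", {
  ses <- cached_session(seed = 1)
  cols_seen <- integer(0)
  for (k in seq_along(ses$views)) {
    v <- ses$views[[k]]
    cents <- marker_centroids(v$left, v$right)
    g <- v$gt$corners
    g <- g[g$row == 0 & g$cos_left > 0 & g$cos_right > 0, ]
    xin <- g$lx > min(cents$l_red[1], cents$l_cyan[1]) &
      g$lx < max(cents$l_red[1], cents$l_cyan[1]) &
      g$ly > min(cents$l_red[2], cents$l_cyan[2]) &
      g$ly < max(cents$l_red[2], cents$l_cyan[2])
    cols_seen <- c(cols_seen, g$col[which(xin)])
  }
  expect_equal(sort(cols_seen), 0:(ses$model$n_cols - 1))
  # full-circle coverage: the union of constrained corners spans 360 deg
  expect_equal(length(cols_seen) * 360 / ses$model$n_cols, 360)
})

test_that("segmentation fixtures are reproducible and well-formed", {
  f1 <- generate_segmentation_fixtures(8, 32, seed = 0)
  f2 <- generate_segmentation_fixtures(8, 32, seed = 0)
  expect_identical(f1, f2)
  fracs <- vapply(f1, function(f) {
    expect_true(all(f$mask %in% c(0L, 1L)))
    expect_true(all(f$image >= 0 & f$image <= 1))
    mean(f$mask)
  }, numeric(1))
  expect_true(all(fracs > 0.05 & fracs < 0.65))
  expect_error(generate_segmentation_fixtures(0), "invalid count")
})
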