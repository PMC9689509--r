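test_that("flat regions and straight edges give no corner response", {
  flat <- matrix(0.5, 40, 40)
  expect_true(all(shi_tomasi_response(flat) == 0))
  expect_length(detect_corners(flat)$x, 0)
  # a vertical step edge has a rank-1 structure tensor: zero min eigenvalue
  edge <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  resp <- shi_tomasi_response(edge)
  expect_lt(max(resp[, 10:30]), 1e-12)
  expect_error(shi_tomasi_response(matrix(0, 3, 3), window_size = 5),
               "invalid window")
})

test_that("detected corners respect the mask and suppression radius", {
  ses <- cached_session(seed = 1)
  v <- ses$views[[1]]
  mask <- v$mask_left
  cs <- detect_corners(v$left, mask = mask, min_distance = 5)
  expect_gt(nrow(cs), 10)
  expect_true(all(mask[cbind(cs$y + 1, cs$x + 1)]))
  d <- as.matrix(dist(cbind(cs$x, cs$y)))
  diag(d) <- Inf
  expect_true(all(d >= 5))
})

test_that("sub-pixel refinement reaches the renderer's corner accuracy", {
  ses <- cached_session(seed = 1)
  errs <- numeric(0)
  for (k in seq_along(ses$views)) {
    v <- ses$views[[k]]
    mp <- run_algorithm1(v$left, v$right, mask_left = v$mask_left,
                         mask_right = v$mask_right)
    g <- v$gt$corners[v$gt$corners$cos_left > 0, ]
    e <- vapply(seq_len(nrow(mp)), function(i)
      sqrt(min((g$lx - mp$xl[i])^2 + (g$ly - mp$yl[i])^2)), numeric(1))
    errs <- c(errs, e)
  }
  expect_lt(sqrt(mean(errs^2)), 0.2)   # RMS localisation
  expect_lt(max(errs), 0.5)
})

test_that("refinement is bounded and fixes already-exact corners", {
  ses <- cached_session(seed = 1)
  v <- ses$views[[1]]
  cs <- detect_corners(v$left, mask = v$mask_left)
  cr <- refine_subpixel(v$left, cs, window = 5)
  moved <- sqrt((cr$x - cs$x)^2 + (cr$y - cs$y)^2)
  expect_true(all(moved[cr$refined] <= 5 / 2 * sqrt(2) + 1e-9))
  # a refined corner is (near) a fixed point of another refinement pass
  cr2 <- refine_subpixel(v$left, cr, window = 5)
  again <- sqrt((cr2$x - cr$x)^2 + (cr2$y - cr$y)^2)
  expect_lt(stats::median(again[cr$refined & cr2$refined]), 0.05)
})

test_that("detection is equivariant under image transposition", {
  ses <- cached_session(seed = 1)
  v <- ses$views[[1]]
  g <- 0.299 * v$left[, , 1] + 0.587 * v$left[, , 2] +
    0.114 * v$left[, , 3]
  cs <- refine_subpixel(g, detect_corners(g, mask = v$mask_left))
  gt <- t(g)
  cst <- refine_subpixel(gt, detect_corners(gt, mask = t(v$mask_left)))
  # transposition swaps x and y
  expect_equal(nrow(cs), nrow(cst))
  for (i in seq_len(nrow(cs))) {
    d <- sqrt((cst$x - cs$y[i])^2 + (cst$y - cs$x[i])^2)
    expect_lt(min(d), 0.2)
  }
})

test_that("moderate pixel noise degrades localisation only slightly", {
  sc <- default_scene_objects()
  v0 <- render_view(sc$model, sc$layout, sc$rig, 0, seed = 31, noise_sigma = 0)
  v2 <- render_view(sc$model, sc$layout, sc$rig, 0, seed = 31, noise_sigma = 2)
  g <- v0$gt$corners[v0$gt$corners$cos_left > 0.3 &
                       abs(v0$gt$corners$row) <= 1, ]
  rms <- function(img, mask) {
    cs <- refine_subpixel(img, detect_corners(img, mask = mask))
    e <- vapply(seq_len(nrow(g)), function(i)
      sqrt(min((cs$x - g$lx[i])^2 + (cs$y - g$ly[i])^2)), numeric(1))
    sqrt(mean(pmin(e, 2)^2))
  }
  r0 <- rms(v0$left, v0$mask_left)
  r2 <- rms(v2$left, v2$mask_left)
  expect_lt(r2 - r0, 0.2)
})

test_that("corner sets round-trip through CSV", {
  cs <- corner_set(c(1.25, 7.5), c(3.125, 9.75), c(0.9, 0.8), view = "right",
                   refined = TRUE)
  path <- tempfile(fileext = ".csv")
  write_corners(cs, path)
  cs2 <- read_corners(path)
  expect_equal(cs2$x, cs$x)
  expect_equal(cs2$y, cs$y)
  expect_equal(attr(cs2, "view"), "right")
})
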