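ellipse_points <- function(a, b, n, z = 0) {
  tab <- stereogirth:::arclength_tables(a, b)
  s <- seq(0, tab$perimeter, length.out = n + 1)[-(n + 1)]
  th <- tab$theta_of_s(s)
  cbind(a * cos(th), b * sin(th), z)
}

test_that("closed-curve fitting recovers analytic circumferences", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(0.15 * cos(th), 0.15 * sin(th), 0)
  expect_lt(abs(fit_girth(circ) - 100 * 2 * pi * 0.15), 0.05)
  ell <- ellipse_points(0.16, 0.12, 36)
  truth <- 100 * ellipse_perimeter(0.16, 0.12)
  expect_lt(abs(fit_girth(ell) - truth) / truth, 0.001)
  # doubling the point density moves the result by < 0.1 %
  ell2 <- ellipse_points(0.16, 0.12, 72)
  expect_lt(abs(fit_girth(ell2) - fit_girth(ell)) / truth, 0.001)
})

test_that("girth fitting is invariant to ordering and rigid motion", {
  set.seed(8)
  ell <- ellipse_points(0.14, 0.11, 30)
  g0 <- fit_girth(ell)
  perm <- sample(nrow(ell))
  expect_equal(fit_girth(ell[perm, ]), g0, tolerance = 1e-9)
  # rigid motion of points together with the axis
  R <- random_rotation(); t <- c(0.3, -0.2, 0.5)
  moved <- sweep(ell %*% t(R), 2, t, "+")
  g1 <- fit_girth(moved, axis_point = t, axis_dir = drop(R %*% c(0, 0, 1)))
  expect_equal(g1, g0, tolerance = 1e-6)
})

test_that("incomplete girdles are rejected", {
  th <- seq(0, pi, length.out = 20)          # half circle only
  half <- cbind(0.15 * cos(th), 0.15 * sin(th), 0)
  expect_error(fit_girth(half), "incomplete girdle")
  expect_error(fit_girth(half[1:4, ]), "incomplete girdle")
})

test_that("measurement selection follows the garment-standard rules", {
  expect_equal(select_measurement(c(95.1, 96.0, 94.7), "bust"), 96.0)
  expect_equal(select_measurement(c(82.9, 83.4, 83.1), "waist"), 82.9)
  expect_equal(select_measurement(c(101, 100.2, 100.9), "hip"), 101)
  expect_equal(select_measurement(c(55, 54, 56), "thigh"), 56)
  expect_equal(select_measurement(89.94, "under-bust"), 89.94)
  expect_equal(select_measurement(51.93, "mid-thigh"), 51.93)
  expect_error(select_measurement(c(1, 2), "bust"), "invalid line set")
  expect_error(select_measurement(c(1, 2, 3), "under-bust"),
               "invalid line set")
  set.seed(14)
  for (i in 1:25) {
    g <- stats::runif(3, 40, 120)
    expect_equal(select_measurement(g, "bust"), max(g))
    expect_equal(select_measurement(g, "waist"), min(g))
  }
})

test_that("mean absolute difference behaves like a metric on series", {
  expect_equal(mad_difference(c(1, 3), c(2, 2)), 1.0)
  expect_equal(mad_difference(c(5, 5, 5), c(5, 5, 5)), 0)
  set.seed(15)
  a <- stats::runif(10); b <- stats::runif(10)
  expect_equal(mad_difference(a, b), mad_difference(b, a))
  expect_equal(mad_difference(a + 3, b + 3), mad_difference(a, b))
  expect_error(mad_difference(1:3, 1:4), "incompatible series")
})

test_that("triangulated ground-truth projections reconstruct exactly", {
  ses <- cached_session(seed = 1)
  pairs <- lapply(seq_along(ses$views), function(k) {
    g <- ses$views[[k]]$gt$corners
    g <- g[g$row == 0 & g$visible & g$cos_left > 0.2 & g$cos_right > 0.2, ]
    structure(data.frame(i = seq_len(nrow(g)), xl = g$lx, yl = g$ly,
                         xr = g$rx, yr = g$ry),
              class = c("matched_pairs", "data.frame"))
  })
  pts <- reconstruct_line(pairs, ses$rig, ses$effective_angles,
                          world_from_left = ses$views[[1]]$gt$world_from_left)
  # after de-rotation all views agree with the body-frame corner positions
  gb <- ses$views[[1]]$gt$corners
  gb <- gb[gb$row == 0, ]
  err <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((gb$x_body - pts$x[i])^2 + (gb$y_body - pts$y[i])^2 +
               (gb$z_body - pts$z[i])^2)), numeric(1))
  expect_lt(max(err), 1e-4)
  expect_gte(azimuth_span(pts), 300)
})

test_that("an end-to-end synthetic session recovers the true girth", {
  ses <- cached_session(seed = 1)
  res <- measure_session(ses, "waist")
  expect_length(res$per_line, 3)
  expect_equal(res$final, min(res$per_line))
  expect_lt(res$abs_error / res$true_girth, 0.01)
  # under-bust uses the single line two steps below the baseline
  res2 <- measure_session(ses, "under-bust")
  expect_length(res2$per_line, 1)
  expect_lt(res2$abs_error / res2$true_girth, 0.01)
})

test_that("measurement reports tabulate errors and MAD", {
  rep <- measurement_report(c(95.64, 89.94), c(94.3, 90.3),
                            labels = c("bust", "under-bust"))
  expect_equal(rep$error_cm, c(-1.34, 0.36), tolerance = 1e-9)
  expect_equal(attr(rep, "mad_cm"), mean(c(1.34, 0.36)), tolerance = 1e-9)
})
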