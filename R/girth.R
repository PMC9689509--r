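# From matched corner pairs to girths: triangulation, turntable
# de-rotation, multi-view merging, closed-curve circumference fitting and
# measurement selection.
#
# The closed-curve fit is a periodic piecewise-cubic parametric curve in an
# intermediate arc parameter (cumulative chord length) through the
# azimuth-ordered cross-section points; its arc length is the girth.  The
# fit sits behind this single function so an alternative closed-curve
# formulation can be slotted in without touching the pipeline.

#' Reconstruct one measurement line in 3-D
#'
#' Triangulates every matched pair of every view, maps the points from the
#' left-camera frame to the world frame when a left-camera pose is given,
#' and reverse-rotates each view's points by its turntable angle so all
#' views share the initial body frame.
#'
#' @param pairs_by_view List of `matched_pairs`, one per view.
#' @param rig A `stereo_rig`.
#' @param angles Turntable angles in degrees, one per view (the effective
#'   rotation of each view relative to the initial body frame).
#' @param axis_point,axis_dir Turntable axis.
#' @param world_from_left Optional `rigid_transform` (world to left camera);
#'   identity keeps points in the left-camera frame, in which case the axis
#'   must be expressed in that frame.
#' @param line Line tag for the result.
#' @return A `point3d_set` of all de-rotated corner points.
#' @export
reconstruct_line <- function(pairs_by_view, rig, angles,
                             axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                             world_from_left = NULL, line = 0L) {
  stopifnot(length(pairs_by_view) >= 2,
            length(angles) == length(pairs_by_view))
  sets <- lapply(seq_along(pairs_by_view), function(k) {
    mp <- pairs_by_view[[k]]
    pts <- t(vapply(seq_len(nrow(mp)), function(i)
      tryCatch(triangulate(c(mp$xl[i], mp$yl[i]), c(mp$xr[i], mp$yr[i]), rig),
               error = function(e)
                 stop("view ", k, ", pair ", i, ": ", conditionMessage(e))),
      numeric(3)))
    if (!is.null(world_from_left)) {
      inv <- invert_transform(world_from_left)
      pts <- transform_points(inv, pts)
    }
    point3d_set(reverse_rotate(pts, angles[k], axis_point, axis_dir),
                line = line, angle = angles[k])
  })
  out <- do.call(rbind, sets)
  class(out) <- c("point3d_set", "data.frame")
  out
}

# azimuths (degrees in [0, 360)) of points about the body axis
point_azimuths <- function(points, axis_point = c(0, 0, 0),
                           axis_dir = c(0, 0, 1)) {
  xyz <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")])
         else as.matrix(points)
  rel <- sweep(xyz, 2, axis_point)
  e3 <- axis_dir / sqrt(sum(axis_dir^2))
  ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  (atan2(rel %*% e2, rel %*% e1) * 180 / pi) %% 360
}

#' Azimuthal span of a point set about the body axis
#'
#' 360 degrees minus the largest azimuthal gap between consecutive points.
#'
#' @inheritParams reconstruct_line
#' @param points A `point3d_set` or n x 3 matrix.
#' @return Span in degrees.
#' @export
azimuth_span <- function(points, axis_point = c(0, 0, 0),
                         axis_dir = c(0, 0, 1)) {
  az <- sort(point_azimuths(points, axis_point, axis_dir))
  if (length(az) < 2) return(0)
  gaps <- c(diff(az), 360 - (az[length(az)] - az[1]))
  360 - max(gaps)
}

#' Fit a closed cross-section curve and return its circumference
#'
#' Projects the points onto the plane normal to the body axis at their mean
#' height, orders them by azimuth about their centroid, fits a smooth
#' closed parametric curve in an intermediate arc parameter (cumulative
#' chord length) and returns the curve's arc length.
#'
#' The fit is least-squares, not interpolating: the in-plane coordinates
#' are first projected onto a truncated Fourier basis in the intermediate
#' parameter (`smooth_harmonics` harmonics), which suppresses per-point
#' triangulation noise — an interpolating curve would convert such noise
#' into a systematic overestimate of the circumference.  The smoothed
#' samples are then joined by a periodic piecewise-cubic curve whose length
#' is evaluated densely.  With `smooth_harmonics = 0` the curve
#' interpolates the raw points.
#'
#' @param points A `point3d_set` or n x 3 matrix (metres); at least 6
#'   points spanning at least `min_span` degrees of azimuth.
#' @param axis_point,axis_dir Body axis defining the measurement plane.
#' @param min_span Required azimuthal coverage in degrees (default 300).
#' @param n_dense Sampling density for the arc-length evaluation.
#' @param smooth_harmonics Number of Fourier harmonics of the low-pass
#'   stage (default 5; capped so the basis stays overdetermined).
#' @return Circumference in centimetres.
#' @export
fit_girth <- function(points, axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                      min_span = 300, n_dense = 4000L,
                      smooth_harmonics = 5L) {
  xyz <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")])
         else as.matrix(points)
  if (nrow(xyz) < 6) stop("incomplete girdle: need at least 6 points")
  span <- azimuth_span(xyz, axis_point, axis_dir)
  if (span < min_span)
    stop(sprintf("incomplete girdle: azimuth span %.1f deg < %.0f deg",
                 span, min_span))
  e3 <- axis_dir / sqrt(sum(axis_dir^2))
  ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  rel <- sweep(xyz, 2, axis_point)
  u <- drop(rel %*% e1); v <- drop(rel %*% e2)     # in-plane coordinates
  cu <- mean(u); cv <- mean(v)
  az <- atan2(v - cv, u - cu)
  ord <- order(az)
  u <- u[ord]; v <- v[ord]
  dup <- c(FALSE, diff(u) == 0 & diff(v) == 0)   # coincident samples
  u <- u[!dup]; v <- v[!dup]
  # intermediate arc parameter (cumulative chord), periodically closed
  n <- length(u)
  cl <- sqrt((u - c(u[-1], u[1]))^2 + (v - c(v[-1], v[1]))^2)
  tp <- 2 * pi * c(0, cumsum(cl[-n])) / sum(cl)
  K <- min(as.integer(smooth_harmonics), (n - 2L) %/% 4L)
  if (K > 0) {
    X <- cbind(1, do.call(cbind, lapply(seq_len(K), function(k)
      cbind(cos(k * tp), sin(k * tp)))))
    u <- drop(X %*% qr.coef(qr(X), u))
    v <- drop(X %*% qr.coef(qr(X), v))
  }
  # periodic closure
  uu <- c(u, u[1]); vv <- c(v, v[1])
  chord <- sqrt(diff(uu)^2 + diff(vv)^2)
  tpar <- c(0, cumsum(chord))
  tt <- seq(0, tpar[length(tpar)], length.out = n_dense)
  ux <- stats::spline(tpar, uu, method = "periodic", xout = tt)$y
  vx <- stats::spline(tpar, vv, method = "periodic", xout = tt)$y
  100 * sum(sqrt(diff(ux)^2 + diff(vx)^2))
}

#' Select the final girth from per-line measurements
#'
#' The garment-measurement convention for multi-line girths: the maximum of
#' the three lines for bust, hip and thigh; the minimum for the waist; and
#' for under-bust and mid-thigh the value of the single designated line
#' shifted down two checkerboard steps from the bust / thigh baseline.
#'
#' @param per_line_girths Numeric vector: three line girths (cm) for bust,
#'   hip, thigh, waist; the single shifted-line girth for under-bust and
#'   mid-thigh.
#' @param body_part One of `"bust"`, `"under-bust"`, `"waist"`, `"hip"`,
#'   `"thigh"`, `"mid-thigh"`.
#' @return Final girth in centimetres.
#' @export
select_measurement <- function(per_line_girths, body_part) {
  body_part <- match.arg(body_part, c("bust", "under-bust", "waist", "hip",
                                      "thigh", "mid-thigh"))
  shifted <- body_part %in% c("under-bust", "mid-thigh")
  if (shifted) {
    if (length(per_line_girths) != 1)
      stop("invalid line set: ", body_part,
           " takes the single 2-step-shifted line")
    return(per_line_girths)
  }
  if (length(per_line_girths) != 3)
    stop("invalid line set: ", body_part, " needs exactly 3 line girths")
  if (body_part == "waist") min(per_line_girths) else max(per_line_girths)
}

#' Mean absolute difference between two measurement series
#'
#' @param proposed,reference Numeric vectors of equal length (cm).
#' @return Mean of absolute differences (cm).
#' @export
mad_difference <- function(proposed, reference) {
  if (length(proposed) != length(reference) || length(proposed) < 1)
    stop("incompatible series: lengths must match and be >= 1")
  mean(abs(proposed - reference))
}

#' Measure a girth from a full turntable session
#'
#' Runs the complete pipeline on a synthetic (or equivalently structured)
#' measurement session: marker-constrained stereo matching per view and
#' measurement line, triangulation, de-rotation into the initial body
#' frame, multi-view merging, closed-curve girth fitting per line and
#' final-measurement selection for the requested body part.
#'
#' @param session A `measurement_session`.
#' @param body_part Body part label deciding line offsets and selection
#'   rule; under-bust and mid-thigh use the single line two steps down.
#' @param params Detector parameters.
#' @param line_offsets Baseline offsets in checkerboard steps for the
#'   three-line parts (default -1, 0, +1).
#' @return An object of class `girth_result` with per-line girths (cm), the
#'   selected final girth, point counts, ground truth and absolute error.
#' @export
measure_session <- function(session, body_part = "waist",
                            params = detector_params(),
                            line_offsets = c(-1L, 0L, 1L)) {
  body_part <- match.arg(body_part, c("bust", "under-bust", "waist", "hip",
                                      "thigh", "mid-thigh"))
  if (body_part %in% c("under-bust", "mid-thigh")) line_offsets <- 2L
  per_line <- numeric(0); counts <- integer(0)
  for (off in line_offsets) {
    pairs <- lapply(seq_along(session$views), function(k) {
      v <- session$views[[k]]
      tryCatch(
        run_algorithm1(v$left, v$right, params = params,
                       mask_left = v$mask_left, mask_right = v$mask_right,
                       shift_offset = off, n_step = session$nstep_px,
                       line = off, angle = session$effective_angles[k]),
        error = function(e)
          stop("line ", off, ", view ", k, ": ", conditionMessage(e)))
    })
    pts <- reconstruct_line(pairs, session$rig, session$effective_angles,
                            axis_point = session$axis_point,
                            axis_dir = session$axis_dir,
                            world_from_left =
                              session$views[[1]]$gt$world_from_left,
                            line = off)
    per_line <- c(per_line, fit_girth(pts, session$axis_point,
                                      session$axis_dir))
    counts <- c(counts, nrow(pts))
  }
  final <- select_measurement(per_line, body_part)
  truth <- 100 * session$model$perimeter
  structure(list(per_line = stats::setNames(per_line,
                                            paste0("line", line_offsets)),
                 final = final, body_part = body_part, n_points = counts,
                 true_girth = truth, abs_error = abs(final - truth)),
            class = "girth_result")
}

#' @export
print.girth_result <- function(x, ...) {
  cat(sprintf("Girth measurement (%s)\n", x$body_part))
  cat("  per-line (cm):", paste(sprintf("%.2f", x$per_line), collapse = ", "),
      "\n")
  cat(sprintf("  final: %.2f cm", x$final))
  if (!is.null(x$true_girth))
    cat(sprintf("  [truth %.2f cm, |error| %.2f cm]", x$true_girth,
                x$abs_error))
  cat("\n")
  invisible(x)
}

#' Tabulate proposed vs reference measurements
#'
#' @param proposed,reference Numeric vectors (cm), one entry per subject or
#'   session.
#' @param labels Optional row labels.
#' @return A `measurement_report` data frame with errors, error rates (%)
#'   and the series MAD (cm) as an attribute.
#' @export
measurement_report <- function(proposed, reference, labels = NULL) {
  stopifnot(length(proposed) == length(reference))
  df <- data.frame(subject = labels %||% seq_along(proposed),
                   proposed_cm = proposed, reference_cm = reference,
                   error_cm = reference - proposed,
                   error_rate_pct = 100 * (reference - proposed) / reference)
  structure(df, mad_cm = mad_difference(proposed, reference),
            class = c("measurement_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.measurement_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("MAD: %.2f cm\n", attr(x, "mad_cm")))
  invisible(x)
}
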