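# ---- camera and rig containers -------------------------------------------

#' Pinhole camera intrinsics
#'
#' Focal lengths and principal point in pixels, plus the image size.  Pixel
#' coordinates are 0-based at pixel centres, x rightward and y downward, so a
#' point on the optical axis projects to `(principal_x, principal_y)`.
#'
#' @param focal_x,focal_y Focal lengths in pixels (> 0).
#' @param principal_x,principal_y Principal point in pixels; must lie inside
#'   the image bounds.
#' @param image_width,image_height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_x, focal_y, principal_x, principal_y,
                              image_width, image_height) {
  stopifnot(focal_x > 0, focal_y > 0, image_width >= 1, image_height >= 1)
  if (principal_x < 0 || principal_x > image_width - 1 ||
      principal_y < 0 || principal_y > image_height - 1)
    stop("principal point outside image bounds")
  structure(list(fx = focal_x, fy = focal_y, cx = principal_x,
                 cy = principal_y, width = as.integer(image_width),
                 height = as.integer(image_height)),
            class = "camera_intrinsics")
}

#' Rigid transform (rotation + translation)
#'
#' Maps reference-frame coordinates to target-frame coordinates as
#' `x_target = R x_ref + t`.  The rotation must be orthonormal with
#' determinant +1 (tolerance 1e-9).
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation Length-3 numeric vector in metres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not a proper orthonormal matrix")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -drop(t(tf$R) %*% tf$t))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$R %*% first$R, drop(second$R %*% first$t) + second$t)
}

#' Apply a rigid transform to points
#' @param tf A `rigid_transform`.
#' @param pts 3-vector or n x 3 matrix of points.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) return(drop(tf$R %*% pts) + tf$t)
  sweep(pts %*% t(tf$R), 2, tf$t, "+")
}

#' Calibrated binocular stereo rig
#'
#' Left and right pinhole cameras and the pose of the right camera relative
#' to the left (`x_right = R x_left + t`), together with the nominal shooting
#' distance D used by the checkerboard pixel-step relation.
#'
#' @param left,right `camera_intrinsics` for the two cameras.
#' @param right_from_left `rigid_transform` taking left-camera coordinates to
#'   right-camera coordinates; the baseline `||t||` must be positive.
#' @param shooting_distance_D Nominal camera-to-subject distance in metres.
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(left, right, right_from_left, shooting_distance_D) {
  stopifnot(inherits(left, "camera_intrinsics"),
            inherits(right, "camera_intrinsics"),
            inherits(right_from_left, "rigid_transform"),
            shooting_distance_D > 0)
  if (sqrt(sum(right_from_left$t^2)) <= 0)
    stop("baseline length must be positive")
  structure(list(left = left, right = right,
                 right_from_left = right_from_left,
                 D = shooting_distance_D),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  b <- sqrt(sum(x$right_from_left$t^2))
  cat(sprintf("Stereo rig: %dx%d px, fx (L) = %.1f px, baseline = %.3f m, D = %.2f m\n",
              x$left$width, x$left$height, x$left$fx, b, x$D))
  invisible(x)
}

# ---- projection / triangulation ------------------------------------------

#' Project a 3-D point through a pinhole camera
#'
#' @param point 3-vector in metres (reference frame of `pose`), or an
#'   n x 3 matrix of points.
#' @param camera `camera_intrinsics`.
#' @param pose `rigid_transform` from the point's frame to the camera frame;
#'   defaults to the identity (point already in camera coordinates).
#' @return Sub-pixel image coordinates `(x, y)` (length-2 vector, or n x 2
#'   matrix).  Signals an error if any point has non-positive depth.
#' @export
project <- function(point, camera, pose = rigid_transform()) {
  single <- is.null(dim(point))
  pts <- if (single) matrix(point, 1, 3) else as.matrix(point)
  pc <- transform_points(pose, pts)
  if (any(pc[, 3] <= 0)) stop("behind camera: non-positive depth")
  uv <- cbind(camera$fx * pc[, 1] / pc[, 3] + camera$cx,
              camera$fy * pc[, 2] / pc[, 3] + camera$cy)
  if (single) drop(uv) else uv
}

# back-project a pixel to a unit ray in the camera frame
pixel_ray <- function(px, camera) {
  d <- c((px[1] - camera$cx) / camera$fx, (px[2] - camera$cy) / camera$fy, 1)
  d / sqrt(sum(d^2))
}

#' Triangulate a stereo pixel pair
#'
#' Back-projects the two pixels to rays and returns the midpoint of their
#' common perpendicular, expressed in the left-camera frame.  This symmetric
#' construction needs no rectification and degrades gracefully under pixel
#' noise.
#'
#' @param pix_left,pix_right Length-2 pixel coordinates in the left and right
#'   views.
#' @param rig `stereo_rig`.
#' @return 3-vector in metres (left-camera frame).  Signals an error for
#'   near-parallel rays (angle below 1e-6 rad).
#' @export
triangulate <- function(pix_left, pix_right, rig) {
  stopifnot(all(is.finite(pix_left)), all(is.finite(pix_right)))
  o1 <- c(0, 0, 0)
  d1 <- pixel_ray(pix_left, rig$left)
  inv <- invert_transform(rig$right_from_left)   # right -> left
  o2 <- inv$t
  d2 <- drop(inv$R %*% pixel_ray(pix_right, rig$right))
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (sqrt(sum(cr^2)) < 1e-6) stop("degenerate geometry: rays nearly parallel")
  # closest points: o1 + s d1, o2 + u d2
  w <- o1 - o2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * cc - b * b
  s <- (b * e - cc * d) / den
  u <- (a * e - b * d) / den
  (o1 + s * d1 + o2 + u * d2) / 2
}

# ---- rotations about an axis ---------------------------------------------

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @param angle_deg Rotation angle in degrees (right-handed about `axis_dir`).
#' @param axis_dir Unit-length 3-vector.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(angle_deg, axis_dir) {
  if (abs(sqrt(sum(axis_dir^2)) - 1) > 1e-9)
    stop("invalid axis: direction must have unit norm")
  th <- angle_deg * pi / 180
  k <- axis_dir
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Undo a turntable rotation on reconstructed points
#'
#' Rotates every point by `-angle` about the axis through `axis_point` along
#' `axis_dir`, taking feature points that rotated with the turntable back to
#' their initial positions so that multi-view point sets share one frame.
#'
#' @param points A `point3d_set` (see [point3d_set()]) or an n x 3 matrix.
#' @param angle Turntable angle in degrees.
#' @param axis_point 3-vector on the rotation axis (metres).
#' @param axis_dir Unit 3-vector along the axis.
#' @return Same container as the input with rotated coordinates.
#' @export
reverse_rotate <- function(points, angle, axis_point = c(0, 0, 0),
                           axis_dir = c(0, 0, 1)) {
  R <- rotation_about_axis(-angle, axis_dir)
  rot <- function(m) sweep(sweep(m, 2, axis_point) %*% t(R), 2, axis_point, "+")
  if (inherits(points, "point3d_set")) {
    points[, c("x", "y", "z")] <- rot(as.matrix(points[, c("x", "y", "z")]))
    points
  } else if (is.null(dim(points))) {
    drop(rot(matrix(points, 1, 3)))
  } else {
    rot(as.matrix(points))
  }
}

#' Tagged 3-D point set
#'
#' A data frame of 3-D points, each tagged with the measurement-line index
#' and the turntable angle of the view it was reconstructed from.
#'
#' @param xyz n x 3 matrix of coordinates in metres.
#' @param line Integer line index (recycled).
#' @param angle Turntable angle in degrees (recycled).
#' @return A `point3d_set` (a classed data frame with columns
#'   `x, y, z, line, angle`).
#' @export
point3d_set <- function(xyz, line = 0L, angle = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       line = as.integer(line), angle = as.numeric(angle)),
            class = c("point3d_set", "data.frame"))
}

# ---- calibration file I/O -------------------------------------------------

#' Read / write stereo calibration files
#'
#' Plain-text YAML schema with per-camera intrinsics (`fx, fy, cx, cy,
#' width, height`), the right-from-left rotation (9 values, row-major) and
#' translation (metres), and the shooting distance `D`.
#'
#' @param path File path.
#' @return `read_calibration` returns a `stereo_rig`;
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  cam <- function(b) camera_intrinsics(b$fx, b$fy, b$cx, b$cy, b$width, b$height)
  stereo_rig(cam(y$left), cam(y$right),
             rigid_transform(matrix(unlist(y$rotation), 3, 3, byrow = TRUE),
                             unlist(y$translation)),
             y$shooting_distance_D)
}

#' @rdname read_calibration
#' @param rig A `stereo_rig` to serialize.
#' @export
write_calibration <- function(rig, path) {
  cam <- function(k) list(fx = k$fx, fy = k$fy, cx = k$cx, cy = k$cy,
                          width = k$width, height = k$height)
  yaml::write_yaml(list(
    left = cam(rig$left), right = cam(rig$right),
    rotation = as.list(as.vector(t(rig$right_from_left$R))),
    translation = as.list(rig$right_from_left$t),
    shooting_distance_D = rig$D), path, precision = 15)
  invisible(path)
}

#' Build a canonical (slightly verged) stereo rig
#'
#' Places the right camera a baseline to the left camera's right and, when
#' `verged = TRUE`, rotates it so both optical axes converge at the shooting
#' distance `D` — the usual close-range anthropometric arrangement.  With
#' `verged = FALSE` the cameras are parallel (rectified-style geometry).
#'
#' @param focal Focal length in pixels (isotropic).
#' @param width,height Image size in pixels.
#' @param baseline Baseline length in metres.
#' @param D Shooting distance in metres.
#' @param verged Logical; default slightly verged.
#' @return A `stereo_rig`.
#' @export
make_default_rig <- function(focal = 1100, width = 320, height = 240,
                             baseline = 0.3, D = 2.4, verged = TRUE) {
  cam <- camera_intrinsics(focal, focal, (width - 1) / 2, (height - 1) / 2,
                           width, height)
  if (verged) {
    # converge the right optical axis on the point D ahead of the left camera
    ang <- atan2(baseline, D)   # rotate about +y (x right, z forward)
    R <- rotation_about_axis(ang * 180 / pi, c(0, 1, 0))
    t <- drop(R %*% c(-baseline, 0, 0))
    rfl <- rigid_transform(R, t)
  } else {
    rfl <- rigid_transform(diag(3), c(-baseline, 0, 0))
  }
  stereo_rig(cam, cam, rfl, D)
}
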