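# Synthetic stereo-scene simulator.
#
# Renders a checkerboard-textured elliptic-cylinder body segment with red
# and cyan circular markers on a turntable, seen by a calibrated stereo rig,
# and returns exact analytic ground truth (corner 3-D positions, marker
# centres, segmentation masks, true girths).  Rendering is analytic
# ray-ellipse intersection per pixel with flat colours, optional
# supersampling for anti-aliasing and optional Gaussian pixel noise -- no
# external renderer, so every rendered structure has a closed-form oracle.
#
# World frame: z up along the turntable axis (through the origin), the left
# camera a shooting distance D in front of the subject.  The checkerboard is
# laid out by surface arc length so adjacent corners are exactly one
# interval apart along the circumference; the cross-section perimeter must
# therefore be an even integer number of intervals for a seamless pattern.

#' Ellipse perimeter by adaptive quadrature
#' @param a,b Semi-axes in metres.
#' @return Perimeter in metres.
#' @export
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

#' Ellipse semi-axes for a target girth
#' @param girth Target perimeter in metres.
#' @param aspect Ratio `b / a` of the semi-axes (1 = circle).
#' @return Length-2 vector `c(a, b)`.
#' @export
ellipse_axes_for_girth <- function(girth, aspect = 1) {
  p1 <- ellipse_perimeter(1, aspect)
  scale <- girth / p1
  c(a = scale, b = scale * aspect)
}

# arc-length parameterization s(theta) and inverse theta(s) on a fine grid
arclength_tables <- function(a, b, n = 8192L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  mid <- (th[-1] + th[-(n + 1L)]) / 2
  seg <- sqrt(a^2 * sin(mid)^2 + b^2 * cos(mid)^2) * diff(th)
  s <- c(0, cumsum(seg))
  list(s_of_theta = stats::approxfun(th, s),
       theta_of_s = stats::approxfun(s, th),
       perimeter = s[n + 1L])
}

#' Body segment model: checkerboard-textured elliptic cylinder
#'
#' @param a,b Cross-section semi-axes in metres; the perimeter must be an
#'   even integer multiple of `checkerboard_interval` (within 1e-6 m) for
#'   the checkerboard to close seamlessly around the seam.
#' @param height_range Axial extent in metres (length 2).
#' @param checkerboard_interval Cell spacing along the surface (default
#'   0.025 m, the 2.5 cm suit spacing).
#' @param axis_point,axis_dir Turntable axis (world frame).
#' @return An object of class `body_segment_model`.
#' @export
body_segment_model <- function(a, b = a, height_range = c(-0.085, 0.085),
                               checkerboard_interval = 0.025,
                               axis_point = c(0, 0, 0),
                               axis_dir = c(0, 0, 1)) {
  stopifnot(a > 0, b > 0, checkerboard_interval > 0,
            height_range[1] < height_range[2])
  per <- ellipse_perimeter(a, b)
  ncols <- per / checkerboard_interval
  if (abs(ncols - round(ncols)) > 1e-4 || round(ncols) %% 2 != 0)
    stop("perimeter must be an even integer number of checkerboard intervals; ",
         "use ellipse_axes_for_girth()")
  structure(list(a = a, b = b, height_range = height_range,
                 interval = checkerboard_interval, axis_point = axis_point,
                 axis_dir = axis_dir, perimeter = per,
                 n_cols = as.integer(round(ncols))),
            class = "body_segment_model")
}

#' Marker layout on the checkerboard grid
#'
#' Four circular markers (red, cyan, red, cyan in circumferential order)
#' whose consecutive horizontal spacings are `horizontal` checkerboard
#' intervals (summing to the full circumference) and whose vertical offsets
#' alternate by `vertical` intervals, so each turntable view sees exactly
#' one red and one cyan marker and the rectangle between their centroids
#' brackets the same measurement baseline in every view.  Marker centres sit
#' at cell centres (half-interval offsets), so consecutive view rectangles
#' tile all corner columns without overlap.
#'
#' @param horizontal Circumferential spacings in intervals (default
#'   `c(8, 7, 8, 7)`).
#' @param vertical Vertical marker-to-marker offsets in intervals (default
#'   `c(-1, 1, -1, 1)`).
#' @param radius Marker radius in metres (default 0.006).
#' @return An object of class `marker_layout`.
#' @export
marker_layout <- function(horizontal = c(8, 7, 8, 7),
                          vertical = c(-1, 1, -1, 1), radius = 0.006) {
  stopifnot(length(horizontal) == length(vertical),
            length(horizontal) %% 2 == 0, radius > 0)
  if (abs(sum(vertical)) > 1e-9)
    stop("vertical offsets must sum to zero (markers must close around the body)")
  structure(list(horizontal = horizontal, vertical = vertical,
                 radius = radius, s_offset = -0.5, row_offset = 0.5),
            class = "marker_layout")
}

# physical marker positions (s along circumference, h height), colours
marker_positions <- function(layout, model) {
  t <- model$interval
  n <- length(layout$horizontal)
  if (sum(layout$horizontal) != model$n_cols)
    stop("marker horizontal spacings must sum to the column count (",
         model$n_cols, ")")
  s <- numeric(n); h <- numeric(n)
  s[1] <- layout$s_offset * t
  h[1] <- layout$row_offset * t
  for (m in seq_len(n - 1)) {
    s[m + 1] <- s[m] + layout$horizontal[m] * t
    h[m + 1] <- h[m] + layout$vertical[m] * t
  }
  data.frame(s = s %% model$perimeter, h = h,
             color = rep(c("red", "cyan"), length.out = n))
}

scene_colors <- list(black = c(0.12, 0.12, 0.12), white = c(0.96, 0.96, 0.96),
                     red = c(0.80, 0.10, 0.10), cyan = c(0.10, 0.80, 0.80),
                     background = c(0.50, 0.50, 0.55))

rot_z <- function(deg) rotation_about_axis(deg, c(0, 0, 1))

# world -> left-camera transform: camera on -y at distance D, looking at the
# origin, x right (world +x), y down (world -z)
world_from_left_camera <- function(D) {
  R <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  rigid_transform(R, c(0, 0, D))
}

# phase aligning the first marker pair with the left camera at angle 0
default_phase <- function(layout, model) {
  t <- model$interval
  mid_s <- layout$s_offset * t + layout$horizontal[1] * t / 2
  -90 - 360 * mid_s / model$perimeter
}

# raycast one camera: returns list of per-pixel fields at supersampled res
raycast <- function(model, layout, world_from_cam, cam, phi_deg, supersample) {
  ss <- supersample
  W2 <- cam$width * ss; H2 <- cam$height * ss
  fx <- cam$fx * ss; fy <- cam$fy * ss
  cx <- (cam$cx + 0.5) * ss - 0.5; cy <- (cam$cy + 0.5) * ss - 0.5
  u <- rep(0:(W2 - 1), each = H2); v <- rep(0:(H2 - 1), times = W2)
  dirc <- cbind((u - cx) / fx, (v - cy) / fy, 1)
  Rcw <- t(world_from_cam$R)
  oc <- drop(-Rcw %*% world_from_cam$t)           # camera centre, world
  dw <- dirc %*% world_from_cam$R                 # = t(Rcw %*% t(dirc))
  Rb <- rot_z(-phi_deg)                           # world -> body
  ob <- drop(Rb %*% oc)
  db <- dw %*% t(Rb)
  a <- model$a; b <- model$b
  A <- (db[, 1] / a)^2 + (db[, 2] / b)^2
  B <- 2 * (ob[1] * db[, 1] / a^2 + ob[2] * db[, 2] / b^2)
  C <- (ob[1] / a)^2 + (ob[2] / b)^2 - 1
  disc <- B^2 - 4 * A * C
  hit <- disc > 0
  tq <- rep(NA_real_, length(A))
  tq[hit] <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
  hit <- hit & tq > 0
  px <- ob[1] + tq * db[, 1]; py <- ob[2] + tq * db[, 2]
  pz <- ob[3] + tq * db[, 3]
  hit <- hit & !is.na(pz) & pz >= model$height_range[1] &
    pz <= model$height_range[2]
  tab <- arclength_tables(a, b)
  th <- atan2(py / b, px / a) %% (2 * pi)
  s <- tab$s_of_theta(th)
  list(hit = hit, s = s, h = pz, H2 = H2, W2 = W2)
}

shade <- function(rc, model, layout, mpos) {
  t <- model$interval
  col_idx <- floor(rc$s / t)
  row_idx <- floor(rc$h / t)
  parity <- (col_idx + row_idx) %% 2
  rgb <- matrix(0, length(rc$hit), 3)
  rgb[] <- matrix(scene_colors$background, length(rc$hit), 3, byrow = TRUE)
  paint <- function(sel, col) {
    if (any(sel, na.rm = TRUE)) {
      sel <- which(sel)
      rgb[sel, ] <<- matrix(col, length(sel), 3, byrow = TRUE)
    }
  }
  paint(rc$hit & parity == 0, scene_colors$white)
  paint(rc$hit & parity == 1, scene_colors$black)
  for (m in seq_len(nrow(mpos))) {
    d0 <- abs(rc$s - mpos$s[m])
    ds <- pmin(d0, model$perimeter - d0)
    dh <- rc$h - mpos$h[m]
    paint(rc$hit & (ds^2 + dh^2 <= layout$radius^2),
          scene_colors[[mpos$color[m]]])
  }
  rgb
}

# average ss x ss blocks of a (H2 x W2) field laid out column-major v-fastest
downsample_field <- function(vals, H2, W2, ss) {
  arr <- matrix(vals, H2, W2)
  H <- H2 %/% ss; W <- W2 %/% ss
  # sum over row blocks then column blocks
  rb <- rowsum(arr, group = rep(seq_len(H), each = ss))
  t(rowsum(t(rb), group = rep(seq_len(W), each = ss))) / ss^2
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

#' Render one stereo view of the synthetic scene
#'
#' Ray-traces the checkerboard-textured body segment (rotated to the given
#' turntable angle) into both cameras of the rig and returns the 8-bit RGB
#' images, binary segmentation masks, and exact ground truth.
#'
#' @param model A [body_segment_model()].
#' @param layout A [marker_layout()].
#' @param rig A [stereo_rig()]; the left camera sits the rig's shooting
#'   distance in front of the turntable axis.
#' @param turntable_angle Turntable angle in degrees.
#' @param seed Seed for the pixel noise.
#' @param noise_sigma Gaussian pixel noise standard deviation on the 8-bit
#'   scale (default 0).
#' @param supersample Anti-aliasing factor (default 3).
#' @param phase Initial turntable phase in degrees; by default aligns the
#'   first marker pair with the camera at angle 0.
#' @return List with `left`, `right` (H x W x 3 arrays in `[0,1]`),
#'   `mask_left`, `mask_right` (logical matrices) and `gt` (ground truth:
#'   corner and marker tables, effective angle, true girth).
#' @export
render_view <- function(model, layout, rig, turntable_angle, seed = 0L,
                        noise_sigma = 0, supersample = 3L,
                        phase = default_phase(layout, model)) {
  mpos <- marker_positions(layout, model)
  phi <- turntable_angle + phase
  wfl <- world_from_left_camera(rig$D)
  wfr <- compose_transform(rig$right_from_left, wfl)
  render_cam <- function(wfc, cam) {
    rc <- raycast(model, layout, wfc, cam, phi, supersample)
    rgb <- shade(rc, model, layout, mpos)
    H <- cam$height; W <- cam$width
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- downsample_field(rgb[, ch], rc$H2, rc$W2, supersample)
    mask <- downsample_field(as.numeric(rc$hit), rc$H2, rc$W2, supersample) > 0.5
    list(img = img, mask = mask)
  }
  L <- render_cam(wfl, rig$left)
  R <- render_cam(wfr, rig$right)
  gt <- scene_ground_truth(model, layout, rig, phi, wfl, wfr)
  if (!any(L$mask) || !any(R$mask)) stop("out of view: segment not visible")
  add_noise <- function(img, seed_off) {
    img <- quantize8(img)
    if (noise_sigma > 0) {
      set.seed(seed + seed_off)
      img <- quantize8(img + array(stats::rnorm(length(img),
                                                sd = noise_sigma / 255),
                                   dim(img)))
    }
    img
  }
  list(left = add_noise(L$img, 1L), right = add_noise(R$img, 2L),
       mask_left = L$mask, mask_right = R$mask, gt = gt,
       turntable_angle = turntable_angle, phase = phase)
}

# exact ground truth: corner grid + marker centres, 3-D and projections
scene_ground_truth <- function(model, layout, rig, phi, wfl, wfr) {
  t <- model$interval
  tab <- arclength_tables(model$a, model$b)
  rows <- seq(ceiling(model$height_range[1] / t),
              floor(model$height_range[2] / t))
  cols <- 0:(model$n_cols - 1)
  grid <- expand.grid(col = cols, row = rows)
  th <- tab$theta_of_s(grid$col * t)
  pb <- cbind(model$a * cos(th), model$b * sin(th), grid$row * t)
  Rw <- rot_z(phi)
  pw <- pb %*% t(Rw)
  # outward normal of the elliptic cylinder, rotated to world
  nb <- cbind(cos(th) / model$a, sin(th) / model$b, 0)
  nb <- nb / sqrt(rowSums(nb^2))
  nw <- nb %*% t(Rw)
  project_tab <- function(wfc, cam) {
    pc <- transform_points(wfc, pw)
    ok <- pc[, 3] > 0
    uv <- matrix(NA_real_, nrow(pw), 2)
    uv[ok, ] <- cbind(cam$fx * pc[ok, 1] / pc[ok, 3] + cam$cx,
                      cam$fy * pc[ok, 2] / pc[ok, 3] + cam$cy)
    ccen <- drop(-t(wfc$R) %*% wfc$t)
    vdir <- sweep(-pw, 2, ccen, "+")
    vdir <- vdir / sqrt(rowSums(vdir^2))
    cosv <- rowSums(nw * vdir)
    inb <- ok & uv[, 1] >= 0 & uv[, 1] <= cam$width - 1 &
      uv[, 2] >= 0 & uv[, 2] <= cam$height - 1
    list(uv = uv, cos = cosv, visible = inb & cosv > 0)
  }
  pl <- project_tab(wfl, rig$left); pr <- project_tab(wfr, rig$right)
  corners <- data.frame(col = grid$col, row = grid$row,
                        x_body = pb[, 1], y_body = pb[, 2], z_body = pb[, 3],
                        x = pw[, 1], y = pw[, 2], z = pw[, 3],
                        lx = pl$uv[, 1], ly = pl$uv[, 2],
                        rx = pr$uv[, 1], ry = pr$uv[, 2],
                        cos_left = pl$cos, cos_right = pr$cos,
                        visible = pl$visible & pr$visible)
  mpos <- marker_positions(layout, model)
  mth <- tab$theta_of_s(mpos$s)
  mb <- cbind(model$a * cos(mth), model$b * sin(mth), mpos$h)
  mw <- mb %*% t(Rw)
  mcen <- drop(-t(wfl$R) %*% wfl$t)
  mdir <- sweep(-mw, 2, mcen, "+"); mdir <- mdir / sqrt(rowSums(mdir^2))
  mnb <- cbind(cos(mth) / model$a, sin(mth) / model$b, 0)
  mnb <- (mnb / sqrt(rowSums(mnb^2))) %*% t(Rw)
  mvis <- rowSums(mnb * mdir) > 0.05
  mpl <- matrix(NA_real_, nrow(mw), 2); mprj <- matrix(NA_real_, nrow(mw), 2)
  pcl <- transform_points(wfl, mw); pcr <- transform_points(wfr, mw)
  okl <- pcl[, 3] > 0; okr <- pcr[, 3] > 0
  mpl[okl, ] <- cbind(rig$left$fx * pcl[okl, 1] / pcl[okl, 3] + rig$left$cx,
                      rig$left$fy * pcl[okl, 2] / pcl[okl, 3] + rig$left$cy)
  mprj[okr, ] <- cbind(rig$right$fx * pcr[okr, 1] / pcr[okr, 3] + rig$right$cx,
                       rig$right$fy * pcr[okr, 2] / pcr[okr, 3] + rig$right$cy)
  markers <- data.frame(color = mpos$color, s = mpos$s, h = mpos$h,
                        x = mw[, 1], y = mw[, 2], z = mw[, 3],
                        lx = mpl[, 1], ly = mpl[, 2],
                        rx = mprj[, 1], ry = mprj[, 2],
                        front = mvis)
  list(corners = corners, markers = markers, effective_angle = phi,
       true_girth = model$perimeter,
       world_from_left = wfl, world_from_right = wfr)
}

#' Generate a full turntable measurement session
#'
#' Renders one stereo pair per turntable angle (default 0/90/180/270
#' degrees), so that consecutive marker-pair rectangles tile every corner
#' column of the measurement baseline and the union of views covers the full
#' circumference.
#'
#' @inheritParams render_view
#' @param angles Distinct turntable angles in degrees (at least 2).
#' @param seed Session seed; each view derives its noise stream from it.
#' @return An object of class `measurement_session`: per-view renders plus
#'   rig, model, layout, effective angles, the turntable axis and the pixel
#'   step of one checkerboard interval.
#' @export
generate_measurement_session <- function(model, layout, rig,
                                         angles = c(0, 90, 180, 270),
                                         seed = 0L, noise_sigma = 0,
                                         supersample = 3L,
                                         phase = default_phase(layout, model)) {
  if (length(angles) < 2) stop("insufficient coverage: need at least 2 angles")
  if (anyDuplicated(angles)) stop("angles must be distinct")
  views <- lapply(seq_along(angles), function(k)
    render_view(model, layout, rig, angles[k], seed = seed + 1000L * k,
                noise_sigma = noise_sigma, supersample = supersample,
                phase = phase))
  structure(list(views = views, rig = rig, model = model, layout = layout,
                 angles = angles, phase = phase,
                 effective_angles = angles + phase,
                 axis_point = model$axis_point, axis_dir = model$axis_dir,
                 nstep_px = rig$left$fy * model$interval / rig$D,
                 seed = seed, noise_sigma = noise_sigma),
            class = "measurement_session")
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf(paste0("<measurement_session: %d views at %s deg, girth %.2f cm,",
                     " noise sigma %.1f>\n"),
              length(x$views), paste(x$angles, collapse = "/"),
              100 * x$model$perimeter, x$noise_sigma))
  invisible(x)
}

#' Procedural image/label fixtures for segmentation training
#'
#' Tiny stand-in corpus for a body-segmentation training set: each fixture
#' is an RGB image of a randomly placed, rotated elliptic "body region"
#' against a darker background, both colour-jittered with Gaussian noise,
#' plus its binary label mask (0 background, 1 region).
#'
#' @param n Number of fixtures (>= 1).
#' @param image_size Side length in pixels (default 32).
#' @param seed RNG seed; fixtures are reproducible per seed.
#' @param noise_sd Pixel noise standard deviation in `[0,1]` units.
#' @return List of `n` lists with elements `image` (H x W x 3) and `mask`
#'   (integer matrix).
#' @export
generate_segmentation_fixtures <- function(n, image_size = 32L, seed = 0L,
                                           noise_sd = 0.03) {
  if (n < 1) stop("invalid count: n must be >= 1")
  set.seed(seed)
  H <- image_size; W <- image_size
  lapply(seq_len(n), function(i) {
    cx <- stats::runif(1, 0.3, 0.7) * W; cy <- stats::runif(1, 0.3, 0.7) * H
    ax <- stats::runif(1, 0.18, 0.38) * W; by <- stats::runif(1, 0.18, 0.38) * H
    ang <- stats::runif(1, 0, pi)
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), times = W), H, W)
    xr <- (xs - cx) * cos(ang) + (ys - cy) * sin(ang)
    yr <- -(xs - cx) * sin(ang) + (ys - cy) * cos(ang)
    mask <- (xr / ax)^2 + (yr / by)^2 <= 1
    fg <- c(0.85, 0.70, 0.60) + stats::rnorm(3, sd = 0.05)
    bg <- c(0.30, 0.38, 0.50) + stats::rnorm(3, sd = 0.05)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- ifelse(mask, fg[ch], bg[ch]) +
        stats::rnorm(H * W, sd = noise_sd)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = matrix(as.integer(mask), H, W))
  })
}
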