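# HSV colour classification and marker-centroid extraction.
#
# The segmented suit images contain four colours: red and cyan circular
# markers that anchor the regional constraint, and the black/white cells of
# the checkerboard.  Colours are classified in HSV with H in [0, 180] and
# S, V in [0, 255] (the usual 8-bit machine-vision convention); red owns two
# hue intervals around the hue wrap.

#' Default HSV classification ranges
#'
#' Per-colour `[min, max]` bounds for H (two intervals for red), S and V.
#' Value dominates: a pixel dark enough to be black is black regardless of
#' hue; white requires high value and low saturation.  Every bound is
#' configurable; the defaults are the published calibration for this suit.
#'
#' @param white_v_max Upper value bound for white; default 255.
#' @return An object of class `hsv_ranges`.
#' @export
hsv_ranges <- function(white_v_max = 255) {
  structure(list(
    red = list(h = rbind(c(0, 10), c(156, 180)), s = c(45, 255), v = c(46, 255)),
    cyan = list(h = rbind(c(78, 99)), s = c(43, 255), v = c(46, 255)),
    black = list(h = c(0, 180), s = c(0, 255), v = c(0, 46)),
    white = list(h = c(0, 180), s = c(0, 30), v = c(221, white_v_max))),
    class = "hsv_ranges")
}

#' Convert RGB in [0,1] to machine-vision HSV
#'
#' @param r,g,b Numeric vectors in `[0, 1]`.
#' @return Matrix with columns `h` in `[0, 180]`, `s`, `v` in `[0, 255]`.
#' @export
rgb_to_hsv180 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b) * 255, maxColorValue = 255)
  cbind(h = hsv[1, ] * 180, s = hsv[2, ] * 255, v = hsv[3, ] * 255)
}

in_range <- function(x, lim, half_open) {
  if (half_open) x >= lim[1] & x < lim[2] else x >= lim[1] & x <= lim[2]
}

#' Classify HSV pixels into marker / checkerboard colours
#'
#' Black is tested first (low value dominates), then white (high value, low
#' saturation), then red and cyan by hue with saturation/value floors.
#' Intervals are half-open `[min, max)` except at the scale tops (180, 255),
#' which are closed so pure white and wrap-around red stay classifiable.
#'
#' @param h,s,v Numeric vectors: H in `[0, 180]`, S and V in `[0, 255]`.
#' @param ranges An [hsv_ranges()] object.
#' @return Character vector of labels in
#'   `c("red", "cyan", "black", "white", "other")`.
#' @export
classify_hsv <- function(h, s, v, ranges = hsv_ranges()) {
  if (any(h < 0 | h > 180 | s < 0 | s > 255 | v < 0 | v > 255))
    stop("invalid HSV: components out of range")
  ho <- function(lim) in_range(h, lim, half_open = lim[2] < 180)
  so <- function(lim) in_range(s, lim, half_open = lim[2] < 255)
  vo <- function(lim) in_range(v, lim, half_open = lim[2] < 255)
  lab <- rep("other", length(h))
  blk <- ranges$black
  is_black <- vo(blk$v) & so(blk$s) & ho(blk$h)
  wht <- ranges$white
  is_white <- !is_black & vo(wht$v) & so(wht$s) & ho(wht$h)
  red <- ranges$red
  hred <- ho(red$h[1, ]) | ho(red$h[2, ])
  is_red <- !is_black & !is_white & hred & so(red$s) & vo(red$v)
  cyn <- ranges$cyan
  is_cyan <- !is_black & !is_white & !is_red & ho(cyn$h[1, ]) &
    so(cyn$s) & vo(cyn$v)
  lab[is_black] <- "black"; lab[is_white] <- "white"
  lab[is_red] <- "red"; lab[is_cyan] <- "cyan"
  lab
}

#' Extract the pixel set of a colour marker
#'
#' Classifies every pixel of an RGB image and collects the coordinates of
#' those matching the requested colour.  Coordinates are 0-based pixel
#' centres, x rightward and y downward.
#'
#' @param image RGB array `(H, W, 3)` with values in `[0, 1]`.
#' @param color One of `"red"`, `"cyan"`, `"black"`, `"white"`.
#' @param ranges An [hsv_ranges()].
#' @param required Signal an error when no pixel matches (default TRUE).
#' @return An object of class `pixel_set`: list with `x`, `y`, `n`, `color`.
#' @export
extract_marker_set <- function(image, color, ranges = hsv_ranges(),
                               required = TRUE) {
  d <- dim(image)
  hsv <- rgb_to_hsv180(as.vector(image[, , 1]), as.vector(image[, , 2]),
                       as.vector(image[, , 3]))
  lab <- classify_hsv(hsv[, 1], hsv[, 2], hsv[, 3], ranges)
  sel <- lab == color
  if (!any(sel)) {
    if (required) stop("marker not found: no ", color, " pixels in image")
    return(structure(list(x = numeric(0), y = numeric(0), n = 0L,
                          color = color), class = "pixel_set"))
  }
  # image arrays are (row, col) = (y, x); linear index is row-fastest
  rows <- (which(sel) - 1L) %% d[1]
  cols <- (which(sel) - 1L) %/% d[1]
  structure(list(x = as.numeric(cols), y = as.numeric(rows),
                 n = sum(sel), color = color), class = "pixel_set")
}

#' @export
print.pixel_set <- function(x, ...) {
  cat(sprintf("<pixel_set: %s, %d px, centroid (%.2f, %.2f)>\n", x$color,
              x$n, mean(x$x), mean(x$y)))
  invisible(x)
}

#' Centroid of a pixel set
#'
#' Arithmetic mean of the member pixel coordinates — the sub-pixel marker
#' centre used to anchor the regional constraint.
#'
#' @param set A `pixel_set`.
#' @return Length-2 numeric `(x, y)` in pixels.
#' @export
centroid <- function(set) {
  if (set$n < 1) stop("empty pixel set")
  c(x = mean(set$x), y = mean(set$y))
}

#' Marker centroids for one stereo view pair
#'
#' Extracts red and cyan marker pixel sets from the left and right images
#' and computes their centroids.
#'
#' @param left,right RGB arrays `(H, W, 3)`.
#' @param ranges An [hsv_ranges()].
#' @return Object of class `marker_centroids`: list of `(x, y)` centroids
#'   `l_red`, `l_cyan`, `r_red`, `r_cyan`, plus the pixel sets.
#' @export
marker_centroids <- function(left, right, ranges = hsv_ranges()) {
  sets <- list(l_red = extract_marker_set(left, "red", ranges),
               l_cyan = extract_marker_set(left, "cyan", ranges),
               r_red = extract_marker_set(right, "red", ranges),
               r_cyan = extract_marker_set(right, "cyan", ranges))
  structure(list(l_red = centroid(sets$l_red), l_cyan = centroid(sets$l_cyan),
                 r_red = centroid(sets$r_red), r_cyan = centroid(sets$r_cyan),
                 sets = sets),
            class = "marker_centroids")
}

#' Shift the marker baseline for multi-line matching
#'
#' Moves all four marker centroids along image y by `offset * n_step`
#' pixels, selecting the corner row `offset` checkerboard intervals above or
#' below the original measurement baseline.
#'
#' @param centroids A `marker_centroids`.
#' @param offset Integer multiple of the step (positive = down).
#' @param n_step Pixel step of one checkerboard interval (see [nstep()]).
#' @param image_height Optional bound check: signal "shift out of bounds"
#'   when any shifted centroid leaves the image.
#' @return A shifted `marker_centroids`.
#' @export
shift_baseline <- function(centroids, offset, n_step, image_height = NULL) {
  dy <- offset * n_step
  out <- centroids
  for (f in c("l_red", "l_cyan", "r_red", "r_cyan")) {
    out[[f]]["y"] <- centroids[[f]]["y"] + dy
    if (!is.null(image_height) &&
        (out[[f]]["y"] < 0 || out[[f]]["y"] > image_height - 1))
      stop("shift out of bounds: marker rectangle leaves the image")
  }
  out
}
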