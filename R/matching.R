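# Corner-based stereo matching with the marker-rectangle regional
# constraint and x-order correspondence.
#
# Both views of a checkerboard-suited body segment contain one red and one
# cyan marker; the axis-aligned rectangle spanned by their centroids
# isolates a single row of checkerboard corners, and because the corners on
# one row are ordered identically in both views, sorting each constrained
# set by x and pairing by rank yields the stereo correspondence without any
# descriptor matching.

#' Constrain a corner set to the marker rectangle
#'
#' Keeps exactly the corners strictly inside the axis-aligned rectangle
#' spanned by the red and cyan marker centroids (symmetric in the two
#' markers).  Corners exactly on the boundary are excluded.
#'
#' @param corners A `corner_set`.
#' @param red,cyan Length-2 centroids `(x, y)`.
#' @return The constrained `corner_set`.  Signals "constraint too tight"
#'   when fewer than 2 corners survive.
#' @export
regional_constrain <- function(corners, red, cyan) {
  if (red[1] == cyan[1] || red[2] == cyan[2])
    stop("marker centroids must differ in both x and y")
  xin <- corners$x > min(red[1], cyan[1]) & corners$x < max(red[1], cyan[1])
  yin <- corners$y > min(red[2], cyan[2]) & corners$y < max(red[2], cyan[2])
  out <- corners[xin & yin, , drop = FALSE]
  if (nrow(out) < 2)
    stop(sprintf(paste0("constraint too tight: %d corner(s) inside rectangle",
                        " x(%.1f, %.1f) y(%.1f, %.1f)"), nrow(out),
                 min(red[1], cyan[1]), max(red[1], cyan[1]),
                 min(red[2], cyan[2]), max(red[2], cyan[2])))
  attr(out, "view") <- attr(corners, "view")
  class(out) <- class(corners)
  out
}

#' Order constrained corner sets and pair by rank
#'
#' Sorts each constrained set by ascending x (ties broken by ascending y —
#' a single corner row cannot produce x ties, the tie-break only makes the
#' order total) and pairs the i-th left corner with the i-th right corner.
#'
#' @param left,right Constrained `corner_set`s with equal counts.
#' @param line Line index tag.
#' @param angle Turntable angle tag (degrees).
#' @return A `matched_pairs` data frame with columns
#'   `i, xl, yl, xr, yr`.  Signals "count mismatch" on unequal counts — no
#'   silent truncation.
#' @export
order_and_match <- function(left, right, line = 0L, angle = 0) {
  if (nrow(left) != nrow(right))
    stop(sprintf("count mismatch: %d left vs %d right constrained corners",
                 nrow(left), nrow(right)))
  ol <- order(left$x, left$y); or <- order(right$x, right$y)
  structure(data.frame(i = seq_len(nrow(left)),
                       xl = left$x[ol], yl = left$y[ol],
                       xr = right$x[or], yr = right$y[or]),
            line = line, angle = angle,
            class = c("matched_pairs", "data.frame"))
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs: %d pairs, line %s, angle %s deg>\n", nrow(x),
              attr(x, "line"), attr(x, "angle")))
  if (nrow(x)) print.data.frame(utils::head(x, 8))
  invisible(x)
}

#' Checkerboard interval pixel step at a shooting distance
#'
#' Evaluates the fitted distance-to-step polynomial
#' `7.02 D^2 - 45.18 D + 93.43` and rounds to the nearest integer pixel —
#' the image-space distance between adjacent checkerboard corners for the
#' calibrated measurement rig, strictly decreasing in `D` over its validity
#' range.
#'
#' @param D Shooting distance in metres (> 0).
#' @param validity Fitted validity range in metres; values outside produce
#'   a warning but are still returned.
#' @return Integer pixel step.
#' @export
nstep <- function(D, validity = c(1.5, 3.0)) {
  stopifnot(D > 0)
  if (D < validity[1] || D > validity[2])
    warning(sprintf("D = %.2f m outside the fitted validity range [%.1f, %.1f] m",
                    D, validity[1], validity[2]))
  as.integer(round(7.02 * D^2 - 45.18 * D + 93.43))
}

# dilated exclusion mask of marker pixels (markers interrupt the
# checkerboard, so responses on their boundaries are not grid corners)
marker_exclusion_mask <- function(sets, dim_hw, dilate = 0L) {
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  for (s in sets) if (s$n > 0) m[cbind(s$y + 1, s$x + 1)] <- TRUE
  if (dilate > 0) {
    box <- rep(1, 2L * dilate + 1L)
    m <- convolve_sep(m + 0, box) > 1e-9
  }
  m
}

#' Default corner-detector parameters
#'
#' @param quality Response fraction threshold.
#' @param min_distance Non-maximum-suppression radius in pixels (about half
#'   the checkerboard pixel step).
#' @param window_size,sigma Structure-tensor window and pre-smoothing.
#' @param refine_window Sub-pixel refinement half-window.
#' @return Named list of parameters.
#' @export
detector_params <- function(quality = 0.05, min_distance = 5,
                            window_size = 5L, sigma = 1.0,
                            refine_window = 5L) {
  list(quality = quality, min_distance = min_distance,
       window_size = window_size, sigma = sigma,
       refine_window = refine_window)
}

#' Refined stereo matching of one segmented stereo pair
#'
#' Runs the full marker-constrained matching sequence on a left/right image
#' pair: extract red and cyan marker pixel sets and centroids, detect
#' Shi-Tomasi corners at sub-pixel accuracy inside the segmented region
#' (marker footprints excluded), constrain both corner sets to the marker
#' rectangle, order by x and pair by rank.  An optional baseline shift of
#' `shift_offset * n_step` pixels selects the corner row above or below the
#' marker baseline for multi-line measurement.
#'
#' @param left,right RGB arrays `(H, W, 3)`.
#' @param ranges An [hsv_ranges()].
#' @param params A [detector_params()] list.
#' @param mask_left,mask_right Optional logical segmentation masks.
#' @param shift_offset Integer multiple of `n_step` to shift the baseline.
#' @param n_step Pixel step of one checkerboard interval (required when
#'   `shift_offset != 0`).
#' @param line Line tag stored on the result.
#' @param angle Turntable angle tag.
#' @return A `matched_pairs` object; errors from any stage ("marker not
#'   found", "constraint too tight", "count mismatch") propagate.
#' @export
run_algorithm1 <- function(left, right, ranges = hsv_ranges(),
                           params = detector_params(),
                           mask_left = NULL, mask_right = NULL,
                           shift_offset = 0L, n_step = NULL,
                           line = shift_offset, angle = 0) {
  cents <- marker_centroids(left, right, ranges)
  if (shift_offset != 0L) {
    if (is.null(n_step)) stop("n_step required for a shifted baseline")
    cents <- shift_baseline(cents, shift_offset, n_step,
                            image_height = dim(left)[1])
  }
  corners_view <- function(img, mask, sets, view) {
    excl <- marker_exclusion_mask(sets, dim(img)[1:2])
    m <- if (is.null(mask)) !excl else mask & !excl
    cs <- detect_corners(img, quality = params$quality,
                         min_distance = params$min_distance, mask = m,
                         window_size = params$window_size,
                         sigma = params$sigma, view = view)
    refine_subpixel(img, cs, window = params$refine_window,
                    sigma = params$sigma)
  }
  cl <- corners_view(left, mask_left, cents$sets[c("l_red", "l_cyan")], "left")
  cr <- corners_view(right, mask_right, cents$sets[c("r_red", "r_cyan")], "right")
  sl <- regional_constrain(cl, cents$l_red, cents$l_cyan)
  sr <- regional_constrain(cr, cents$r_red, cents$r_cyan)
  order_and_match(sl, sr, line = line, angle = angle)
}

#' Evaluate matching correctness against simulator ground truth
#'
#' Runs [run_algorithm1()] on every view of a synthetic session and labels
#' each produced pair by the nearest ground-truth corner projection in each
#' view; a pair is mismatched when its two members derive from different
#' physical corners.
#'
#' @param session A `measurement_session`.
#' @param shift_offset Baseline line offset (multiples of the session step).
#' @param params Detector parameters.
#' @return Data frame with one row per view: pairs, mismatches, and the
#'   expected in-rectangle ground-truth corner count.
#' @export
evaluate_matching <- function(session, shift_offset = 0L,
                              params = detector_params()) {
  res <- lapply(seq_along(session$views), function(k) {
    v <- session$views[[k]]
    mp <- run_algorithm1(v$left, v$right, mask_left = v$mask_left,
                         mask_right = v$mask_right, params = params,
                         shift_offset = shift_offset,
                         n_step = session$nstep_px,
                         angle = session$effective_angles[k])
    gtc <- v$gt$corners
    gtc <- gtc[gtc$cos_left > 0 & gtc$cos_right > 0, , drop = FALSE]
    nearest <- function(px, py, gx, gy) {
      vapply(seq_along(px), function(i)
        which.min((gx - px[i])^2 + (gy - py[i])^2), integer(1))
    }
    idl <- nearest(mp$xl, mp$yl, gtc$lx, gtc$ly)
    idr <- nearest(mp$xr, mp$yr, gtc$rx, gtc$ry)
    data.frame(view = k, n_pairs = nrow(mp),
               n_mismatched = sum(idl != idr),
               max_px_err = max(sqrt((gtc$lx[idl] - mp$xl)^2 +
                                     (gtc$ly[idl] - mp$yl)^2)))
  })
  do.call(rbind, res)
}
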