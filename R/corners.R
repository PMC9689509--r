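# Shi-Tomasi corner detection with non-maximum suppression and sub-pixel
# refinement.  The detector scores each pixel by the minimum eigenvalue of
# the local gradient structure tensor; refinement relocates each corner to
# the point where window gradients are orthogonal to the displacement, the
# canonical companion of the minimum-eigenvalue detector.

to_gray <- function(image) {
  if (length(dim(image)) == 2) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# separable convolution with replicated borders
convolve_sep <- function(m, kernel) {
  k <- length(kernel); half <- (k - 1) %/% 2
  pad_rows <- function(m) m[c(rep(1, half), seq_len(nrow(m)), rep(nrow(m), half)), , drop = FALSE]
  conv_cols <- function(m) {
    mp <- pad_rows(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(k)) out <- out + kernel[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  convolve_sep(m, gaussian_kernel(sigma))
}

# central-difference gradients (replicated borders)
image_gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  gx <- (m[, c(2:W, W)] - m[, c(1, 1:(W - 1))]) / 2   # d/dx (columns)
  gy <- (m[c(2:H, H), ] - m[c(1, 1:(H - 1)), ]) / 2   # d/dy (rows)
  list(gx = gx, gy = gy)
}

#' Shi-Tomasi minimum-eigenvalue response map
#'
#' Smooths the grayscale image with a Gaussian, takes central-difference
#' gradients, box-filters the structure-tensor components over
#' `window_size`, and returns the per-pixel minimum eigenvalue
#' `min(lambda1, lambda2)` — near zero on flat regions and straight edges,
#' large only at corners.
#'
#' @param image Grayscale matrix or RGB array; values in `[0, 1]`.
#' @param window_size Odd box window for the structure tensor (default 5).
#' @param sigma Gaussian pre-smoothing in pixels (default 1).
#' @return Matrix of responses, same size as the image.
#' @export
shi_tomasi_response <- function(image, window_size = 5L, sigma = 1.0) {
  g <- to_gray(image)
  if (window_size %% 2 != 1) stop("window_size must be odd")
  if (window_size > min(dim(g))) stop("invalid window: larger than image")
  gs <- gaussian_blur(g, sigma)
  gr <- image_gradients(gs)
  box <- rep(1, window_size) / window_size
  sxx <- convolve_sep(gr$gx * gr$gx, box)
  syy <- convolve_sep(gr$gy * gr$gy, box)
  sxy <- convolve_sep(gr$gx * gr$gy, box)
  tr2 <- (sxx + syy) / 2
  pmax(tr2 - sqrt(pmax(((sxx - syy) / 2)^2 + sxy^2, 0)), 0)
}

#' Detect corners by response maxima with non-maximum suppression
#'
#' Greedy selection of response maxima above `quality * max(response)`,
#' suppressing any candidate within `min_distance` of an accepted corner.
#' When a mask is given (the segmented body region) both the maximum and
#' the candidates are restricted to it.
#'
#' @param image Grayscale matrix or RGB array.
#' @param quality Fraction of the maximum response in `(0, 1)`.
#' @param min_distance Suppression radius in pixels.
#' @param mask Optional logical matrix; candidates outside are discarded.
#' @param window_size,sigma Passed to [shi_tomasi_response()].
#' @param view View tag (`"left"` / `"right"`), carried in the result.
#' @return A `corner_set`: data frame with 0-based pixel columns `x`, `y`,
#'   `response`, and attributes `view` and `refined`.
#' @export
detect_corners <- function(image, quality = 0.05, min_distance = 5,
                           mask = NULL, window_size = 5L, sigma = 1.0,
                           view = "left") {
  stopifnot(quality > 0, quality < 1, min_distance >= 1)
  resp <- shi_tomasi_response(image, window_size, sigma)
  inmask <- if (is.null(mask)) resp else ifelse(mask, resp, -Inf)
  mx <- max(inmask)
  if (!is.finite(mx) || mx <= 0)
    return(corner_set(numeric(0), numeric(0), numeric(0), view))
  thr <- quality * mx
  # local maxima over a 3x3 neighbourhood of the *full* response surface
  # (masked regions still suppress adjacent candidates, so an excluded
  # maximum cannot promote its unmasked neighbours to spurious corners)
  H <- nrow(resp); W <- ncol(resp)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(H) + dr, 1), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[ri, ci]
  }
  ismax <- inmask >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & resp >= shift(resp, dr, dc)
  }
  cand <- which(ismax)
  if (!length(cand)) return(corner_set(numeric(0), numeric(0), numeric(0), view))
  ry <- (cand - 1L) %% H; rx <- (cand - 1L) %/% H
  rv <- resp[cand]
  ord <- order(rv, decreasing = TRUE)
  rx <- rx[ord]; ry <- ry[ord]; rv <- rv[ord]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_r <- numeric(0)
  md2 <- min_distance^2
  for (i in seq_along(rx)) {
    if (!length(keep_x) ||
        all((keep_x - rx[i])^2 + (keep_y - ry[i])^2 >= md2)) {
      keep_x <- c(keep_x, rx[i]); keep_y <- c(keep_y, ry[i])
      keep_r <- c(keep_r, rv[i])
    }
  }
  corner_set(keep_x, keep_y, keep_r, view)
}

#' Corner set container
#' @param x,y 0-based pixel coordinates.
#' @param response Detector responses.
#' @param view View tag.
#' @param refined Logical refinement flags (recycled).
#' @return Classed data frame `corner_set`.
#' @export
corner_set <- function(x, y, response = rep(NA_real_, length(x)),
                       view = "left", refined = FALSE) {
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       response = response,
                       refined = rep(as.logical(refined), length.out = length(x))),
            view = view, class = c("corner_set", "data.frame"))
}

#' @export
print.corner_set <- function(x, ...) {
  cat(sprintf("<corner_set: %d corners, view %s, %s>\n", nrow(x),
              attr(x, "view"),
              if (all(x$refined)) "sub-pixel" else "integer-pixel"))
  if (nrow(x)) print.data.frame(utils::head(x, 8))
  invisible(x)
}

#' Sub-pixel corner refinement
#'
#' Iteratively relocates each corner to the point `q` minimising
#' `sum_p w_p (grad I(p) . (p - q))^2` over a window — at the optimum every
#' window gradient is orthogonal to its displacement from `q`, which is the
#' saddle point of an ideal checkerboard corner.  Corners whose normal
#' matrix is singular, or that sit too close to the border, are kept at
#' their original position and flagged unrefined.
#'
#' @param image Grayscale matrix or RGB array.
#' @param corners A `corner_set`.
#' @param window Half-width of the refinement window in pixels (default 5,
#'   i.e. an 11 x 11 window).
#' @param max_iter,eps Iteration cap and convergence shift in pixels.
#' @param sigma Gaussian pre-smoothing for the gradient field.
#' @return The refined `corner_set` (same order), `refined` flags updated.
#' @export
refine_subpixel <- function(image, corners, window = 5L, max_iter = 40L,
                            eps = 1e-3, sigma = 1.0) {
  g <- gaussian_blur(to_gray(image), sigma)
  gr <- image_gradients(g)
  H <- nrow(g); W <- ncol(g)
  off <- seq(-window, window)
  wgt <- exp(-(off^2) / (2 * (window / 2)^2))
  wmat <- outer(wgt, wgt)
  out <- corners
  for (i in seq_len(nrow(corners))) {
    q <- c(corners$x[i], corners$y[i])
    q0 <- q
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      cx <- round(q[1]); cy <- round(q[2])
      xs <- cx + off; ys <- cy + off
      if (min(xs) < 0 || max(xs) > W - 1 || min(ys) < 0 || max(ys) > H - 1) {
        ok <- FALSE; break
      }
      # matrices are indexed (row=y+1, col=x+1)
      gx <- gr$gx[ys + 1, xs + 1]; gy <- gr$gy[ys + 1, xs + 1]
      gx <- t(gx); gy <- t(gy)      # now [x, y] indexing
      px <- matrix(xs, length(off), length(off))
      py <- matrix(ys, length(off), length(off), byrow = TRUE)
      wq <- t(wmat)
      a <- sum(wq * gx * gx); b <- sum(wq * gx * gy); c2 <- sum(wq * gy * gy)
      det <- a * c2 - b * b
      if (!is.finite(det) || abs(det) < 1e-12) { ok <- FALSE; break }
      bx <- sum(wq * (gx * gx * px + gx * gy * py))
      by <- sum(wq * (gx * gy * px + gy * gy * py))
      qn <- c((c2 * bx - b * by) / det, (a * by - b * bx) / det)
      # never move further than half the window from the initial position
      if (max(abs(qn - q0)) > window / 2) { qn <- q; ok <- it > 1; break }
      shift <- sqrt(sum((qn - q)^2))
      q <- qn
      if (shift < eps) break
    }
    if (ok) {
      out$x[i] <- q[1]; out$y[i] <- q[2]; out$refined[i] <- TRUE
    } else {
      out$refined[i] <- FALSE
    }
  }
  out
}

#' Write / read a corner set as CSV
#' @param corners A `corner_set`.
#' @param path File path.
#' @return `write_corners` returns `path` invisibly; `read_corners` a
#'   `corner_set`.
#' @export
write_corners <- function(corners, path) {
  df <- cbind(view = attr(corners, "view"), as.data.frame(corners))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corners
#' @export
read_corners <- function(path) {
  df <- utils::read.csv(path)
  corner_set(df$x, df$y, df$response, view = df$view[1], refined = df$refined)
}
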