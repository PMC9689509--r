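# Low-level tensor operations for the segmentation networks.
#
# A feature map is a numeric array of shape (channels, height, width).
# Convolution is evaluated by patch extraction (im2col) and BLAS matrix
# multiplication; every op has an exact analytic backward so small networks
# can be trained without an external framework.  Weight layout for a
# convolution is (in_channels/groups, kh, kw, out_channels), which matches
# the row ordering produced by im2col.

im2col_indices <- function(C, H, W, k, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  ci <- rep(seq_len(C), times = k * k)
  di <- rep(rep(seq_len(k), each = C), times = k)
  dj <- rep(seq_len(k), each = C * k)
  rbase <- ci + C * (di - 1) + C * Hp * (dj - 1)
  oi <- rep(seq_len(Hout), times = Wout)
  oj <- rep(seq_len(Wout), each = Hout)
  lbase <- C * stride * (oi - 1) + C * Hp * stride * (oj - 1)
  list(idx = outer(rbase, lbase, "+"), Hout = Hout, Wout = Wout,
       Hp = Hp, Wp = Wp)
}

pad_chw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad))
  xp[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <- x
  xp
}

#' 2-D convolution forward pass
#'
#' @param x Input array `(C, H, W)`.
#' @param w Weight array `(C/groups, k, k, Cout)`.
#' @param b Optional bias vector (length `Cout`).
#' @param stride,pad Integer stride and symmetric zero padding.
#' @param groups Number of channel groups; must divide both channel counts.
#' @return List with `out` `(Cout, Hout, Wout)` and a `cache` for
#'   [conv2d_backward()].
#' @keywords internal
#' @export
conv2d_forward <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x); C <- d[1]
  dw <- dim(w); cing <- dw[1]; k <- dw[2]; cout <- dw[4]
  if (C %% groups != 0 || cout %% groups != 0 || cing != C %/% groups)
    stop("invalid groups for channel counts")
  ii <- im2col_indices(cing, d[2], d[3], k, stride, pad)
  coutg <- cout %/% groups
  out <- array(0, c(cout, ii$Hout, ii$Wout))
  cols <- vector("list", groups)
  for (g in seq_len(groups)) {
    xg <- x[(g - 1) * cing + seq_len(cing), , , drop = FALSE]
    xp <- pad_chw(array(xg, c(cing, d[2], d[3])), pad)
    col <- matrix(xp[ii$idx], nrow = nrow(ii$idx))
    Wm <- matrix(w[, , , (g - 1) * coutg + seq_len(coutg)], ncol = coutg)
    y <- crossprod(Wm, col)                       # (coutg, L)
    if (!is.null(b)) y <- y + b[(g - 1) * coutg + seq_len(coutg)]
    out[(g - 1) * coutg + seq_len(coutg), , ] <- array(y, c(coutg, ii$Hout, ii$Wout))
    cols[[g]] <- col
  }
  list(out = out,
       cache = list(cols = cols, ii = ii, dimx = d, w = w, stride = stride,
                    pad = pad, groups = groups, bias = !is.null(b)))
}

#' 2-D convolution backward pass
#' @param dout Gradient w.r.t. the output `(Cout, Hout, Wout)`.
#' @param cache Cache from [conv2d_forward()].
#' @return List `dx`, `dw`, `db`.
#' @keywords internal
#' @export
conv2d_backward <- function(dout, cache) {
  w <- cache$w; ii <- cache$ii; d <- cache$dimx
  cing <- dim(w)[1]; k <- dim(w)[2]; cout <- dim(w)[4]
  groups <- cache$groups; coutg <- cout %/% groups
  dx <- array(0, d)
  dw <- array(0, dim(w))
  db <- if (cache$bias) numeric(cout) else NULL
  L <- ii$Hout * ii$Wout
  for (g in seq_len(groups)) {
    dy <- matrix(dout[(g - 1) * coutg + seq_len(coutg), , ], nrow = coutg, ncol = L)
    col <- cache$cols[[g]]
    dWm <- tcrossprod(col, dy)                    # (rows, coutg)
    dw[, , , (g - 1) * coutg + seq_len(coutg)] <- array(dWm, c(cing, k, k, coutg))
    if (cache$bias) db[(g - 1) * coutg + seq_len(coutg)] <- rowSums(dy)
    Wm <- matrix(w[, , , (g - 1) * coutg + seq_len(coutg)], ncol = coutg)
    dcol <- Wm %*% dy                             # (rows, L)
    dxp <- numeric(cing * ii$Hp * ii$Wp)
    agg <- rowsum(as.vector(dcol), group = as.vector(ii$idx))
    dxp[as.integer(rownames(agg))] <- agg
    dxp <- array(dxp, c(cing, ii$Hp, ii$Wp))
    p <- cache$pad
    dx[(g - 1) * cing + seq_len(cing), , ] <-
      dxp[, (p + 1):(p + d[2]), (p + 1):(p + d[3])]
  }
  list(dx = dx, dw = dw, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# adaptive average pooling to a (k, k) grid, torch-style bin edges
adaptive_bins <- function(n, k) {
  lo <- floor((seq_len(k) - 1) * n / k) + 1
  hi <- ceiling(seq_len(k) * n / k)
  cbind(lo, hi)
}

adaptive_avgpool_forward <- function(x, k) {
  d <- dim(x)
  bh <- adaptive_bins(d[2], k); bw <- adaptive_bins(d[3], k)
  out <- array(0, c(d[1], k, k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[, i, j] <- apply(x[, bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], drop = FALSE],
                         1, mean)
  }
  list(out = out, cache = list(dimx = d, bh = bh, bw = bw, k = k))
}

adaptive_avgpool_backward <- function(dout, cache) {
  d <- cache$dimx; bh <- cache$bh; bw <- cache$bw; k <- cache$k
  dx <- array(0, d)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hh <- bh[i, 1]:bh[i, 2]; ww <- bw[j, 1]:bw[j, 2]
    nel <- length(hh) * length(ww)
    dx[, hh, ww] <- dx[, hh, ww] +
      array(rep(dout[, i, j] / nel, times = nel), c(d[1], length(hh), length(ww)))
  }
  dx
}

# separable bilinear interpolation matrix from n source to N target samples
# (half-pixel centre convention)
bilinear_matrix <- function(N, n) {
  U <- matrix(0, N, n)
  for (X in seq_len(N)) {
    s <- (X - 0.5) * n / N - 0.5          # 0-based source coordinate
    i0 <- floor(s); f <- s - i0
    i0 <- min(max(i0, 0), n - 1); i1 <- min(i0 + 1, n - 1)
    U[X, i0 + 1] <- U[X, i0 + 1] + (1 - f)
    U[X, i1 + 1] <- U[X, i1 + 1] + f
  }
  U
}

bilinear_upsample_forward <- function(x, H, W) {
  d <- dim(x)
  Uh <- bilinear_matrix(H, d[2]); Uw <- bilinear_matrix(W, d[3])
  out <- array(0, c(d[1], H, W))
  for (c in seq_len(d[1])) out[c, , ] <- Uh %*% x[c, , ] %*% t(Uw)
  list(out = out, cache = list(Uh = Uh, Uw = Uw, dimx = d))
}

bilinear_upsample_backward <- function(dout, cache) {
  d <- cache$dimx
  dx <- array(0, d)
  for (c in seq_len(d[1]))
    dx[c, , ] <- t(cache$Uh) %*% dout[c, , ] %*% cache$Uw
  dx
}

# channel-wise global pooling (used by channel attention)
global_avgpool <- function(x) apply(x, 1, mean)
global_maxpool <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1])
  idx <- max.col(m, ties.method = "first")
  list(val = m[cbind(seq_len(d[1]), idx)], idx = idx)
}

softmax_cross_entropy <- function(logits, labels) {
  # logits (K, H, W); labels (H, W) integer in 0..K-1
  d <- dim(logits)
  m <- matrix(logits, d[1])                   # (K, HW)
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  lab <- as.vector(labels) + 1L
  n <- ncol(m)
  loss <- -mean(log(pmax(p[cbind(lab, seq_len(n))], 1e-12)))
  dl <- p
  dl[cbind(lab, seq_len(n))] <- dl[cbind(lab, seq_len(n))] - 1
  list(loss = loss, dlogits = array(dl / n, d), prob = array(p, d))
}
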