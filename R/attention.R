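# Convolutional block attention (CBAM): sequential channel gating then
# spatial gating of a feature map.  The channel module squeezes the map with
# global average and max pooling, passes both vectors through one shared
# two-layer perceptron (hidden size C/r, ReLU, no biases), adds the results
# element-wise and applies a sigmoid; the spatial module concatenates the
# channel-wise mean and max maps and convolves them with a single 7x7 kernel.

he_init <- function(dims, fan_in, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Channel attention gating
#'
#' Computes the channel attention map
#' `a = sigmoid(MLP(avgpool(f)) + MLP(maxpool(f)))` with a shared bias-free
#' two-layer perceptron of hidden width `C/r`, and returns the gated map
#' `f * a` (each channel scaled by its attention weight).
#'
#' @param f Feature map array `(C, H, W)`.
#' @param r Reduction ratio; must divide the channel count.
#' @param W1 Optional hidden weights `(C/r, C)`; seeded He init when omitted.
#' @param W2 Optional output weights `(C, C/r)`.
#' @param seed Seed for the default weight init.
#' @return List with `attention` (length-`C` vector in (0,1)) and `output`
#'   (array, same shape as `f`).
#' @export
channel_attention <- function(f, r = 16, W1 = NULL, W2 = NULL, seed = 0) {
  d <- dim(f)
  if (length(d) != 3) stop("feature map must be (C, H, W)")
  C <- d[1]
  if (C %% r != 0) stop("invalid reduction: r must divide the channel count")
  hid <- C %/% r
  if (is.null(W1)) W1 <- he_init(c(hid, C), C, seed)
  if (is.null(W2)) W2 <- he_init(c(C, hid), hid, seed + 1)
  stopifnot(all(dim(W1) == c(hid, C)), all(dim(W2) == c(C, hid)))
  avg <- global_avgpool(f)
  mx <- global_maxpool(f)$val
  z <- drop(W2 %*% pmax(W1 %*% avg, 0)) + drop(W2 %*% pmax(W1 %*% mx, 0))
  a <- sigmoid(z)
  list(attention = a, output = f * a)   # recycling: first dim is channels
}

#' Spatial attention gating
#'
#' Concatenates the channel-wise mean and max maps of `f_c` into a 2-channel
#' map, convolves with one `k x k` kernel (padding preserving the spatial
#' size), applies a sigmoid, and broadcasts the resulting spatial mask over
#' all channels.
#'
#' @param f_c Channel-refined feature map `(C, H, W)`.
#' @param kernel Optional kernel array `(2, k, k)`; seeded He init if omitted.
#' @param ksize Kernel size (default 7).
#' @param seed Seed for the default kernel init.
#' @return List with `attention` (`(H, W)` matrix in (0,1)) and `output`.
#' @export
spatial_attention <- function(f_c, kernel = NULL, ksize = 7, seed = 0) {
  d <- dim(f_c)
  if (length(d) != 3) stop("feature map must be (C, H, W)")
  if (is.null(kernel)) kernel <- he_init(c(2, ksize, ksize), 2 * ksize^2, seed)
  ksize <- dim(kernel)[2]
  pool <- array(0, c(2, d[2], d[3]))
  pool[1, , ] <- apply(f_c, c(2, 3), mean)
  pool[2, , ] <- apply(f_c, c(2, 3), max)
  w <- array(kernel, c(2, ksize, ksize, 1))
  s <- conv2d_forward(pool, w, stride = 1L, pad = (ksize - 1L) %/% 2L)$out
  a <- sigmoid(s[1, , ])
  out <- f_c
  for (c in seq_len(d[1])) out[c, , ] <- f_c[c, , ] * a
  list(attention = a, output = out)
}

# ---- CBAM with backward (used by the trainable reduced network) ----------

cbam_forward <- function(x, p) {
  d <- dim(x); C <- d[1]
  avg <- global_avgpool(x)
  mx <- global_maxpool(x)
  h_a <- pmax(p$W1 %*% avg, 0); h_m <- pmax(p$W1 %*% mx$val, 0)
  z <- drop(p$W2 %*% h_a) + drop(p$W2 %*% h_m)
  a_c <- sigmoid(z)
  xc <- x * a_c
  m <- matrix(xc, C)                             # (C, HW)
  mm <- max.col(t(m), ties.method = "first")     # argmax channel per pixel
  pool <- array(0, c(2, d[2], d[3]))
  pool[1, , ] <- colMeans(m)
  pool[2, , ] <- m[cbind(mm, seq_along(mm))]
  k <- dim(p$Wsp)[2]
  cf <- conv2d_forward(pool, p$Wsp, stride = 1L, pad = (k - 1L) %/% 2L)
  a_s <- sigmoid(cf$out[1, , ])
  out <- xc
  for (c in seq_len(C)) out[c, , ] <- xc[c, , ] * a_s
  list(out = out,
       cache = list(x = x, avg = avg, mx = mx, h_a = h_a, h_m = h_m,
                    a_c = a_c, xc = xc, pool = pool, mm = mm, cf = cf,
                    a_s = a_s, p = p, d = d))
}

cbam_backward <- function(dout, cache) {
  d <- cache$d; C <- d[1]; HW <- d[2] * d[3]
  p <- cache$p
  # spatial gate
  dxc <- dout
  da_s <- matrix(0, d[2], d[3])
  for (c in seq_len(C)) {
    dxc[c, , ] <- dout[c, , ] * cache$a_s
    da_s <- da_s + dout[c, , ] * cache$xc[c, , ]
  }
  ds <- da_s * cache$a_s * (1 - cache$a_s)
  cb <- conv2d_backward(array(ds, c(1, d[2], d[3])), cache$cf$cache)
  dWsp <- cb$dw
  dpool <- cb$dx
  # mean branch over channels
  for (c in seq_len(C)) dxc[c, , ] <- dxc[c, , ] + dpool[1, , ] / C
  # max branch to argmax channel
  lin <- cbind(cache$mm,
               rep(seq_len(d[2]), times = d[3]),
               rep(seq_len(d[3]), each = d[2]))
  dxc[lin] <- dxc[lin] + as.vector(dpool[2, , ])
  # channel gate
  dx <- dxc * cache$a_c
  da_c <- apply(dxc * cache$x, 1, sum)
  dz <- da_c * cache$a_c * (1 - cache$a_c)
  dh_a <- drop(crossprod(p$W2, dz)); dh_m <- dh_a
  dW2 <- tcrossprod(dz, cache$h_a) + tcrossprod(dz, cache$h_m)
  dh_a <- dh_a * (cache$h_a > 0); dh_m <- dh_m * (cache$h_m > 0)
  dW1 <- tcrossprod(dh_a, cache$avg) + tcrossprod(dh_m, cache$mx$val)
  davg <- drop(crossprod(p$W1, dh_a))
  dmax <- drop(crossprod(p$W1, dh_m))
  dx <- dx + array(rep(davg / HW, times = HW), d)
  mxidx <- cache$mx$idx                      # flat (h,w) index per channel
  flat <- matrix(dx, C)
  flat[cbind(seq_len(C), mxidx)] <- flat[cbind(seq_len(C), mxidx)] + dmax
  dx <- array(flat, d)
  list(dx = dx, dW1 = dW1, dW2 = dW2, dWsp = dWsp)
}
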