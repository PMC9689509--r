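# Reduced-depth trainable variant of the attention + pyramid-pooling
# segmentation network.
#
# Same ingredients as the full architecture -- a grouped 3x3 convolution,
# a CBAM (channel then spatial attention), a pyramid-pooling context branch
# with bilinear upsampling, and a per-pixel classifier -- at a width and
# depth where exact backpropagation in plain R is practical.  Its purpose
# is to demonstrate that the architecture as wired is differentiable and
# learnable, not to reproduce full-scale segmentation accuracy.

#' Build the reduced-depth trainable segmentation network
#'
#' @param in_channels Input channels (3 for RGB).
#' @param width Base channel width (default 8).
#' @param groups Groups of the second 3x3 convolution (default 2).
#' @param r CBAM reduction ratio (default 2; must divide `width`).
#' @param num_classes Output classes (default 2).
#' @param pools Pyramid pooling grid sizes (default 1 and 2).
#' @param seed Weight-init seed.
#' @return An object of class `tiny_segnet` holding the weight list.
#' @export
build_tiny_segnet <- function(in_channels = 3L, width = 8L, groups = 2L,
                              r = 2L, num_classes = 2L, pools = c(1L, 2L),
                              seed = 0L) {
  if (width %% groups != 0) stop("invalid groups")
  if (width %% r != 0) stop("invalid reduction")
  set.seed(seed)
  rnd <- function(dims, fan_in) array(stats::rnorm(prod(dims),
                                                   sd = sqrt(2 / fan_in)), dims)
  C <- width; Cb <- C %/% 2L
  p <- list(
    w1 = rnd(c(in_channels, 3, 3, C), in_channels * 9), b1 = numeric(C),
    w2 = rnd(c(C %/% groups, 3, 3, C), C %/% groups * 9), b2 = numeric(C),
    W1 = rnd(c(C %/% r, C), C), W2 = rnd(c(C, C %/% r), C %/% r),
    Wsp = rnd(c(2, 7, 7, 1), 98),
    b4 = numeric(num_classes))
  for (i in seq_along(pools)) {
    p[[paste0("wp", i)]] <- rnd(c(C, 1, 1, Cb), C)
    p[[paste0("bp", i)]] <- numeric(Cb)
  }
  p$w3 <- rnd(c(C + length(pools) * Cb, 3, 3, C), (C + length(pools) * Cb) * 9)
  p$b3 <- numeric(C)
  p$w4 <- rnd(c(C, 1, 1, num_classes), C)
  structure(list(params = p, width = C, groups = groups, r = r,
                 num_classes = num_classes, pools = pools),
            class = "tiny_segnet")
}

tiny_forward <- function(net, x) {
  p <- net$params
  c1 <- conv2d_forward(x, p$w1, p$b1, pad = 1L)
  r1 <- relu_forward(c1$out)
  c2 <- conv2d_forward(r1$out, p$w2, p$b2, pad = 1L, groups = net$groups)
  r2 <- relu_forward(c2$out)
  cb <- cbam_forward(r2$out, list(W1 = p$W1, W2 = p$W2, Wsp = p$Wsp))
  d <- dim(cb$out)
  branches <- list(cb$out)
  pcache <- list()
  for (i in seq_along(net$pools)) {
    ap <- adaptive_avgpool_forward(cb$out, net$pools[i])
    pc <- conv2d_forward(ap$out, p[[paste0("wp", i)]], p[[paste0("bp", i)]])
    pr <- relu_forward(pc$out)
    up <- bilinear_upsample_forward(pr$out, d[2], d[3])
    branches[[i + 1]] <- up$out
    pcache[[i]] <- list(ap = ap, pc = pc, pr = pr, up = up)
  }
  cat_out <- array(0, c(sum(vapply(branches, function(b) dim(b)[1], 0)),
                        d[2], d[3]))
  ch0 <- 0L
  for (b in branches) {
    cat_out[ch0 + seq_len(dim(b)[1]), , ] <- b
    ch0 <- ch0 + dim(b)[1]
  }
  c3 <- conv2d_forward(cat_out, p$w3, p$b3, pad = 1L)
  r3 <- relu_forward(c3$out)
  c4 <- conv2d_forward(r3$out, p$w4, p$b4)
  list(logits = c4$out,
       cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, cb = cb,
                    pcache = pcache, c3 = c3, r3 = r3, c4 = c4,
                    nbr = length(branches), d = d))
}

tiny_backward <- function(net, dlogits, cache) {
  p <- net$params
  g <- list()
  b4 <- conv2d_backward(dlogits, cache$c4$cache)
  g$w4 <- b4$dw; g$b4 <- b4$db
  dr3 <- relu_backward(b4$dx, cache$r3$cache)
  b3 <- conv2d_backward(dr3, cache$c3$cache)
  g$w3 <- b3$dw; g$b3 <- b3$db
  d <- cache$d; C <- d[1]
  dcb_out <- b3$dx[seq_len(C), , , drop = FALSE]
  dcb_out <- array(dcb_out, d)
  ch0 <- C
  for (i in seq_along(net$pools)) {
    pc <- cache$pcache[[i]]
    nb <- dim(pc$up$out)[1]
    dup <- array(b3$dx[ch0 + seq_len(nb), , , drop = FALSE],
                 c(nb, d[2], d[3]))
    dpr <- bilinear_upsample_backward(dup, pc$up$cache)
    dpc <- relu_backward(dpr, pc$pr$cache)
    bb <- conv2d_backward(dpc, pc$pc$cache)
    g[[paste0("wp", i)]] <- bb$dw; g[[paste0("bp", i)]] <- bb$db
    dcb_out <- dcb_out + adaptive_avgpool_backward(bb$dx, pc$ap$cache)
    ch0 <- ch0 + nb
  }
  cbb <- cbam_backward(dcb_out, cache$cb$cache)
  g$W1 <- cbb$dW1; g$W2 <- cbb$dW2; g$Wsp <- cbb$dWsp
  dr2 <- relu_backward(cbb$dx, cache$r2$cache)
  b2 <- conv2d_backward(dr2, cache$c2$cache)
  g$w2 <- b2$dw; g$b2 <- b2$db
  dr1 <- relu_backward(b2$dx, cache$r1$cache)
  b1 <- conv2d_backward(dr1, cache$c1$cache)
  g$w1 <- b1$dw; g$b1 <- b1$db
  g
}

# image (H, W, 3) in [0,1] -> feature tensor (3, H, W), centred
image_to_tensor <- function(img) {
  d <- dim(img)
  aperm(img, c(3, 1, 2)) - 0.5
}

#' Predict a label mask with the reduced network
#' @param net A trained `tiny_segnet`.
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @return Integer matrix of class labels (0-based).
#' @export
predict_tiny_segnet <- function(net, image) {
  fw <- tiny_forward(net, image_to_tensor(image))
  d <- dim(fw$logits)
  lab <- max.col(t(matrix(fw$logits, d[1])), ties.method = "first") - 1L
  matrix(lab, d[2], d[3])
}

#' Train the reduced segmentation network
#'
#' Per-pixel softmax cross-entropy minimised with Adam over the fixture
#' set.  Deterministic for a fixed seed.
#'
#' @param net A `tiny_segnet`.
#' @param fixtures List of `list(image, mask)` as produced by
#'   [generate_segmentation_fixtures()].
#' @param steps Optimisation steps (each step sweeps a minibatch).
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Sampling seed.
#' @param verbose Print the running loss every 20 steps.
#' @return The trained `tiny_segnet` (loss trace in attribute `loss`).
#' @export
train_tiny_segnet <- function(net, fixtures, steps = 120L, batch = 4L,
                              lr = 5e-3, seed = 0L, verbose = FALSE) {
  set.seed(seed)
  p <- net$params
  m <- lapply(p, function(w) w * 0); v <- m
  beta1 <- 0.9; beta2 <- 0.999; epsb <- 1e-8
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    idx <- sample(length(fixtures), min(batch, length(fixtures)))
    g <- NULL; loss <- 0
    for (i in idx) {
      fx <- fixtures[[i]]
      fw <- tiny_forward(net, image_to_tensor(fx$image))
      sce <- softmax_cross_entropy(fw$logits, fx$mask)
      loss <- loss + sce$loss / length(idx)
      gi <- tiny_backward(net, sce$dlogits, fw$cache)
      g <- if (is.null(g)) lapply(gi, function(x) x / length(idx))
           else mapply(function(a, b) a + b / length(idx), g, gi,
                       SIMPLIFY = FALSE)
    }
    for (k in names(p)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
      mh <- m[[k]] / (1 - beta1^s); vh <- v[[k]] / (1 - beta2^s)
      p[[k]] <- p[[k]] - lr * mh / (sqrt(vh) + epsb)
    }
    net$params <- p
    trace[s] <- loss
    if (verbose && s %% 20 == 0)
      message(sprintf("step %d  loss %.4f", s, loss))
  }
  attr(net, "loss") <- trace
  net
}
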