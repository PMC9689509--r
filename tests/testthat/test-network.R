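# brute-force convolution oracle: direct summation
conv_oracle <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); k <- dim(w)[2]; cout <- dim(w)[4]; cing <- dim(w)[1]
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- x
  Hout <- (d[2] + 2 * pad - k) %/% stride + 1
  Wout <- (d[3] + 2 * pad - k) %/% stride + 1
  out <- array(if (is.null(b)) 0 else rep(b, Hout * Wout),
               c(cout, Hout, Wout))
  coutg <- cout %/% groups
  for (o in seq_len(cout)) {
    g <- (o - 1) %/% coutg
    for (i in seq_len(Hout)) for (j in seq_len(Wout)) {
      acc <- 0
      for (c in seq_len(cing)) for (di in seq_len(k)) for (dj in seq_len(k))
        acc <- acc + w[c, di, dj, o] *
          xp[g * cing + c, (i - 1) * stride + di, (j - 1) * stride + dj]
      out[o, i, j] <- out[o, i, j] + acc
    }
  }
  out
}

test_that("im2col convolution agrees with direct summation", {
  set.seed(11)
  for (case in list(list(c = 3, co = 4, k = 3, s = 1, p = 1, g = 1),
                    list(c = 4, co = 4, k = 3, s = 2, p = 1, g = 2),
                    list(c = 2, co = 2, k = 1, s = 1, p = 0, g = 1),
                    list(c = 6, co = 3, k = 5, s = 1, p = 2, g = 3))) {
    x <- array(stats::rnorm(case$c * 7 * 8), c(case$c, 7, 8))
    w <- array(stats::rnorm(case$c / case$g * case$k^2 * case$co),
               c(case$c / case$g, case$k, case$k, case$co))
    b <- stats::rnorm(case$co)
    got <- conv2d_forward(x, w, b, stride = case$s, pad = case$p,
                          groups = case$g)$out
    expect_equal(got, conv_oracle(x, w, b, case$s, case$p, case$g),
                 tolerance = 1e-12)
  }
})

test_that("grouped-convolution parameter identity holds", {
  expect_identical(conv_params(3, 3, 64, 64, 1), 36864)
  expect_identical(conv_params(3, 3, 64, 64, 4), 9216)
  set.seed(5)
  for (i in 1:20) {
    g <- sample(c(1, 2, 4, 8), 1)
    din <- g * sample(1:8, 1); dout <- g * sample(1:8, 1)
    h <- sample(1:7, 1); w <- sample(1:7, 1)
    expect_equal(conv_params(h, w, din, dout, g),
                 conv_params(h, w, din, dout, 1) / g)
  }
  expect_error(conv_params(3, 3, 5, 4, 2), "invalid groups")
})

test_that("backbone accounting reproduces the published architecture", {
  std <- build_backbone(backbone_config())
  expect_equal(round(count_parameters(std) / 1e6, 2), 42.50)
  imp <- build_backbone(backbone_config(groups = 2, cbam_enabled = TRUE))
  expect_equal(round(count_parameters(imp) / 1e6, 2), 32.52)
  # every grouped 3x3 conv obeys the 1/g parameter identity, checked by
  # walking the module tree
  collect_convs <- function(m) {
    if (m$type == "conv") return(list(m))
    kids <- switch(m$type,
                   seq = m$children,
                   residual = c(list(m$body), if (!is.null(m$downsample))
                     list(m$downsample)),
                   list())
    unlist(lapply(kids, collect_convs), recursive = FALSE)
  }
  convs <- collect_convs(imp$module)
  grouped <- Filter(function(cv) cv$groups > 1, convs)
  expect_gt(length(grouped), 30)   # one per bottleneck
  for (cv in grouped)
    expect_equal(conv_params(cv$k, cv$k, cv$cin, cv$cout, cv$groups),
                 conv_params(cv$k, cv$k, cv$cin, cv$cout, 1) / cv$groups)
  expect_error(build_backbone(backbone_config(groups = 3)), "invalid groups")
})

test_that("shape propagation matches ResNet101 downsampling", {
  std <- build_backbone(backbone_config(cbam_enabled = TRUE, groups = 2))
  sh <- infer_shapes(std, c(3L, 224L, 224L))
  expect_equal(sh$stages[[5]], c(2048, 7, 7))
  # CBAM insertion preserves shapes: same stage shapes without attention
  sh0 <- infer_shapes(build_backbone(backbone_config()), c(3L, 224L, 224L))
  expect_equal(sh$stages, sh0$stages)
  psp <- build_pspnet(build_backbone(backbone_config()), num_classes = 2)
  out <- infer_shapes(psp, c(3L, 224L, 224L))$output
  expect_equal(out, c(2, 224, 224))
  expect_equal(length(psp$config$pools), 4L)
})

test_that("channel attention implements the shared-MLP gating", {
  set.seed(3)
  f <- array(stats::rnorm(8 * 4 * 4), c(8, 4, 4))
  ca <- channel_attention(f, r = 2)
  expect_equal(dim(ca$output), dim(f))
  expect_true(all(ca$attention > 0 & ca$attention < 1))
  # multiplicative gating: zero input stays zero
  z <- channel_attention(array(0, c(8, 4, 4)), r = 2)
  expect_true(all(z$output == 0))
  # 2-channel 1x1 case with identity perceptron: a = sigmoid(2 relu(v))
  f2 <- array(c(0.3, -0.2), c(2, 1, 1))
  ca2 <- channel_attention(f2, r = 1, W1 = diag(2), W2 = diag(2))
  expect_equal(ca2$attention,
               1 / (1 + exp(-2 * pmax(c(0.3, -0.2), 0))))
  expect_equal(as.vector(ca2$output), c(0.3, -0.2) * ca2$attention)
  expect_error(channel_attention(array(0, c(6, 2, 2)), r = 4),
               "invalid reduction")
})

test_that("spatial attention concatenates mean/max maps through one kernel", {
  f <- array(1.7, c(3, 5, 5))
  sa <- spatial_attention(f, kernel = array(0, c(2, 7, 7)))
  expect_true(all(abs(sa$attention - 0.5) < 1e-12))
  expect_equal(dim(sa$output), dim(f))
  # 1-channel 3x3 kernel against direct convolution of [mean; max]
  set.seed(9)
  f1 <- array(stats::rnorm(9), c(1, 3, 3))
  k <- array(stats::rnorm(18), c(2, 3, 3))
  sa1 <- spatial_attention(f1, kernel = k)
  pool <- array(0, c(2, 3, 3))
  pool[1, , ] <- f1[1, , ]; pool[2, , ] <- f1[1, , ]
  oracle <- conv_oracle(pool, array(k, c(2, 3, 3, 1)), pad = 1)
  expect_equal(sa1$attention, 1 / (1 + exp(-oracle[1, , ])), tolerance = 1e-12)
  expect_true(all(sa1$attention > 0 & sa1$attention < 1))
})

test_that("reduced network backpropagation matches finite differences", {
  set.seed(21)
  net <- build_tiny_segnet(width = 4L, r = 2L, pools = c(1L, 2L), seed = 13)
  x <- array(stats::runif(3 * 8 * 8), c(3, 8, 8)) - 0.5
  lab <- matrix(sample(0:1, 64, TRUE), 8, 8)
  fw <- stereogirth:::tiny_forward(net, x)
  sce <- stereogirth:::softmax_cross_entropy(fw$logits, lab)
  g <- stereogirth:::tiny_backward(net, sce$dlogits, fw$cache)
  lossfn <- function(n) {
    f <- stereogirth:::tiny_forward(n, x)
    stereogirth:::softmax_cross_entropy(f$logits, lab)$loss
  }
  eps <- 1e-5
  for (k in c("w1", "w2", "W2", "Wsp", "wp2", "w3", "w4", "b3")) {
    w <- net$params[[k]]
    i <- sample(length(w), 1)
    np <- net; np$params[[k]][i] <- w[i] + eps
    nm <- net; nm$params[[k]][i] <- w[i] - eps
    num <- (lossfn(np) - lossfn(nm)) / (2 * eps)
    expect_equal(g[[k]][i], num, tolerance = 1e-4,
                 label = paste("grad", k))
  }
})

test_that("segmentation metrics match the confusion-matrix definitions", {
  t4 <- matrix(c(0, 0, 1, 1), 2, 2)
  p4 <- matrix(c(0, 1, 1, 1), 2, 2)
  m <- segmentation_metrics(p4, t4, 2)
  expect_equal(m$pa, 75)
  expect_equal(m$mpa, 75)                       # (50 + 100) / 2
  expect_equal(m$miou, 100 * mean(c(1 / 2, 2 / 3)), tolerance = 1e-9)
  ident <- segmentation_metrics(t4, t4, 2)
  expect_equal(unlist(ident), c(pa = 100, mpa = 100, miou = 100))
  sw <- segmentation_metrics(1 - t4, t4, 2)
  expect_equal(sw$pa, 0)
  expect_error(segmentation_metrics(matrix(0, 2, 3), t4, 2), "incompatible")
})
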