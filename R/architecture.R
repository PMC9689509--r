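# Architecture descriptors for the attention-augmented pyramid-pooling
# segmentation network and its grouped-convolution ResNet101 backbone.
#
# Networks are represented symbolically as nested module descriptors; shapes
# are propagated exactly and trainable parameters / multiply-accumulate
# operations are accounted in closed form per layer.  This keeps the
# accounting instant and independent of any materialized weights.

mod_conv <- function(k, cin, cout, stride = 1L, pad = k %/% 2, groups = 1L,
                     bias = FALSE) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("invalid groups: g must divide both channel counts")
  list(type = "conv", k = k, cin = cin, cout = cout, stride = stride,
       pad = pad, groups = groups, bias = bias)
}
mod_bn <- function(c) list(type = "bn", c = c)
mod_relu <- function() list(type = "relu")
mod_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
mod_linear <- function(cin, cout, bias = FALSE)
  list(type = "linear", cin = cin, cout = cout, bias = bias)
mod_seq <- function(...) list(type = "seq", children = list(...))
mod_residual <- function(body, downsample = NULL)
  list(type = "residual", body = body, downsample = downsample)
mod_cbam <- function(channels, r = 16L, ksize = 7L) {
  if (channels %% r != 0) stop("invalid reduction: r must divide channels")
  list(type = "cbam", c = channels, r = r, ksize = ksize)
}
mod_ppm <- function(cin, pool_sizes = c(1L, 2L, 3L, 6L),
                    branch_channels = cin %/% 4L)
  list(type = "ppm", cin = cin, pools = pool_sizes, cb = branch_channels)
mod_upsample_to_input <- function() list(type = "upsample_input")

conv_out_hw <- function(hw, k, stride, pad)
  c((hw[1] + 2 * pad - k) %/% stride + 1L, (hw[2] + 2 * pad - k) %/% stride + 1L)

# walk a module: returns list(params, flops, shape) given input shape (C,H,W)
walk_module <- function(m, shape, input_hw = NULL) {
  switch(m$type,
    conv = {
      hw <- conv_out_hw(shape[2:3], m$k, m$stride, m$pad)
      p <- m$k^2 * (m$cin / m$groups) * m$cout + if (m$bias) m$cout else 0
      pm <- m$k^2 * (m$cin / m$groups) * m$cout      # MACs per output position
      list(params = p, flops = pm * hw[1] * hw[2], shape = c(m$cout, hw))
    },
    bn = list(params = 2 * m$c, flops = 0, shape = shape),
    relu = list(params = 0, flops = 0, shape = shape),
    maxpool = {
      hw <- conv_out_hw(shape[2:3], m$k, m$stride, m$pad)
      list(params = 0, flops = 0, shape = c(shape[1], hw))
    },
    linear = list(params = m$cin * m$cout + if (m$bias) m$cout else 0,
                  flops = m$cin * m$cout, shape = shape),
    seq = {
      p <- 0; f <- 0
      for (ch in m$children) {
        r <- walk_module(ch, shape, input_hw)
        p <- p + r$params; f <- f + r$flops; shape <- r$shape
      }
      list(params = p, flops = f, shape = shape)
    },
    residual = {
      b <- walk_module(m$body, shape, input_hw)
      p <- b$params; f <- b$flops
      if (!is.null(m$downsample)) {
        dsr <- walk_module(m$downsample, shape, input_hw)
        p <- p + dsr$params; f <- f + dsr$flops
      }
      list(params = p, flops = f, shape = b$shape)
    },
    cbam = {
      C <- m$c; hid <- C %/% m$r
      # shared bias-free two-layer perceptron, applied to both pooled vectors
      p <- 2 * C * hid + m$ksize^2 * 2
      f <- 2 * (C * hid + hid * C) + m$ksize^2 * 2 * shape[2] * shape[3]
      list(params = p, flops = f, shape = shape)
    },
    ppm = {
      p <- 0; f <- 0
      for (ps in m$pools) {
        br <- mod_seq(mod_conv(1L, m$cin, m$cb), mod_bn(m$cb), mod_relu())
        r <- walk_module(br, c(m$cin, ps, ps), input_hw)
        p <- p + r$params; f <- f + r$flops
      }
      list(params = p, flops = f,
           shape = c(m$cin + length(m$pools) * m$cb, shape[2], shape[3]))
    },
    upsample_input = list(params = 0, flops = 0,
                          shape = c(shape[1], input_hw)),
    stop("unknown module type: ", m$type))
}

# ---- backbone / head builders --------------------------------------------

#' Backbone configuration
#'
#' Configuration of the ResNet101-topology feature extractor: group count for
#' every bottleneck's 3x3 convolution, whether an attention block (channel +
#' spatial) follows each of the four stages, and the attention reduction
#' ratio.  Block counts are fixed to ResNet101's (3, 4, 23, 3) and pyramid
#' pool sizes default to (1, 2, 3, 6).
#'
#' @param groups Group count `g` for the bottleneck 3x3 convolutions.
#' @param cbam_enabled Insert a CBAM after each of layers 1-4.
#' @param cbam_reduction Attention reduction ratio `r` (default 16).
#' @param blocks Residual block counts per stage.
#' @param pool_sizes Pyramid pooling grid sizes.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(groups = 1L, cbam_enabled = FALSE,
                            cbam_reduction = 16L,
                            blocks = c(3L, 4L, 23L, 3L),
                            pool_sizes = c(1L, 2L, 3L, 6L)) {
  widths <- c(64L, 128L, 256L, 512L)
  if (any(widths %% groups != 0))
    stop("invalid groups: g must divide every bottleneck width")
  structure(list(groups = as.integer(groups), cbam = cbam_enabled,
                 r = as.integer(cbam_reduction), blocks = as.integer(blocks),
                 widths = widths, pools = as.integer(pool_sizes)),
            class = "backbone_config")
}

bottleneck_module <- function(cin, width, stride, groups) {
  body <- mod_seq(
    mod_conv(1L, cin, width, stride = 1L, pad = 0L), mod_bn(width), mod_relu(),
    mod_conv(3L, width, width, stride = stride, pad = 1L, groups = groups),
    mod_bn(width), mod_relu(),
    mod_conv(1L, width, width * 4L, stride = 1L, pad = 0L), mod_bn(width * 4L))
  ds <- if (stride != 1L || cin != width * 4L)
    mod_seq(mod_conv(1L, cin, width * 4L, stride = stride, pad = 0L),
            mod_bn(width * 4L))
  mod_residual(body, ds)
}

#' Build the feature-extraction backbone
#'
#' ResNet101-topology extractor: 7x7/64 stride-2 stem convolution, 3x3
#' stride-2 max pooling, then four stages of bottleneck blocks with counts
#' (3, 4, 23, 3).  The 3x3 convolution of every bottleneck is grouped by
#' `config$groups` (the stride-2 spatial reduction sits on that 3x3), and a
#' CBAM is appended to each stage output when enabled.  No classification
#' head is included.
#'
#' @param config A [backbone_config()].
#' @return An object of class `sg_network`.
#' @export
build_backbone <- function(config = backbone_config()) {
  stopifnot(inherits(config, "backbone_config"))
  stages <- list(mod_seq(mod_conv(7L, 3L, 64L, stride = 2L, pad = 3L),
                         mod_bn(64L), mod_relu(), mod_maxpool()))
  cin <- 64L
  for (li in 1:4) {
    w <- config$widths[li]
    stride <- if (li == 1L) 1L else 2L
    blocks <- list()
    for (b in seq_len(config$blocks[li])) {
      blocks[[b]] <- bottleneck_module(cin, w, if (b == 1L) stride else 1L,
                                       config$groups)
      cin <- w * 4L
    }
    if (config$cbam) blocks[[length(blocks) + 1L]] <- mod_cbam(cin, config$r)
    stages[[length(stages) + 1L]] <- do.call(mod_seq, blocks)
  }
  structure(list(module = do.call(mod_seq, stages), stages = stages,
                 config = config, kind = "backbone"),
            class = "sg_network")
}

#' Build the pyramid-pooling segmentation network
#'
#' Appends the pyramid scene-parsing head to a backbone: adaptive average
#' pooling of the stage-4 features at the four pyramid levels, a 1x1
#' convolution (+ batch norm + ReLU) per level, bilinear upsampling back to
#' the feature resolution, concatenation with the input features, a 3x3
#' fusion convolution and a 1x1 per-pixel classifier, bilinearly upsampled
#' to the input resolution.
#'
#' @param backbone An `sg_network` from [build_backbone()].
#' @param num_classes Number of output classes.
#' @return An `sg_network` of kind `"pspnet"`.
#' @export
build_pspnet <- function(backbone, num_classes = 2L) {
  stopifnot(inherits(backbone, "sg_network"), backbone$kind == "backbone")
  cfeat <- 2048L
  head <- mod_seq(
    mod_ppm(cfeat, backbone$config$pools, 512L),
    mod_conv(3L, cfeat + 4L * 512L, 512L, stride = 1L, pad = 1L),
    mod_bn(512L), mod_relu(),
    mod_conv(1L, 512L, as.integer(num_classes), stride = 1L, pad = 0L,
             bias = TRUE),
    mod_upsample_to_input())
  structure(list(module = do.call(mod_seq, c(backbone$stages, list(head))),
                 stages = backbone$stages, head = head,
                 config = backbone$config, num_classes = num_classes,
                 kind = "pspnet"),
            class = "sg_network")
}

#' @export
print.sg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sg_network: %s, groups = %d, attention = %s>\n", x$kind,
              cfg$groups, if (cfg$cbam) sprintf("CBAM (r = %d)", cfg$r)
              else "none"))
  cat(sprintf("  parameters: %.2f M\n", count_parameters(x) / 1e6))
  invisible(x)
}

# ---- accounting -----------------------------------------------------------

#' Grouped-convolution parameter count
#'
#' Number of weights in a (possibly grouped) convolution:
#' `h * w * (d_in / g) * (d_out / g) * g`, i.e. `1/g` of the ungrouped count.
#'
#' @param h,w Kernel size in pixels.
#' @param d_in,d_out Input and output channel counts.
#' @param g Number of groups (must divide both channel counts).
#' @return Integer parameter count.
#' @export
conv_params <- function(h, w, d_in, d_out, g = 1L) {
  if (d_in %% g != 0 || d_out %% g != 0)
    stop("invalid groups: g must divide both channel counts")
  h * w * (d_in / g) * (d_out / g) * g
}

#' Count trainable parameters of a network
#'
#' Exact total of convolution, batch-norm and perceptron weights in the
#' symbolic network description.
#'
#' @param network An `sg_network`.
#' @param input_size Input `(C, H, W)`; shapes only matter for FLOPs but are
#'   propagated for validation.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(network, input_size = c(3L, 224L, 224L)) {
  walk_module(network$module, input_size, input_size[2:3])$params
}

#' Count forward-pass FLOPs of a network
#'
#' Multiply-accumulate operations of all convolution and linear layers, with
#' 1 MAC counted as 1 FLOP and spatial sizes propagated exactly from the
#' input.  Normalization, activation, pooling and element-wise operations
#' are excluded; the convention is stated here because published totals
#' rarely state theirs.
#'
#' @param network An `sg_network`.
#' @param input_size Input `(C, H, W)`; default `(3, 224, 224)`.
#' @return Numeric FLOP count.
#' @export
count_flops <- function(network, input_size = c(3L, 224L, 224L)) {
  walk_module(network$module, input_size, input_size[2:3])$flops
}

#' Propagate feature-map shapes through a network
#'
#' @param network An `sg_network`.
#' @param input_size Input `(C, H, W)`.
#' @return List with the output shape and the per-stage output shapes.
#' @export
infer_shapes <- function(network, input_size = c(3L, 224L, 224L)) {
  shape <- input_size
  stage_shapes <- list()
  for (s in network$stages) {
    shape <- walk_module(s, shape, input_size[2:3])$shape
    stage_shapes[[length(stage_shapes) + 1L]] <- shape
  }
  out <- if (network$kind == "pspnet")
    walk_module(network$head, shape, input_size[2:3])$shape else shape
  list(output = out, stages = stage_shapes)
}

#' Architecture accounting report
#'
#' Builds the standard backbone (g = 1, no attention) and the improved one
#' (grouped 3x3 bottleneck convolutions + CBAM) and tabulates trainable
#' parameters (millions), FLOPs (billions) and percentage reductions.
#'
#' @param groups Group count of the improved backbone (default 2).
#' @param r Attention reduction ratio (default 16).
#' @param input_size Input `(C, H, W)` for FLOP accounting.
#' @return Data frame with one row per backbone, printed in a table-style
#'   layout.
#' @export
architecture_report <- function(groups = 2L, r = 16L,
                                input_size = c(3L, 224L, 224L)) {
  std <- build_backbone(backbone_config())
  imp <- build_backbone(backbone_config(groups = groups, cbam_enabled = TRUE,
                                        cbam_reduction = r))
  p <- c(count_parameters(std), count_parameters(imp))
  f <- c(count_flops(std, input_size), count_flops(imp, input_size))
  out <- data.frame(
    backbone = c("ResNet101", "Improved ResNet101"),
    params_million = round(p / 1e6, 2),
    flops_billion = round(f / 1e9, 2),
    param_reduction_pct = c(NA, round(100 * (1 - p[2] / p[1]), 1)),
    flop_reduction_pct = c(NA, round(100 * (1 - f[2] / f[1]), 1)))
  class(out) <- c("architecture_report", "data.frame")
  out
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("Backbone accounting (input 224x224, 1 MAC = 1 FLOP, conv + linear):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
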