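# Background Suppression Integration stem.
#
# Dual-input detector stem: the facility-applied raw frame and the
# facility-applied background-suppressed frame each pass a stride-2 2D
# convolution; the suppressed branch becomes an attention-like map
# (activation + SoftMax, scaled by a multiplier lambda) that modulates the
# input branch by element-wise multiplication. The modulated map and the
# input-branch map are stacked along a new depth axis, fused by a 3D
# convolution with spatial stride 2, and reduced back to 4D by max pooling
# over depth, giving features at 1/4 input resolution.

#' BSI stem configuration
#'
#' @param C Number of stem channels.
#' @param lambda_mult Non-negative SoftMax multiplier lambda; the attention
#'   map sums to `lambda_mult` along the SoftMax axis. Default 2 (the most
#'   consistent setting of the 1x/2x/3x sweep).
#' @param activation Activation identifier: `"silu"` (default), `"relu"` or
#'   `"identity"`.
#' @param softmax_axis `"channel"` (SoftMax across channels at each spatial
#'   location; default) or `"spatial"`.
#' @param fusion Fusion stage: `"3dconv"` (default), `"addition"` or
#'   `"concat2d"`.
#' @param kernel_3d Odd (depth, height, width) kernel of the 3D convolution.
#' @param kernel_2d Odd spatial kernel of the two stride-2 2D convolutions.
#' @param seed Seed for weight initialization.
#' @return A validated list of class `bsi_config`.
#' @export
bsi_config <- function(C = 16L, lambda_mult = 2, activation = "silu",
                       softmax_axis = c("channel", "spatial"),
                       fusion = c("3dconv", "addition", "concat2d"),
                       kernel_3d = c(3L, 3L, 3L), kernel_2d = 3L, seed = 1L) {
  softmax_axis <- match.arg(softmax_axis)
  fusion <- match.arg(fusion)
  stopifnot(C >= 1L, is.finite(lambda_mult), lambda_mult >= 0,
            all(kernel_3d %% 2L == 1L), kernel_2d %% 2L == 1L,
            activation %in% c("silu", "relu", "identity"))
  structure(list(C = as.integer(C), lambda_mult = lambda_mult,
                 activation = activation, softmax_axis = softmax_axis,
                 fusion = fusion, kernel_3d = as.integer(kernel_3d),
                 kernel_2d = as.integer(kernel_2d), seed = as.integer(seed)),
            class = "bsi_config")
}

act_fwd <- function(x, kind) {
  switch(kind, silu = silu(x), relu = pmax(x, 0), identity = x)
}

act_bwd <- function(x, dy, kind) {
  switch(kind, silu = silu_bwd(x, dy), relu = dy * (x > 0), identity = dy)
}

#' Initialize BSI stem weights
#'
#' He-style seeded initialization for the two 2D convolutions, the 3D fusion
#' convolution, and the 2D convolution of the `concat2d` fusion variant.
#'
#' @param cfg A [bsi_config()].
#' @return Named list of weight/bias arrays.
#' @export
bsi_init_weights <- function(cfg) {
  stopifnot(inherits(cfg, "bsi_config"))
  k2 <- cfg$kernel_2d; k3 <- cfg$kernel_3d; C <- cfg$C
  with_seed(cfg$seed, list(
    in.W = he_init(c(C, 3L, k2, k2)), in.b = numeric(C),
    sup.W = he_init(c(C, 3L, k2, k2)), sup.b = numeric(C),
    f3.W = he_init(c(C, C, k3[1L], k3[2L], k3[3L])), f3.b = numeric(C),
    fuse2d.W = he_init(c(C, 2L * C, 3L, 3L)), fuse2d.b = numeric(C)
  ))
}

#' Attention map of the background-suppressed branch
#'
#' Applies the activation, a SoftMax along the configured axis, and the
#' multiplier lambda; along the SoftMax axis the result sums to lambda at
#' every position.
#'
#' @param pre (B, C, H, W) pre-activation feature array.
#' @param cfg A [bsi_config()].
#' @return Array of the same shape.
#' @export
attention_map <- function(pre, cfg) {
  stopifnot(inherits(cfg, "bsi_config"))
  if (!all(is.finite(pre))) stop("non-finite values in attention input")
  d <- dim(pre)
  stopifnot(length(d) == 4L)
  out <- array(0, d)
  for (b in seq_len(d[1L])) {
    x <- array(pre[b, , , ], d[-1L])
    out[b, , , ] <- cfg$lambda_mult * softmax3(act_fwd(x, cfg$activation), cfg$softmax_axis)
  }
  out
}

# single-image stem forward with cache; x_in, x_sup: (3, H, W)
bsi_stem_fwd <- function(x_in, x_sup, cfg, w) {
  p2 <- (cfg$kernel_2d - 1L) %/% 2L
  f1 <- conv2d_fwd(x_in, w$in.W, w$in.b, stride = 2L, pad = p2)
  a1 <- act_fwd(f1$out, cfg$activation)
  f2 <- conv2d_fwd(x_sup, w$sup.W, w$sup.b, stride = 2L, pad = p2)
  g2 <- act_fwd(f2$out, cfg$activation)
  sm <- softmax3(g2, cfg$softmax_axis)
  att <- cfg$lambda_mult * sm
  mod <- att * a1
  fuse_fwd <- fuse_stage_fwd(a1, mod, cfg, w)
  c(list(f1 = f1, a1 = a1, f2 = f2, g2 = g2, sm = sm, att = att, mod = mod),
    fuse_fwd)
}

# fusion stage on single-image maps a1 (input branch) and mod (modulated),
# each (C, H2, W2); returns out (C, H2/2, W2/2) plus caches
fuse_stage_fwd <- function(a1, mod, cfg, w) {
  d <- dim(a1)
  if (cfg$fusion == "addition") {
    mp <- maxpool2_fwd(a1 + mod)
    list(out = mp$out, mp = mp)
  } else if (cfg$fusion == "concat2d") {
    z <- array(0, c(2L * d[1L], d[2L], d[3L]))
    z[seq_len(d[1L]), , ] <- mod
    z[d[1L] + seq_len(d[1L]), , ] <- a1
    cc <- conv2d_fwd(z, w$fuse2d.W, w$fuse2d.b, stride = 2L, pad = 1L)
    ac <- act_fwd(cc$out, cfg$activation)
    list(out = ac, cc = cc, z = z)
  } else {
    z <- array(0, c(d[1L], 2L, d[2L], d[3L]))
    z[, 1L, , ] <- mod
    z[, 2L, , ] <- a1
    c3 <- conv3d_fwd(z, w$f3.W, w$f3.b, stride = c(1L, 2L, 2L))
    a3 <- act_fwd(c3$out, cfg$activation)
    mp <- depth_maxpool_fwd(a3)
    list(out = mp$out, c3 = c3, a3pre = c3$out, mp = mp, z = z)
  }
}

fuse_stage_bwd <- function(dy, cache, cfg, w) {
  if (cfg$fusion == "addition") {
    ds <- maxpool2_bwd(dy, cache$mp)
    list(d_a1 = ds, d_mod = ds, grads = list())
  } else if (cfg$fusion == "concat2d") {
    dcc <- act_bwd(cache$cc$out, dy, cfg$activation)
    bb <- conv2d_bwd(dcc, cache$cc, w$fuse2d.W)
    C <- dim(w$fuse2d.W)[1L]
    dz <- bb$dx
    list(d_mod = array(dz[seq_len(C), , ], dim(dz) - c(C, 0L, 0L)),
         d_a1 = array(dz[C + seq_len(C), , ], dim(dz) - c(C, 0L, 0L)),
         grads = list(fuse2d.W = bb$gW, fuse2d.b = bb$gb))
  } else {
    da3 <- depth_maxpool_bwd(dy, cache$mp)
    dc3 <- act_bwd(cache$a3pre, da3, cfg$activation)
    bb <- conv3d_bwd(dc3, cache$c3, w$f3.W)
    dz <- bb$dx
    dd <- dim(dz)
    list(d_mod = array(dz[, 1L, , ], dd[-2L]),
         d_a1 = array(dz[, 2L, , ], dd[-2L]),
         grads = list(f3.W = bb$gW, f3.b = bb$gb))
  }
}

bsi_stem_bwd <- function(dy, cache, cfg, w, need_input_grad = TRUE) {
  fb <- fuse_stage_bwd(dy, cache, cfg, w)
  # modulation: mod = att * a1
  datt <- fb$d_mod * cache$a1
  da1 <- fb$d_a1 + fb$d_mod * cache$att
  # attention: att = lambda * softmax(act(f2))
  dsm <- cfg$lambda_mult * datt
  dg2 <- softmax3_bwd(cache$sm, dsm, cfg$softmax_axis)
  df2 <- act_bwd(cache$f2$out, dg2, cfg$activation)
  b2 <- conv2d_bwd(df2, cache$f2, w$sup.W, need_dx = need_input_grad)
  # input branch
  df1 <- act_bwd(cache$f1$out, da1, cfg$activation)
  b1 <- conv2d_bwd(df1, cache$f1, w$in.W, need_dx = need_input_grad)
  grads <- c(list(in.W = b1$gW, in.b = b1$gb, sup.W = b2$gW, sup.b = b2$gb),
             fb$grads)
  list(grads = grads, d_in = b1$dx, d_sup = b2$dx)
}

as_batch4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    array(x, c(1L, d))
  } else if (length(d) == 4L) {
    x
  } else stop("expected a (B, C, H, W) or (C, H, W) array")
}

#' Forward pass of the BSI stem
#'
#' Consumes the two co-registered views and produces the fused feature map at
#' 1/4 of the input resolution: conv(s2) per view, attention modulation of
#' the input branch by the suppressed branch, depth stacking, 3D convolution
#' with spatial stride 2, and max pooling over the depth axis. With
#' `cfg$fusion` set to `"addition"` or `"concat2d"` the fusion stage is
#' replaced by the corresponding ablation variant; the output shape is
#' identical for all variants.
#'
#' @param input_view (B, 3, H, W) array (or (3, H, W)); H, W divisible by 4.
#' @param suppressed_view Same shape as `input_view`.
#' @param cfg A [bsi_config()].
#' @param weights Weights from [bsi_init_weights()].
#' @return (B, C, H/4, W/4) array.
#' @export
bsi_forward <- function(input_view, suppressed_view, cfg, weights = bsi_init_weights(cfg)) {
  stopifnot(inherits(cfg, "bsi_config"))
  xi <- as_batch4(input_view)
  xs <- as_batch4(suppressed_view)
  if (!all(dim(xi) == dim(xs))) stop("the two views must share dimensions")
  d <- dim(xi)
  if (d[3L] %% 4L != 0L || d[4L] %% 4L != 0L) {
    stop("input height and width must be divisible by 4")
  }
  out <- array(0, c(d[1L], cfg$C, d[3L] %/% 4L, d[4L] %/% 4L))
  for (b in seq_len(d[1L])) {
    fw <- bsi_stem_fwd(array(xi[b, , , ], d[-1L]), array(xs[b, , , ], d[-1L]),
                       cfg, weights)
    out[b, , , ] <- fw$out
  }
  out
}

#' Fusion-stage ablation forward
#'
#' Combines the input-branch and modulated feature maps with one of the three
#' fusion strategies: element-wise `addition` followed by stride-2 max
#' pooling, channel `concat2d` followed by a stride-2 2D convolution, or the
#' depth-stacked `3dconv` with depth max pooling. All variants map
#' (B, C, H/2, W/2) inputs to (B, C, H/4, W/4).
#'
#' @param input_feat (B, C, H2, W2) input-branch features.
#' @param modulated_feat Same shape: attention-modulated features.
#' @param cfg A [bsi_config()] whose `fusion` selects the variant.
#' @param weights Weights from [bsi_init_weights()].
#' @return (B, C, H2/2, W2/2) array.
#' @export
fuse_variant_forward <- function(input_feat, modulated_feat, cfg,
                                 weights = bsi_init_weights(cfg)) {
  stopifnot(inherits(cfg, "bsi_config"))
  fi <- as_batch4(input_feat)
  fm <- as_batch4(modulated_feat)
  if (!all(dim(fi) == dim(fm))) stop("feature maps must share dimensions")
  d <- dim(fi)
  out <- array(0, c(d[1L], cfg$C, d[3L] %/% 2L, d[4L] %/% 2L))
  for (b in seq_len(d[1L])) {
    fw <- fuse_stage_fwd(array(fi[b, , , ], d[-1L]), array(fm[b, , , ], d[-1L]),
                         cfg, weights)
    out[b, , , ] <- fw$out
  }
  out
}

#' Serializable descriptor of the BSI stem
#'
#' Describes the stem's layer geometry (channels, kernels, strides) so it can
#' replace the first convolution layer of a downstream detector backbone;
#' downstream layers then see features at 1/4 instead of 1/2 resolution.
#'
#' @param cfg A [bsi_config()].
#' @return A list of class `stem_descriptor` with a `layers` list and an
#'   `output_stride` of 4.
#' @export
stem_replace_descriptor <- function(cfg) {
  stopifnot(inherits(cfg, "bsi_config"))
  layers <- list(
    list(op = "conv2d", branch = "input", cin = 3L, cout = cfg$C,
         kernel = c(cfg$kernel_2d, cfg$kernel_2d), stride = 2L),
    list(op = "conv2d", branch = "suppressed", cin = 3L, cout = cfg$C,
         kernel = c(cfg$kernel_2d, cfg$kernel_2d), stride = 2L)
  )
  if (cfg$fusion == "3dconv") {
    layers <- c(layers, list(
      list(op = "conv3d", cin = cfg$C, cout = cfg$C, kernel = cfg$kernel_3d,
           stride = c(1L, 2L, 2L)),
      list(op = "maxpool_depth")
    ))
  } else if (cfg$fusion == "concat2d") {
    layers <- c(layers, list(
      list(op = "conv2d", branch = "fuse", cin = 2L * cfg$C, cout = cfg$C,
           kernel = c(3L, 3L), stride = 2L)
    ))
  } else {
    layers <- c(layers, list(list(op = "add"), list(op = "maxpool2d", stride = 2L)))
  }
  structure(list(kind = "bsi_stem", channels = cfg$C,
                 lambda_mult = cfg$lambda_mult, activation = cfg$activation,
                 softmax_axis = cfg$softmax_axis, fusion = cfg$fusion,
                 output_stride = 4L, layers = layers),
            class = "stem_descriptor")
}

#' Serialize a stem descriptor to YAML text
#'
#' @param desc A `stem_descriptor`.
#' @return A YAML character scalar.
#' @export
stem_descriptor_yaml <- function(desc) {
  stopifnot(inherits(desc, "stem_descriptor"))
  yaml::as.yaml(unclass(desc))
}

#' Parse a stem descriptor back from YAML text
#'
#' @param text YAML produced by [stem_descriptor_yaml()].
#' @return A `stem_descriptor`.
#' @export
parse_stem_descriptor <- function(text) {
  x <- yaml::yaml.load(text)
  norm_layer <- function(l) {
    for (nm in intersect(c("cin", "cout", "kernel", "stride"), names(l))) {
      l[[nm]] <- as.integer(unlist(l[[nm]]))
    }
    l
  }
  x$layers <- lapply(x$layers, norm_layer)
  x$channels <- as.integer(x$channels)
  x$output_stride <- as.integer(x$output_stride)
  structure(x, class = "stem_descriptor")
}
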