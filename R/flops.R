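# Layer-wise convolution FLOPs accounting.
#
# One multiply-accumulate counts as two floating-point operations. Only
# convolution layers are counted; activations, pooling and normalization are
# excluded from the audit.

#' Describe one convolution layer for FLOPs accounting
#'
#' @param kind `"conv2d"` or `"conv3d"`.
#' @param cin,cout Input / output channels.
#' @param kernel Kernel sizes: length 2 `(Kh, Kw)` for 2D, length 3
#'   `(Kd, Kh, Kw)` for 3D.
#' @param out Output feature-map size: `(Hout, Wout)` for 2D,
#'   `(Dout, Hout, Wout)` for 3D.
#' @param groups Number of groups (1 = standard convolution).
#' @param name Optional label.
#' @return A list of class `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kind = c("conv2d", "conv3d"), cin, cout, kernel,
                            out, groups = 1L, name = "") {
  kind <- match.arg(kind)
  nd <- if (kind == "conv2d") 2L else 3L
  stopifnot(length(kernel) == nd, length(out) == nd,
            cin >= 1L, cout >= 1L, groups >= 1L,
            all(kernel >= 1L), all(out >= 1L))
  if (cin %% groups != 0L) stop("`cin` must be divisible by `groups`")
  structure(list(kind = kind, cin = as.integer(cin), cout = as.integer(cout),
                 kernel = as.integer(kernel), out = as.integer(out),
                 groups = as.integer(groups), name = as.character(name)),
            class = "conv_layer_spec")
}

#' FLOPs of one convolution layer
#'
#' For a 2D convolution: `2 * Hout * Wout * Cout * (Cin / g) * Kh * Kw`,
#' one multiplication plus one addition per multiply-accumulate. A 3D
#' convolution additionally multiplies by `Dout * Kd`. Exact integer count
#' (returned as a double to avoid 32-bit overflow).
#'
#' @param spec A [conv_layer_spec()].
#' @return FLOPs count.
#' @export
conv_flops <- function(spec) {
  stopifnot(inherits(spec, "conv_layer_spec"))
  2 * prod(as.double(spec$out)) * spec$cout * (spec$cin / spec$groups) *
    prod(as.double(spec$kernel))
}

#' Total GFLOPs of a layer list
#'
#' @param layers Nonempty list of [conv_layer_spec()] objects.
#' @return Sum of per-layer FLOPs divided by 1e9.
#' @export
model_gflops <- function(layers) {
  if (!length(layers)) stop("empty layer list")
  sum(vapply(layers, conv_flops, 0)) / 1e9
}

scale_spatial <- function(spec, factor) {
  nd <- length(spec$out)
  out <- spec$out
  out[(nd - 1L):nd] <- as.integer(round(out[(nd - 1L):nd] * factor))
  conv_layer_spec(spec$kind, spec$cin, spec$cout, spec$kernel, out,
                  spec$groups, spec$name)
}

# conv specs for a stem descriptor at a given input size
stem_layer_specs <- function(desc, height, width) {
  h2 <- height %/% 2L; w2 <- width %/% 2L
  h4 <- height %/% 4L; w4 <- width %/% 4L
  specs <- list()
  for (l in desc$layers) {
    if (identical(l$op, "conv2d")) {
      o <- if (identical(l$branch, "fuse")) c(h4, w4) else c(h2, w2)
      specs[[length(specs) + 1L]] <-
        conv_layer_spec("conv2d", l$cin, l$cout, l$kernel, o,
                        name = paste0("stem_", l$branch))
    } else if (identical(l$op, "conv3d")) {
      specs[[length(specs) + 1L]] <-
        conv_layer_spec("conv3d", l$cin, l$cout, l$kernel, c(2L, h4, w4),
                        name = "stem_3dconv")
    }
  }
  specs
}

#' Baseline single-convolution stem descriptor
#'
#' The stem the BSI module replaces: one stride-2 convolution from RGB to `C`
#' channels, leaving downstream layers at 1/2 input resolution.
#'
#' @param C Stem channels.
#' @param kernel Spatial kernel size.
#' @return A list of class `stem_descriptor`.
#' @export
baseline_stem_descriptor <- function(C = 16L, kernel = 3L) {
  structure(list(kind = "baseline_stem", channels = as.integer(C),
                 output_stride = 2L,
                 layers = list(list(op = "conv2d", branch = "input", cin = 3L,
                                    cout = as.integer(C),
                                    kernel = c(kernel, kernel), stride = 2L))),
            class = "stem_descriptor")
}

#' Compare the compute cost of a baseline stem vs the BSI stem
#'
#' The baseline configuration runs the downstream layers at 1/2 input
#' resolution; the BSI configuration runs the identical downstream stack at
#' 1/4 resolution (each downstream convolution then costs exactly 1/4 as
#' much, since FLOPs are linear in `Hout * Wout`). Reports the two totals and
#' their ratio.
#'
#' @param baseline A baseline `stem_descriptor` (output stride 2).
#' @param bsi A BSI `stem_descriptor` (output stride 4).
#' @param downstream List of [conv_layer_spec()] giving the downstream layers
#'   with output sizes as they would run in the *baseline* configuration.
#' @param height,width Input image size in pixels.
#' @return List with `baseline_gflops`, `bsi_gflops`, `ratio`, and the
#'   per-configuration layer lists.
#' @export
stem_comparison <- function(baseline, bsi, downstream = list(),
                            height = 640L, width = 640L) {
  stopifnot(inherits(baseline, "stem_descriptor"), inherits(bsi, "stem_descriptor"))
  base_layers <- c(stem_layer_specs(baseline, height, width), downstream)
  bsi_down <- lapply(downstream, scale_spatial, factor = 0.5)
  bsi_layers <- c(stem_layer_specs(bsi, height, width), bsi_down)
  bg <- model_gflops(base_layers)
  sg <- model_gflops(bsi_layers)
  list(baseline_gflops = bg, bsi_gflops = sg, ratio = sg / bg,
       baseline_layers = base_layers, bsi_layers = bsi_layers)
}

#' Downstream layer inventory of the bundled reference backbone
#'
#' A medium-depth, all-convolution backbone-and-head inventory (channel
#' widths 64 to 512, repeated 3x3 blocks over four stages) representative of
#' the single-scale detectors the stem targets. Output sizes are given for
#' the baseline configuration, i.e. with the first stage at 1/2 input
#' resolution.
#'
#' @param height,width Input image size in pixels.
#' @param C Stem output channels feeding the first stage.
#' @return List of [conv_layer_spec()].
#' @export
reference_backbone_specs <- function(height = 640L, width = 640L, C = 16L) {
  h <- function(s) height %/% s
  w <- function(s) width %/% s
  widths <- c(64L, 128L, 256L, 512L)
  strides <- c(4L, 8L, 16L, 32L)
  reps <- c(2L, 3L, 4L, 2L)
  specs <- list()
  cin <- C
  for (i in seq_along(widths)) {
    specs[[length(specs) + 1L]] <- conv_layer_spec(
      "conv2d", cin, widths[i], c(3L, 3L), c(h(strides[i]), w(strides[i])),
      name = sprintf("stage%d_down", i))
    for (r in seq_len(reps[i])) {
      specs[[length(specs) + 1L]] <- conv_layer_spec(
        "conv2d", widths[i], widths[i], c(3L, 3L),
        c(h(strides[i]), w(strides[i])), name = sprintf("stage%d_block%d", i, r))
    }
    cin <- widths[i]
  }
  specs[[length(specs) + 1L]] <- conv_layer_spec(
    "conv2d", cin, 5L, c(1L, 1L), c(h(32L), w(32L)), name = "head")
  specs
}
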