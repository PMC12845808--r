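# Minimal single-class, single-scale dense detector.
#
# Small enough to train on a CPU in minutes, yet structured like the
# detectors the stem targets: a stem (baseline single-input convolution, or
# the dual-input BSI stem), a fixed all-convolution body, and a 1x1 head
# predicting objectness plus box offsets on a coarse grid. The baseline stem
# feeds the body at 1/2 input resolution and adds one extra downsampling
# block before the head; the BSI stem feeds the identical body at 1/4
# resolution, so both variants share the same head grid.

#' Toy detector configuration
#'
#' @param stem `"baseline"` (single input view) or `"bsi"` (dual view).
#' @param bsi A [bsi_config()] used when `stem = "bsi"`; its `C` also sets
#'   the baseline stem width.
#' @param body_channels Length-2 integer vector of body widths.
#' @param grid_stride Pixels per head cell; must equal 16 for the default
#'   two-downsample body.
#' @param conf_threshold Objectness threshold for decoding.
#' @param nms_iou IoU above which a lower-confidence box is suppressed.
#' @param epochs,batch_size,lr Training schedule.
#' @param lambda_box Weight of the box L1 loss against objectness BCE.
#' @param pos_weight BCE weight of positive (object) cells.
#' @param seed Seed for weight init and batch shuffling.
#' @return List of class `detector_config`.
#' @export
detector_config <- function(stem = c("bsi", "baseline"), bsi = bsi_config(),
                            body_channels = c(64L, 128L), grid_stride = 16L,
                            conf_threshold = 0.3, nms_iou = 0.5,
                            epochs = 30L, batch_size = 8L, lr = 2e-3,
                            lambda_box = 5, pos_weight = 2, seed = 1L) {
  stem <- match.arg(stem)
  stopifnot(length(body_channels) == 2L, grid_stride == 16L,
            conf_threshold > 0, conf_threshold < 1,
            nms_iou > 0, nms_iou < 1)
  structure(list(stem = stem, bsi = bsi,
                 body_channels = as.integer(body_channels),
                 grid_stride = as.integer(grid_stride),
                 conf_threshold = conf_threshold, nms_iou = nms_iou,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lambda_box = lambda_box, pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "detector_config")
}

init_detector_params <- function(cfg) {
  C <- cfg$bsi$C
  bc <- cfg$body_channels
  with_seed(cfg$seed, {
    p <- list()
    if (cfg$stem == "baseline") {
      p$stem.W <- he_init(c(C, 3L, 3L, 3L)); p$stem.b <- numeric(C)
    } else {
      sw <- bsi_init_weights(cfg$bsi)
      names(sw) <- paste0("stem_", names(sw))
      p <- c(p, sw)
    }
    p$body1.W <- he_init(c(bc[1L], C, 3L, 3L)); p$body1.b <- numeric(bc[1L])
    p$body2.W <- he_init(c(bc[2L], bc[1L], 3L, 3L)); p$body2.b <- numeric(bc[2L])
    if (cfg$stem == "baseline") {
      p$extra.W <- he_init(c(bc[2L], bc[2L], 3L, 3L)); p$extra.b <- numeric(bc[2L])
    }
    p$head.W <- he_init(c(5L, bc[2L], 1L, 1L)); p$head.b <- numeric(5L)
    p
  })
}

# views: list of (3, H, W) arrays (one for baseline, two for bsi)
detector_fwd <- function(views, cfg, p) {
  cache <- list()
  if (cfg$stem == "baseline") {
    cache$stem <- conv2d_fwd(views[[1L]], p$stem.W, p$stem.b, stride = 2L, pad = 1L)
    x <- silu(cache$stem$out)
  } else {
    sw <- p[startsWith(names(p), "stem_")]
    names(sw) <- sub("^stem_", "", names(sw))
    cache$stem <- bsi_stem_fwd(views[[1L]], views[[2L]], cfg$bsi, sw)
    x <- cache$stem$out
  }
  cache$b1 <- conv2d_fwd(x, p$body1.W, p$body1.b, stride = 2L, pad = 1L)
  a1 <- silu(cache$b1$out)
  cache$b2 <- conv2d_fwd(a1, p$body2.W, p$body2.b, stride = 2L, pad = 1L)
  a2 <- silu(cache$b2$out)
  if (cfg$stem == "baseline") {
    cache$extra <- conv2d_fwd(a2, p$extra.W, p$extra.b, stride = 2L, pad = 1L)
    a2 <- silu(cache$extra$out)
  }
  cache$head <- conv2d_fwd(a2, p$head.W, p$head.b, stride = 1L, pad = 0L)
  cache$stem_in <- x
  list(grid = cache$head$out, cache = cache)
}

detector_bwd <- function(dgrid, fw, views, cfg, p) {
  g <- list()
  hb <- conv2d_bwd(dgrid, fw$cache$head, p$head.W)
  g$head.W <- hb$gW; g$head.b <- hb$gb
  dx <- hb$dx
  if (cfg$stem == "baseline") {
    dx <- silu_bwd(fw$cache$extra$out, dx)
    eb <- conv2d_bwd(dx, fw$cache$extra, p$extra.W)
    g$extra.W <- eb$gW; g$extra.b <- eb$gb
    dx <- eb$dx
  }
  dx <- silu_bwd(fw$cache$b2$out, dx)
  b2 <- conv2d_bwd(dx, fw$cache$b2, p$body2.W)
  g$body2.W <- b2$gW; g$body2.b <- b2$gb
  dx <- silu_bwd(fw$cache$b1$out, b2$dx)
  b1 <- conv2d_bwd(dx, fw$cache$b1, p$body1.W)
  g$body1.W <- b1$gW; g$body1.b <- b1$gb
  dstem <- b1$dx
  if (cfg$stem == "baseline") {
    ds <- silu_bwd(fw$cache$stem$out, dstem)
    sb <- conv2d_bwd(ds, fw$cache$stem, p$stem.W, need_dx = FALSE)
    g$stem.W <- sb$gW; g$stem.b <- sb$gb
  } else {
    sw <- p[startsWith(names(p), "stem_")]
    names(sw) <- sub("^stem_", "", names(sw))
    sb <- bsi_stem_bwd(dstem, fw$cache$stem, cfg$bsi, sw, need_input_grad = FALSE)
    sg <- sb$grads
    names(sg) <- paste0("stem_", names(sg))
    g <- c(g, sg)
  }
  g
}

# targets: (5, G, G) array; channel 1 objectness in {0,1}, channels 2:5 the
# sigmoid-space box targets (cell offsets cx, cy and image-fraction w, h)
build_targets <- function(gt, H, W, stride) {
  G <- H %/% stride
  t <- array(0, c(5L, G, G))
  if (nrow(gt)) {
    for (i in seq_len(nrow(gt))) {
      cx <- (gt$x1[i] + gt$x2[i]) / 2
      cy <- (gt$y1[i] + gt$y2[i]) / 2
      gj <- min(G - 1L, max(0L, floor(cx / stride)))
      gi <- min(G - 1L, max(0L, floor(cy / stride)))
      if (t[1L, gi + 1L, gj + 1L] == 1) next  # first box claims the cell
      t[1L, gi + 1L, gj + 1L] <- 1
      t[2L, gi + 1L, gj + 1L] <- cx / stride - gj
      t[3L, gi + 1L, gj + 1L] <- cy / stride - gi
      t[4L, gi + 1L, gj + 1L] <- min(1, (gt$x2[i] - gt$x1[i]) / W)
      t[5L, gi + 1L, gj + 1L] <- min(1, (gt$y2[i] - gt$y1[i]) / H)
    }
  }
  t
}

loss_and_dgrid <- function(grid, targets, cfg) {
  G2 <- prod(dim(grid)[2:3])
  y <- targets[1L, , ]
  s <- sigmoid(grid[1L, , ])
  s <- pmin(pmax(s, 1e-7), 1 - 1e-7)
  pw <- cfg$pos_weight
  bce <- -mean(pw * y * log(s) + (1 - y) * log(1 - s))
  dgrid <- array(0, dim(grid))
  dgrid[1L, , ] <- (pw * y * (s - 1) + (1 - y) * s) / G2
  npos <- sum(y)
  l1 <- 0
  if (npos > 0) {
    for (k in 2:5) {
      sb <- sigmoid(grid[k, , ])
      diff <- (sb - targets[k, , ]) * y
      l1 <- l1 + sum(abs(diff))
      dgrid[k, , ] <- cfg$lambda_box * sign(diff) * sb * (1 - sb) * y / (4 * npos)
    }
    l1 <- l1 / (4 * npos)
  }
  list(loss = bce + cfg$lambda_box * l1, dgrid = dgrid,
       obj_loss = bce, box_loss = l1)
}

#' Convert an H x W x 3 frame to a channel-first network tensor
#'
#' @param frame H x W x 3 integer array in \code{[0, 255]}.
#' @return A (3, H, W) double array scaled to \code{[0, 1]}.
#' @export
frame_to_tensor <- function(frame) {
  aperm(frame, c(3L, 1L, 2L)) / 255
}

variant_settings <- function(variant) {
  switch(variant,
    baseline = list(stem = "baseline", use_fig = FALSE, input_mode = "suppressed",
                    fusion = NULL),
    big = list(stem = "bsi", use_fig = FALSE, input_mode = "suppressed",
               fusion = "3dconv"),
    big_fig = list(stem = "bsi", use_fig = TRUE, input_mode = "suppressed",
                   fusion = "3dconv"),
    big_fig_addition = list(stem = "bsi", use_fig = TRUE,
                            input_mode = "suppressed", fusion = "addition"),
    big_fig_concat2d = list(stem = "bsi", use_fig = TRUE,
                            input_mode = "suppressed", fusion = "concat2d"),
    diff_fig = list(stem = "bsi", use_fig = TRUE, input_mode = "difference",
                    fusion = "3dconv"),
    stop(sprintf("unknown variant '%s'", variant))
  )
}

#' Load a generated dataset directory
#'
#' @param dir Directory written by [generate_dataset()].
#' @return List with `frames`, `labels`, `manifest`, and the environment's
#'   `background_model`.
#' @export
load_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  nm <- unlist(manifest$images)
  frames <- lapply(nm, function(n) read_frame(file.path(dir, "images", paste0(n, ".png"))))
  labels <- lapply(nm, function(n) read_yolo_labels(file.path(dir, "labels", paste0(n, ".txt")),
                                                    manifest$width, manifest$height))
  model <- build_background_model(read_frame(file.path(dir, "background.png")),
                                  read_gray(file.path(dir, "depth.png")),
                                  env_id = manifest$env_id)
  list(frames = frames, labels = labels, names = nm, manifest = manifest,
       model = model)
}

build_views <- function(frame, model, vs) {
  if (vs$stem == "baseline") {
    return(list(frame_to_tensor(frame)))
  }
  fp <- fuse_inputs(frame, model, use_fig = vs$use_fig, input_mode = vs$input_mode)
  list(frame_to_tensor(fp$input_view), frame_to_tensor(fp$suppressed_view))
}

#' Fit the toy detector on a generated dataset
#'
#' Prepares the per-frame network inputs for the chosen pipeline variant
#' (the static-camera preprocessing runs once per frame before training),
#' then trains the dense detector with Adam on objectness BCE plus an L1
#' box loss. Deterministic for a fixed config seed.
#'
#' Variants: `"baseline"` (raw single input), `"big"` (dual input with
#' background suppression), `"big_fig"` (plus facility masking, the full
#' pipeline), `"big_fig_addition"` / `"big_fig_concat2d"` (fusion-stage
#' ablations) and `"diff_fig"` (raw difference image instead of the
#' background-suppressed image).
#'
#' @param train_dir Dataset directory from [generate_dataset()].
#' @param variant Pipeline variant; see Details.
#' @param config A [detector_config()].
#' @param verbose Print per-epoch losses?
#' @return Object of class `pen_detector`.
#' @export
pen_detector <- function(train_dir, variant = "big_fig",
                         config = detector_config(), verbose = FALSE) {
  vs <- variant_settings(variant)
  cfg <- config
  cfg$stem <- vs$stem
  if (!is.null(vs$fusion)) cfg$bsi$fusion <- vs$fusion
  ds <- load_dataset(train_dir)
  if (!length(ds$frames)) stop("empty training dataset")
  H <- ds$manifest$height; W <- ds$manifest$width
  views <- lapply(ds$frames, build_views, model = ds$model, vs = vs)
  targets <- lapply(ds$labels, build_targets, H = H, W = W, stride = cfg$grid_stride)
  params <- init_detector_params(cfg)
  state <- adam_init(params)
  n <- length(views)
  losses <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, 77L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
        grads <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- detector_fwd(views[[i]], cfg, params)
          lo <- loss_and_dgrid(fw$grid, targets[[i]], cfg)
          gi <- detector_bwd(lo$dgrid, fw, views[[i]], cfg, params)
          bloss <- bloss + lo$loss
          if (is.null(grads)) {
            grads <- gi
          } else {
            for (nm in names(gi)) grads[[nm]] <- grads[[nm]] + gi[[nm]]
          }
        }
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(idx)
        upd <- adam_step(params, grads, state, lr = cfg$lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bloss / length(idx)
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
    }
  })
  structure(list(params = params, config = cfg, variant = variant,
                 losses = losses, train_env = ds$manifest$env_id,
                 image_size = c(H, W)),
            class = "pen_detector")
}

#' @export
print.pen_detector <- function(x, ...) {
  cat(sprintf("Toy pen detector (variant '%s', %s stem)\n", x$variant, x$config$stem))
  cat(sprintf("  trained %d epochs on env '%s'; final loss %.4f\n",
              length(x$losses), x$train_env, x$losses[length(x$losses)]))
  invisible(x)
}

#' @export
summary.pen_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  loss: first %.4f -> last %.4f\n",
              object$losses[1L], object$losses[length(object$losses)]))
  cat(sprintf("  parameters: %d arrays, %d values\n", length(object$params),
              sum(vapply(object$params, length, 0L))))
  invisible(object)
}

#' Decode a prediction grid into detections with greedy NMS
#'
#' @param grid (5, G, G) head output (logits).
#' @param cfg A [detector_config()].
#' @param H,W Image size in pixels.
#' @return Data frame `x1,y1,x2,y2,confidence`.
#' @export
decode_and_nms <- function(grid, cfg, H, W) {
  G <- dim(grid)[2L]
  stride <- H / G
  conf <- sigmoid(grid[1L, , ])
  sel <- which(conf > cfg$conf_threshold, arr.ind = TRUE)
  if (!nrow(sel)) {
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), confidence = numeric()))
  }
  boxes <- do.call(rbind, lapply(seq_len(nrow(sel)), function(k) {
    gi <- sel[k, 1L]; gj <- sel[k, 2L]
    sx <- sigmoid(grid[2L, gi, gj]); sy <- sigmoid(grid[3L, gi, gj])
    sw <- sigmoid(grid[4L, gi, gj]); sh <- sigmoid(grid[5L, gi, gj])
    cx <- (gj - 1L + sx) * stride; cy <- (gi - 1L + sy) * stride
    bw <- sw * W; bh <- sh * H
    data.frame(x1 = max(0, cx - bw / 2), y1 = max(0, cy - bh / 2),
               x2 = min(W, cx + bw / 2), y2 = min(H, cy + bh / 2),
               confidence = conf[gi, gj])
  }))
  boxes <- boxes[boxes$x2 > boxes$x1 & boxes$y2 > boxes$y1, , drop = FALSE]
  if (!nrow(boxes)) return(boxes)
  ord <- order(-boxes$confidence, seq_len(nrow(boxes)))
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (box_iou(as.numeric(boxes[i, 1:4]), as.numeric(boxes[j, 1:4])) > cfg$nms_iou) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the detector on a dataset directory
#'
#' Applies the variant's own static-camera preprocessing using the *target*
#' directory's background and depth plates (one-time per environment, no
#' retraining), then decodes detections per frame.
#'
#' @param object A fitted `pen_detector`.
#' @param newdata Dataset directory from [generate_dataset()].
#' @param ... Unused.
#' @return Data frame `image,x1,y1,x2,y2,confidence`.
#' @export
predict.pen_detector <- function(object, newdata, ...) {
  vs <- variant_settings(object$variant)
  ds <- load_dataset(newdata)
  H <- ds$manifest$height; W <- ds$manifest$width
  out <- list()
  for (i in seq_along(ds$frames)) {
    views <- build_views(ds$frames[[i]], ds$model, vs)
    fw <- detector_fwd(views, object$config, object$params)
    dets <- decode_and_nms(fw$grid, object$config, H, W)
    if (nrow(dets)) {
      dets$image <- ds$names[[i]]
      out[[length(out) + 1L]] <- dets
    }
  }
  if (!length(out)) {
    return(data.frame(image = character(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), confidence = numeric()))
  }
  res <- do.call(rbind, out)
  res[, c("image", "x1", "y1", "x2", "y2", "confidence")]
}

#' Evaluate a fitted detector on a dataset directory
#'
#' @param object A fitted `pen_detector`.
#' @param dir Dataset directory.
#' @return An `eval_report` (AP50, precision, recall, F1).
#' @export
evaluate_detector <- function(object, dir) {
  ds <- load_dataset(dir)
  gts <- do.call(rbind, lapply(seq_along(ds$labels), function(i) {
    g <- ds$labels[[i]]
    if (nrow(g)) g$image <- ds$names[[i]]
    g
  }))
  dets <- predict(object, dir)
  if (is.null(gts) || nrow(gts) == 0L) stop("dataset has no ground-truth boxes")
  ap50(dets, gts)
}

#' Save / load a fitted detector
#'
#' @param object A `pen_detector`.
#' @param path Checkpoint path (RDS).
#' @return `save_pen_detector` invisibly returns `path`;
#'   `load_pen_detector` returns the restored object.
#' @export
save_pen_detector <- function(object, path) {
  stopifnot(inherits(object, "pen_detector"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_pen_detector
#' @export
load_pen_detector <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "pen_detector"))
  obj
}

#' Convolution layer inventory of a toy detector variant
#'
#' @param variant Pipeline variant name.
#' @param config A [detector_config()].
#' @param height,width Input size.
#' @return List of [conv_layer_spec()].
#' @export
detector_layer_specs <- function(variant, config = detector_config(),
                                 height = 160L, width = 160L) {
  vs <- variant_settings(variant)
  C <- config$bsi$C
  bc <- config$body_channels
  if (vs$stem == "baseline") {
    specs <- list(conv_layer_spec("conv2d", 3L, C, c(3L, 3L),
                                  c(height %/% 2L, width %/% 2L), name = "stem"))
    s1 <- 4L
  } else {
    cfgb <- config$bsi
    if (!is.null(vs$fusion)) cfgb$fusion <- vs$fusion
    specs <- stem_layer_specs(stem_replace_descriptor(cfgb), height, width)
    s1 <- 8L
  }
  specs <- c(specs, list(
    conv_layer_spec("conv2d", C, bc[1L], c(3L, 3L),
                    c(height %/% s1, width %/% s1), name = "body1"),
    conv_layer_spec("conv2d", bc[1L], bc[2L], c(3L, 3L),
                    c(height %/% (2L * s1), width %/% (2L * s1)), name = "body2")
  ))
  if (vs$stem == "baseline") {
    specs <- c(specs, list(conv_layer_spec("conv2d", bc[2L], bc[2L], c(3L, 3L),
                                           c(height %/% 16L, width %/% 16L),
                                           name = "extra_down")))
  }
  c(specs, list(conv_layer_spec("conv2d", bc[2L], 5L, c(1L, 1L),
                                c(height %/% 16L, width %/% 16L), name = "head")))
}

#' Seen-vs-unseen experiment over pipeline variants and seeds
#'
#' For each seed: generates a training and an evaluation split in the "seen"
#' environment (sharing one static background plate) and an evaluation set in
#' the "unseen" environment; trains each variant on the seen split; evaluates
#' AP50/F1 on both environments. Each environment is preprocessed with its
#' own plates, never retrained.
#'
#' @param seen_config,unseen_config [scene_config()]s of the two environments.
#' @param variants Character vector of variant names.
#' @param seeds Integer vector of experiment seeds.
#' @param n_train,n_test Images per split.
#' @param config A [detector_config()].
#' @param work_dir Where datasets are written (default a temp dir).
#' @param verbose Print progress?
#' @return Data frame with one row per (variant, seed, env):
#'   `variant, seed, env, ap50, f1, precision, recall`.
#' @export
run_experiment <- function(seen_config = example_scene_config("seen"),
                           unseen_config = example_scene_config("unseen"),
                           variants = c("baseline", "big_fig"),
                           seeds = 1:3, n_train = 24L, n_test = 12L,
                           config = detector_config(),
                           work_dir = tempfile("penexp"), verbose = FALSE) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seeds) {
    d_train <- file.path(work_dir, sprintf("seed%d_seen_train", s))
    d_seen <- file.path(work_dir, sprintf("seed%d_seen_eval", s))
    d_unseen <- file.path(work_dir, sprintf("seed%d_unseen_eval", s))
    env_seed <- derive_seed(s, 900L)
    generate_dataset(seen_config, n_train, d_train, seed = derive_seed(s, 1L),
                     env_seed = env_seed)
    generate_dataset(seen_config, n_test, d_seen, seed = derive_seed(s, 2L),
                     env_seed = env_seed)
    generate_dataset(unseen_config, n_test, d_unseen, seed = derive_seed(s, 3L))
    for (v in variants) {
      cfg <- config
      cfg$seed <- derive_seed(s, 10L)
      fit <- pen_detector(d_train, variant = v, config = cfg)
      for (env in c("seen", "unseen")) {
        rep <- evaluate_detector(fit, if (env == "seen") d_seen else d_unseen)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, seed = s, env = env, ap50 = rep$ap50, f1 = rep$f1,
          precision = rep$precision, recall = rep$recall)
        if (verbose) {
          message(sprintf("seed %d %-16s %-6s AP50 %.3f F1 %.3f",
                          s, v, env, rep$ap50, rep$f1))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write an experiment results table to CSV and YAML
#'
#' @param results Data frame from [run_experiment()].
#' @param stem_path Output path stem; writes `<stem>.csv` and `<stem>.yaml`.
#' @return Invisibly, the two paths.
#' @export
write_results_table <- function(results, stem_path) {
  csv <- paste0(stem_path, ".csv")
  yml <- paste0(stem_path, ".yaml")
  utils::write.csv(results, csv, row.names = FALSE)
  yaml::write_yaml(lapply(seq_len(nrow(results)), function(i) as.list(results[i, ])),
                   yml)
  invisible(c(csv, yml))
}
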