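# Seeded synthetic pen-scene simulator.
#
# Emulates what a fixed camera over a pig pen sees: a static, low-frequency
# textured floor, bright facility structures (feeder rails, ceiling pipes)
# closer to the camera than the floor, and several elliptical animal blobs
# with speckled texture. Facilities occlude animals; animals whose visible
# fraction is at most 20% are dropped from the ground truth, matching the
# labeling rule used for real pen footage.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 100003 + as.double(i) * 7919) %% 2147483629)
}

# box blur with edge replication, used to give the floor its low-frequency look
blur_box <- function(m, r) {
  if (r < 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  mp <- m[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
  k <- 2L * r + 1L
  cs <- apply(mp, 2L, cumsum)
  rows <- cs[k:(h + k - 1L), , drop = FALSE] -
    rbind(matrix(0, 1L, ncol(cs)), cs[1:(h - 1L), , drop = FALSE])
  cs2 <- t(apply(rows, 1L, cumsum))
  out <- cs2[, k:(w + k - 1L), drop = FALSE] -
    cbind(matrix(0, nrow(cs2), 1L), cs2[, 1:(w - 1L), drop = FALSE])
  out / (k * k)
}

#' Configuration of a synthetic pen scene
#'
#' @param height,width Image size in pixels; both must be divisible by 4.
#' @param n_animals Number of elliptical animals per frame.
#' @param animal_axis_range Length-2 vector, min and max semi-axis in pixels.
#' @param animal_intensity Length-2 vector, mean and sd of the per-animal
#'   base 8-bit intensity.
#' @param background_texture List with `scale` (blur radius in pixels), `rgb`
#'   (length-3 base color) and `amp` (texture amplitude, 8-bit units).
#' @param facility_layout List of bars, each a list with `x1,y1,x2,y2`
#'   (1-based inclusive pixel coords) and `brightness` (8-bit).
#' @param facility_depth_value,background_depth_value 8-bit depth levels;
#'   facility must be strictly closer (larger) than background.
#' @param noise_std Per-pixel Gaussian noise sd, 8-bit units.
#' @param env_id Environment label, e.g. `"seen"` or `"unseen"`.
#' @param seed Default seed used when none is passed to the generators.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(height = 160L, width = 160L, n_animals = 3L,
                         animal_axis_range = c(9, 18),
                         animal_intensity = c(175, 18),
                         background_texture = list(scale = 9L, rgb = c(60, 72, 58), amp = 10),
                         facility_layout = list(
                           list(x1 = 1L, y1 = 30L, x2 = 160L, y2 = 44L, brightness = 235L),
                           list(x1 = 100L, y1 = 1L, x2 = 112L, y2 = 160L, brightness = 215L)
                         ),
                         facility_depth_value = 220L,
                         background_depth_value = 40L,
                         noise_std = 3,
                         env_id = "seen",
                         seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_animals = as.integer(n_animals),
              animal_axis_range = animal_axis_range,
              animal_intensity = animal_intensity,
              background_texture = background_texture,
              facility_layout = facility_layout,
              facility_depth_value = as.integer(facility_depth_value),
              background_depth_value = as.integer(background_depth_value),
              noise_std = noise_std, env_id = env_id, seed = as.integer(seed))
  if (cfg$height <= 0L || cfg$width <= 0L) stop("image dimensions must be positive")
  if (cfg$height %% 4L != 0L || cfg$width %% 4L != 0L) {
    stop("height and width must be divisible by 4")
  }
  if (cfg$facility_depth_value <= cfg$background_depth_value) {
    stop("facility_depth_value must exceed background_depth_value (higher = closer)")
  }
  if (2 * max(cfg$animal_axis_range) >= min(cfg$height, cfg$width)) {
    stop("animals larger than the image: shrink animal_axis_range")
  }
  vals <- c(cfg$animal_intensity[1L], cfg$background_texture$rgb,
            vapply(cfg$facility_layout, function(b) as.double(b$brightness), 0),
            cfg$facility_depth_value, cfg$background_depth_value)
  if (any(vals < 0 | vals > 255)) stop("all intensities must lie in [0, 255]")
  structure(cfg, class = "scene_config")
}

#' Canonical seen / unseen study configurations
#'
#' The `"unseen"` environment shifts the floor color and texture scale and
#' rearranges the facility bars, emulating deployment in a pen the detector
#' was never trained on.
#'
#' @param env `"seen"` or `"unseen"`.
#' @param ... Overrides forwarded to [scene_config()].
#' @return A `scene_config`.
#' @export
example_scene_config <- function(env = c("seen", "unseen"), ...) {
  env <- match.arg(env)
  if (env == "seen") return(scene_config(env_id = "seen", ...))
  scene_config(
    env_id = "unseen",
    background_texture = list(scale = 14L, rgb = c(125, 102, 78), amp = 14),
    facility_layout = list(
      list(x1 = 1L, y1 = 92L, x2 = 160L, y2 = 108L, brightness = 245L),
      list(x1 = 30L, y1 = 1L, x2 = 41L, y2 = 160L, brightness = 225L)
    ),
    ...
  )
}

facility_raster <- function(cfg) {
  f <- matrix(FALSE, cfg$height, cfg$width)
  for (b in cfg$facility_layout) {
    y1 <- max(1L, as.integer(b$y1)); y2 <- min(cfg$height, as.integer(b$y2))
    x1 <- max(1L, as.integer(b$x1)); x2 <- min(cfg$width, as.integer(b$x2))
    if (y1 > y2 || x1 > x2) next  # bar lies outside this image
    f[y1:y2, x1:x2] <- TRUE
  }
  f
}

paint_facility <- function(img, cfg) {
  for (b in cfg$facility_layout) {
    y1 <- max(1L, as.integer(b$y1)); y2 <- min(cfg$height, as.integer(b$y2))
    x1 <- max(1L, as.integer(b$x1)); x2 <- min(cfg$width, as.integer(b$x2))
    if (y1 > y2 || x1 > x2) next
    img[y1:y2, x1:x2, ] <- as.integer(b$brightness)
  }
  img
}

# environment-level products shared by all frames of one camera: textured
# floor, facility raster, and the paired background/depth plates
make_environment <- function(cfg, seed) {
  with_seed(seed, {
    h <- cfg$height; w <- cfg$width
    tex <- blur_box(matrix(stats::rnorm(h * w), h, w), as.integer(cfg$background_texture$scale))
    if (stats::sd(tex) > 0) tex <- tex / stats::sd(tex) * cfg$background_texture$amp
    bg0 <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      layer <- cfg$background_texture$rgb[ch] + tex
      if (cfg$noise_std > 0) layer <- layer + stats::rnorm(h * w, 0, cfg$noise_std)
      bg0[, , ch] <- layer
    }
    bg0 <- as_u8(clamp8(round(bg0)))
    fac <- facility_raster(cfg)
    plate <- paint_facility(bg0, cfg)
    depth <- matrix(as.double(cfg$background_depth_value), h, w)
    depth[fac] <- cfg$facility_depth_value
    if (cfg$noise_std > 0) {
      depth <- depth + stats::rnorm(h * w, 0, cfg$noise_std)
    }
    depth <- as_u8(clamp8(round(depth)))
    list(bg0 = bg0, plate = plate, depth = depth, facility = fac)
  })
}

ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h), h, w) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Fraction of an animal's pixels not covered by facility structures
#'
#' @param animal_pixels Logical (or \{0, 255\}) H x W mask of the animal.
#' @param facility_mask Logical (or \{0, 255\}) H x W facility mask.
#' @return Real in \code{[0, 1]}: visible pixels / total animal pixels.
#' @export
visible_fraction <- function(animal_pixels, facility_mask) {
  a <- animal_pixels > 0
  f <- facility_mask > 0
  if (!all(dim(a) == dim(f))) stop("masks must share dimensions")
  n <- sum(a)
  if (n == 0L) stop("empty animal mask: visible fraction undefined")
  sum(a & !f) / n
}

#' Generate one synthetic pen scene
#'
#' Deterministic for a fixed `(config, seed)`. Animals are drawn beneath the
#' facility structures (facilities occlude animals), and only animals whose
#' visible fraction strictly exceeds 0.2 are kept in the ground truth.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param env Optional precomputed environment (internal; lets a whole
#'   dataset share one background plate, as a static camera would).
#' @return A list of class `synth_scene` with `frame`, `background_plate`,
#'   `depth_plate`, `gt_boxes` (data frame with `x1,y1,x2,y2,
#'   visible_fraction`, half-open 0-based pixel coords), plus the facility
#'   raster and per-animal masks for diagnostics.
#' @export
generate_scene <- function(config, seed = config$seed, env = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(env)) env <- make_environment(config, seed)
  h <- config$height; w <- config$width
  with_seed(derive_seed(seed, 1L), {
    frame <- env$bg0
    masks <- list()
    boxes <- list()
    amax <- max(config$animal_axis_range)
    if (config$n_animals > 0L) {
      for (k in seq_len(config$n_animals)) {
        a <- stats::runif(1, config$animal_axis_range[1L], config$animal_axis_range[2L])
        b <- stats::runif(1, config$animal_axis_range[1L], a)  # minor <= major
        cx <- stats::runif(1, amax + 1, w - amax)
        cy <- stats::runif(1, amax + 1, h - amax)
        th <- stats::runif(1, 0, pi)
        base <- stats::rnorm(1, config$animal_intensity[1L], config$animal_intensity[2L])
        m <- ellipse_mask(h, w, cx, cy, a, b, th)
        npx <- sum(m)
        if (npx == 0L) next
        speckle <- stats::rnorm(npx, 0, 12)
        tint <- c(12, -2, -8)  # pinkish animal hue
        for (ch in 1:3) {
          layer <- frame[, , ch]
          layer[m] <- clamp8(round(base + tint[ch] + speckle))
          frame[, , ch] <- layer
        }
        masks[[length(masks) + 1L]] <- m
      }
    }
    frame <- paint_facility(as_u8(frame), config)
    for (m in masks) {
      vf <- visible_fraction(m, env$facility)
      if (vf > 0.2) {
        ij <- which(m, arr.ind = TRUE)
        boxes[[length(boxes) + 1L]] <- data.frame(
          x1 = min(ij[, 2L]) - 1L, y1 = min(ij[, 1L]) - 1L,
          x2 = max(ij[, 2L]), y2 = max(ij[, 1L]),
          visible_fraction = vf)
      }
    }
    gt <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(x1 = integer(), y1 = integer(), x2 = integer(),
                 y2 = integer(), visible_fraction = numeric())
    structure(list(frame = frame, background_plate = env$plate,
                   depth_plate = env$depth, gt_boxes = gt,
                   facility = env$facility, animal_masks = masks),
              class = "synth_scene")
  })
}

#' Write boxes as YOLO-format labels
#'
#' One line per box: `0 cx cy w h`, center/size normalized to \code{[0, 1]},
#' 6-decimal fixed point, class id 0 (pig).
#'
#' @param boxes Data frame with columns `x1,y1,x2,y2` (half-open pixel coords).
#' @param path Output text file.
#' @param width,height Image size used for normalization.
#' @return Invisibly, `path`.
#' @export
write_yolo_labels <- function(boxes, path, width, height) {
  lines <- character(0)
  if (nrow(boxes)) {
    cx <- (boxes$x1 + boxes$x2) / 2 / width
    cy <- (boxes$y1 + boxes$y2) / 2 / height
    bw <- (boxes$x2 - boxes$x1) / width
    bh <- (boxes$y2 - boxes$y1) / height
    lines <- sprintf("0 %.6f %.6f %.6f %.6f", cx, cy, bw, bh)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels back into pixel-coordinate boxes
#'
#' @param path Label text file.
#' @param width,height Image size used to denormalize.
#' @return Data frame with columns `x1,y1,x2,y2` (continuous pixel coords).
#' @export
read_yolo_labels <- function(path, width, height) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cx <- m[, 2L] * width; cy <- m[, 3L] * height
  bw <- m[, 4L] * width; bh <- m[, 5L] * height
  data.frame(x1 = cx - bw / 2, y1 = cy - bh / 2,
             x2 = cx + bw / 2, y2 = cy + bh / 2)
}

#' Generate a dataset of synthetic frames sharing one static background
#'
#' Writes `n_images` PNG frames with YOLO label files, the shared background
#' plate and depth plate, and a YAML manifest. Per-image seeds are derived
#' deterministically from the master seed.
#'
#' @param config A [scene_config()].
#' @param n_images Number of frames.
#' @param out_dir Output directory (created).
#' @param seed Master seed; defaults to `config$seed`.
#' @param env_seed Seed of the environment-level products (background plate,
#'   depth plate). Two datasets generated with the same `env_seed` and config
#'   share one static background, emulating train/test splits from the same
#'   fixed camera.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(config, n_images, out_dir, seed = config$seed,
                             env_seed = derive_seed(seed, 0L)) {
  stopifnot(inherits(config, "scene_config"), n_images >= 1L)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  env <- make_environment(config, env_seed)
  names_ <- sprintf("frame_%04d", seq_len(n_images))
  for (i in seq_len(n_images)) {
    sc <- generate_scene(config, seed = derive_seed(seed, i), env = env)
    write_frame(sc$frame, file.path(out_dir, "images", paste0(names_[i], ".png")))
    write_yolo_labels(sc$gt_boxes, file.path(out_dir, "labels", paste0(names_[i], ".txt")),
                      config$width, config$height)
  }
  write_frame(env$plate, file.path(out_dir, "background.png"))
  write_gray(env$depth, file.path(out_dir, "depth.png"))
  manifest <- list(env_id = config$env_id, seed = as.integer(seed),
                   n_images = as.integer(n_images),
                   height = config$height, width = config$width,
                   images = as.list(names_))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
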