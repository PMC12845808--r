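# Depth-based facility masking and the image fuser.
#
# Pen infrastructure (feeders, pipes) sits closer to a ceiling- or
# tilted-mounted camera than the floor, so on an 8-bit depth map with
# "higher = closer" the facility separates from the background by a global
# threshold. The facility mask is computed once per environment and painted
# white into both network inputs so facility textures are equalized across
# environments.

#' Facility mask from an 8-bit depth map
#'
#' Applies Otsu's threshold to the depth image (higher values = closer to the
#' camera) and keeps the closer class as the facility. On a uniform depth map
#' the degenerate Otsu convention yields an empty mask, which is a valid state
#' for pens without occluding infrastructure.
#'
#' @param depth H x W matrix in \code{[0, 255]}, higher = closer.
#' @return H x W binary mask (values in \{0, 255\}) marking facility pixels.
#' @export
facility_mask_from_depth <- function(depth) {
  check_gray(depth, "depth")
  t <- otsu_threshold(depth)
  bin <- foreground_mask(depth, t)
  # binarized map is passed through its own >128 gate before use
  as_u8(ifelse(bin > 128, 255L, 0L))
}

#' Paint facility pixels white in a frame
#'
#' Pixels where the facility mask is at least 128 are assigned (255, 255, 255)
#' so the heterogeneous facility appearance is identical in every environment;
#' all other pixels are unchanged.
#'
#' @param frame H x W x 3 frame.
#' @param facility H x W facility mask.
#' @return H x W x 3 integer array.
#' @export
apply_facility_mask <- function(frame, facility) {
  check_frame(frame)
  if (!is_gray(facility)) stop("`facility` must be an H x W matrix")
  if (!same_hw(frame, facility)) stop("`frame` and `facility` dimensions disagree")
  out <- frame
  out[array(facility >= 128, dim(frame))] <- 255L
  as_u8(out)
}

#' Build a per-environment background model
#'
#' Bundles the static-camera preprocessing products for one environment: the
#' background plate, its depth map, and the facility mask derived from the
#' depth map. Built once per camera installation and reused for every frame.
#'
#' @param background H x W x 3 background plate (frame without animals).
#' @param depth H x W depth map, 8-bit, higher = closer. `NULL` declares an
#'   environment with no occluding facility (empty facility mask).
#' @param env_id Character label for the environment.
#' @return An object of class `background_model` with elements `background`,
#'   `depth`, `facility_mask`, `env_id`.
#' @export
build_background_model <- function(background, depth = NULL, env_id = "env") {
  check_frame(background, "background")
  if (is.null(depth)) {
    depth <- matrix(0L, dim(background)[1L], dim(background)[2L])
    fm <- depth
  } else {
    check_gray(depth, "depth")
    if (!same_hw(background, depth)) stop("`background` and `depth` dimensions disagree")
    fm <- facility_mask_from_depth(depth)
  }
  structure(
    list(background = as_u8(background), depth = as_u8(depth),
         facility_mask = as_u8(fm), env_id = as.character(env_id)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  d <- dim(x$background)
  cat(sprintf("Background model for environment '%s'\n", x$env_id))
  cat(sprintf("  plate: %d x %d px; facility pixels: %d (%.1f%%)\n",
              d[1L], d[2L], sum(x$facility_mask == 255L),
              100 * mean(x$facility_mask == 255L)))
  invisible(x)
}

#' Save a background model to a directory
#'
#' Persists the model as `{background.png, depth.png, facility_mask.png,
#' meta.yaml}`.
#'
#' @param model A `background_model`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_background_model <- function(model, dir) {
  stopifnot(inherits(model, "background_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame(model$background, file.path(dir, "background.png"))
  write_gray(model$depth, file.path(dir, "depth.png"))
  write_gray(model$facility_mask, file.path(dir, "facility_mask.png"))
  yaml::write_yaml(list(env_id = model$env_id), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a background model from a directory
#'
#' @param dir Directory written by [save_background_model()].
#' @return A `background_model`.
#' @export
load_background_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  m <- build_background_model(read_frame(file.path(dir, "background.png")),
                              read_gray(file.path(dir, "depth.png")),
                              env_id = meta$env_id)
  # keep the persisted mask rather than recomputing, so a manually edited
  # (e.g. explicitly empty) mask survives the round trip
  m$facility_mask <- read_gray(file.path(dir, "facility_mask.png"))
  m
}

#' Estimate a background plate as the temporal median of a frame stack
#'
#' Fallback background-plate provider for when no clean plate is available:
#' with enough frames, moving animals occupy each pixel a minority of the
#' time and the per-pixel median recovers the static background.
#'
#' @param frames List of H x W x 3 frames.
#' @return H x W x 3 integer array.
#' @export
estimate_background <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  for (f in frames) check_frame(f)
  d <- dim(frames[[1L]])
  stk <- vapply(frames, identity, FUN.VALUE = array(0L, d))
  as_u8(round(apply(stk, 1:3, stats::median)))
}

#' Fuse a frame with its background model into the dual network input
#'
#' Produces the pair of co-registered views consumed by the dual-input stem:
#' the (optionally facility-masked) input frame and the (optionally
#' facility-masked) background-suppressed image. The `difference` input mode
#' feeds the raw difference image (replicated to 3 channels) instead of the
#' background-suppressed image, for ablation.
#'
#' @param frame H x W x 3 frame.
#' @param model A `background_model` with matching dimensions.
#' @param use_fig Apply the facility mask to both views?
#' @param input_mode `"suppressed"` (background-suppressed second view) or
#'   `"difference"` (raw difference image second view).
#' @return A list of class `fused_pair` with elements `input_view` and
#'   `suppressed_view`, both H x W x 3.
#' @export
fuse_inputs <- function(frame, model, use_fig = TRUE,
                        input_mode = c("suppressed", "difference")) {
  check_frame(frame)
  stopifnot(inherits(model, "background_model"))
  if (!all(dim(frame) == dim(model$background))) {
    stop("`frame` and background model dimensions disagree")
  }
  input_mode <- match.arg(input_mode)
  second <- if (input_mode == "suppressed") {
    big_generate(frame, model$background)
  } else {
    d <- difference_image(frame, model$background)
    array(rep(d, 3L), dim = c(dim(d), 3L))
  }
  iv <- frame
  if (isTRUE(use_fig)) {
    iv <- apply_facility_mask(iv, model$facility_mask)
    second <- apply_facility_mask(second, model$facility_mask)
  }
  structure(list(input_view = as_u8(iv), suppressed_view = as_u8(second)),
            class = "fused_pair")
}
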