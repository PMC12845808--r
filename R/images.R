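# Images are plain integer arrays in [0, 255]:
#   frame       H x W x 3 array (RGB)
#   gray image  H x W matrix
#   binary mask H x W matrix with values in {0, 255}

clamp8 <- function(x) {
  x[x < 0] <- 0L
  x[x > 255] <- 255L
  x
}

as_u8 <- function(x) {
  storage.mode(x) <- "integer"
  x
}

is_frame <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L

is_gray <- function(x) (is.matrix(x) || (is.array(x) && length(dim(x)) == 2L))

check_frame <- function(x, arg = "frame") {
  if (!is_frame(x)) stop(sprintf("`%s` must be an H x W x 3 array", arg))
  rng <- range(x)
  if (rng[1L] < 0 || rng[2L] > 255) stop(sprintf("`%s` has values outside [0, 255]", arg))
  invisible(x)
}

check_gray <- function(x, arg = "image") {
  if (!is_gray(x)) stop(sprintf("`%s` must be an H x W matrix", arg))
  if (length(x) == 0L) stop(sprintf("`%s` is empty", arg))
  rng <- range(x)
  if (rng[1L] < 0 || rng[2L] > 255) stop(sprintf("`%s` has values outside [0, 255]", arg))
  invisible(x)
}

check_mask <- function(x, arg = "mask") {
  if (!is_gray(x)) stop(sprintf("`%s` must be an H x W matrix", arg))
  if (!all(x == 0L | x == 255L)) stop(sprintf("`%s` must only contain 0 and 255", arg))
  invisible(x)
}

same_hw <- function(a, b) {
  all(dim(a)[1:2] == dim(b)[1:2])
}

#' Read an 8-bit RGB frame from a PNG file
#'
#' @param path Path to a PNG image.
#' @return An H x W x 3 integer array with values in \code{[0, 255]}.
#' @export
read_frame <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  as_u8(round(px * 255))
}

#' Write an 8-bit RGB frame to a PNG file
#'
#' @param frame H x W x 3 array in \code{[0, 255]}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_frame <- function(frame, path) {
  check_frame(frame)
  png::writePNG(frame / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale image (e.g. a depth map or mask) from PNG
#'
#' @param path Path to a PNG image.
#' @return An H x W integer matrix with values in \code{[0, 255]}.
#' @export
read_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  as_u8(round(px * 255))
}

#' Write an 8-bit grayscale image to PNG
#'
#' @param gray H x W matrix in \code{[0, 255]}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gray <- function(gray, path) {
  check_gray(gray)
  png::writePNG(gray / 255, path)
  invisible(path)
}

#' Convert an RGB frame to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luma weights.
#'
#' @param frame H x W x 3 array in \code{[0, 255]}.
#' @return H x W integer matrix.
#' @export
rgb_to_gray <- function(frame) {
  check_frame(frame)
  g <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
  as_u8(round(g))
}
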