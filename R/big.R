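# Background-suppressed image generation.
#
# A per-environment background plate (obtained once, when the camera is
# installed) is differenced against each incoming frame; Otsu's method on the
# difference image separates foreground from background, and background pixels
# are zeroed while foreground pixels keep their original texture.

#' Absolute difference image between a frame and its background plate
#'
#' Computes the per-pixel, per-channel absolute difference in widened integer
#' arithmetic (no 8-bit wraparound) and reduces the three channels to one by
#' taking the per-pixel channel maximum, so a strong change in any single
#' channel survives the reduction.
#'
#' @param input H x W x 3 frame in \code{[0, 255]}.
#' @param background H x W x 3 background plate, same shape as `input`.
#' @return H x W integer matrix in \code{[0, 255]}.
#' @export
difference_image <- function(input, background) {
  check_frame(input, "input")
  check_frame(background, "background")
  if (!all(dim(input) == dim(background))) {
    stop("`input` and `background` must have identical dimensions")
  }
  d <- abs(array(as.double(input), dim(input)) - as.double(background))
  as_u8(pmax(d[, , 1L], d[, , 2L], d[, , 3L]))
}

#' Otsu's threshold over the 256-bin histogram of an 8-bit image
#'
#' Returns the threshold \code{t} maximizing the between-class variance
#' \code{w0 * w1 * (mu0 - mu1)^2}, where the background class is \code{<= t}
#' and the foreground class is \code{> t}. Ties are broken towards the
#' smallest maximizing \code{t}. A constant image returns its single value,
#' so the foreground is empty.
#'
#' @param gray H x W matrix in \code{[0, 255]}.
#' @return Integer threshold in \code{[0, 255]}.
#' @export
otsu_threshold <- function(gray) {
  check_gray(gray)
  v <- as.integer(gray)
  if (min(v) == max(v)) return(min(v))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  p <- h / n
  lev <- 0:255
  w0 <- cumsum(p)                # weight of class {0..t}
  m0 <- cumsum(p * lev)          # unnormalized class-0 mean
  mt <- m0[256L]                 # global mean
  w1 <- 1 - w0
  # between-class variance for t = 0..255; 0 where a class is empty
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  sb <- ifelse(den > 0, num / den, 0)
  which.max(sb) - 1L             # which.max takes the first (smallest t) tie
}

#' Binary foreground mask from a grayscale image and a threshold
#'
#' @param gray H x W matrix in \code{[0, 255]}.
#' @param t Threshold in \code{[0, 255]}; pixels strictly greater than `t`
#'   become foreground (255), the rest background (0).
#' @return H x W integer matrix with values in \{0, 255\}.
#' @export
foreground_mask <- function(gray, t) {
  check_gray(gray)
  stopifnot(length(t) == 1L, t >= 0, t <= 255)
  as_u8(ifelse(gray > t, 255L, 0L))
}

#' Apply a foreground mask to a frame, zeroing background pixels
#'
#' Pixels whose mask value is at least 128 keep their original RGB values;
#' all other pixels are set to (0, 0, 0).
#'
#' @param input H x W x 3 frame.
#' @param mask H x W mask; treated as foreground where \code{>= 128}.
#' @return H x W x 3 integer array.
#' @export
suppress_background <- function(input, mask) {
  check_frame(input, "input")
  if (!is_gray(mask)) stop("`mask` must be an H x W matrix")
  if (!same_hw(input, mask)) stop("`input` and `mask` dimensions disagree")
  keep <- mask >= 128
  out <- input
  out[!array(keep, dim(input))] <- 0L
  as_u8(out)
}

#' Generate a background-suppressed image
#'
#' Full per-frame pipeline: absolute difference against the background plate,
#' Otsu threshold on the difference image, binarize, and suppress background
#' pixels of the original frame. The background plate itself comes from the
#' one-time static-camera preprocessing phase; only this composition runs per
#' frame.
#'
#' @param input H x W x 3 frame.
#' @param background H x W x 3 background plate.
#' @return H x W x 3 integer array: the background-suppressed image.
#' @export
big_generate <- function(input, background) {
  d <- difference_image(input, background)
  t <- otsu_threshold(d)
  m <- foreground_mask(d, t)
  suppress_background(input, m)
}
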