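# Independent oracles used across the suite. These deliberately share no
# code with the package internals: plain loops and exhaustive searches.

# exhaustive Otsu: argmax of between-class variance over all 256 thresholds,
# smallest maximizing t, foreground strictly greater than t
otsu_bruteforce <- function(gray) {
  v <- as.integer(gray)
  if (min(v) == max(v)) return(min(v))
  best_t <- 0L
  best_s <- -1
  n <- length(v)
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# maximum one-to-one assignment TP count by recursion over detections
max_matching_tp <- function(iou, thr) {
  nd <- nrow(iou); ng <- ncol(iou)
  if (nd == 0L || ng == 0L) return(0L)
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)  # leave detection i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && iou[i, j] >= thr) {
        u <- used; u[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, u))
      }
    }
    best
  }
  rec(1L, logical(ng))
}

random_boxes <- function(n, size = 100) {
  if (n == 0L) {
    return(data.frame(x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  x1 <- runif(n, 0, size - 12)
  y1 <- runif(n, 0, size - 12)
  w <- runif(n, 6, 30)
  h <- runif(n, 6, 30)
  data.frame(x1 = x1, y1 = y1, x2 = pmin(size, x1 + w), y2 = pmin(size, y1 + h))
}

random_frame <- function(h = 8, w = 8) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

tiny_scene_config <- function(...) {
  example_scene_config("seen", height = 64, width = 64, n_animals = 2,
                       animal_axis_range = c(5, 9),
                       facility_layout = list(
                         list(x1 = 1, y1 = 12, x2 = 64, y2 = 18, brightness = 235)
                       ), ...)
}
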