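# Detection evaluation: IoU, confidence-ordered one-to-one matching,
# precision/recall/F1, and all-point-interpolated AP50.
#
# Boxes live in continuous half-open pixel coordinates (x1, y1, x2, y2) with
# the origin at the top-left, so areas are (x2 - x1) * (y2 - y1) with no
# off-by-one ambiguity.

#' Intersection over union of two axis-aligned boxes
#'
#' @param b,g Numeric length-4 vectors `(x1, y1, x2, y2)` with `x2 > x1`,
#'   `y2 > y1`.
#' @return IoU in \code{[0, 1]}.
#' @export
box_iou <- function(b, g) {
  if (b[3L] <= b[1L] || b[4L] <= b[2L] || g[3L] <= g[1L] || g[4L] <= g[2L]) {
    stop("degenerate (zero-area) box")
  }
  iw <- min(b[3L], g[3L]) - max(b[1L], g[1L])
  ih <- min(b[4L], g[4L]) - max(b[2L], g[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (b[3L] - b[1L]) * (b[4L] - b[2L]) +
    (g[3L] - g[1L]) * (g[4L] - g[2L]) - inter
  inter / union
}

iou_matrix <- function(dets, gts) {
  m <- matrix(0, nrow(dets), nrow(gts))
  for (i in seq_len(nrow(dets))) {
    for (j in seq_len(nrow(gts))) {
      m[i, j] <- box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                         as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
    }
  }
  m
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties broken by input
#' order); each is matched to the still-unmatched ground-truth box of highest
#' IoU, provided that IoU reaches the threshold. Unmatched detections are
#' false positives; unmatched ground-truth boxes are false negatives.
#'
#' @param dets Data frame with columns `x1,y1,x2,y2,confidence`.
#' @param gts Data frame with columns `x1,y1,x2,y2`.
#' @param iou_thr Match threshold in `(0, 1]`, default 0.5.
#' @return List of class `match_result` with `TP`, `FP`, `FN` and
#'   `matched_pairs` (data frame `det`, `gt`, `iou`, indices in input order).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr <= 1)
  nd <- nrow(dets); ng <- nrow(gts)
  pairs <- data.frame(det = integer(), gt = integer(), iou = numeric())
  if (nd > 0L && ng > 0L) {
    ord <- order(-dets$confidence, seq_len(nd))
    iom <- iou_matrix(dets, gts)
    taken <- logical(ng)
    for (i in ord) {
      ious <- iom[i, ]
      ious[taken] <- -1
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        taken[j] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, gt = j, iou = ious[j]))
      }
    }
  }
  structure(list(TP = nrow(pairs), FP = nd - nrow(pairs),
                 FN = ng - nrow(pairs), matched_pairs = pairs),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' Ratios with the 0/0 -> 0 convention; F1 is the harmonic mean of precision
#' and recall (0 when both are 0).
#'
#' @param m A `match_result` from [match_detections()].
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(m) {
  p <- if (m$TP + m$FP > 0) m$TP / (m$TP + m$FP) else 0
  r <- if (m$TP + m$FN > 0) m$TP / (m$TP + m$FN) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision at IoU 0.5 with all-point interpolation
#'
#' Sweeps the detections in descending confidence, accumulating TP/FP against
#' the greedy one-to-one matching, forms the precision-recall curve, applies
#' the all-point interpolation `p_interp(r) = max{ p(r') : r' >= r }` and
#' integrates over the distinct recall levels.
#'
#' @param dets Data frame `x1,y1,x2,y2,confidence`; may span several images
#'   when `image` columns are present in both inputs (matching is then done
#'   per image).
#' @param gts Nonempty data frame `x1,y1,x2,y2` (plus optional `image`).
#' @param iou_thr Match threshold, default 0.5.
#' @return List of class `eval_report` with `ap50`, `precision`, `recall`,
#'   `f1` (at the full detection set) and the `pr_curve` data frame.
#' @export
ap50 <- function(dets, gts, iou_thr = 0.5) {
  if (nrow(gts) == 0L) stop("AP is undefined without ground-truth boxes")
  if (is.null(dets$image)) dets$image <- rep("img", nrow(dets))
  if (is.null(gts$image)) gts$image <- rep("img", nrow(gts))
  # flag each detection TP/FP at this threshold via per-image greedy matching
  dets$._id <- seq_len(nrow(dets))
  tp_flag <- logical(nrow(dets))
  for (img in unique(dets$image)) {
    d <- dets[dets$image == img, , drop = FALSE]
    g <- gts[gts$image == img, , drop = FALSE]
    if (nrow(g) == 0L || nrow(d) == 0L) next
    m <- match_detections(d, g, iou_thr)
    if (nrow(m$matched_pairs)) tp_flag[d$._id[m$matched_pairs$det]] <- TRUE
  }
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  tp_c <- cumsum(tp_flag[ord])
  fp_c <- cumsum(!tp_flag[ord])
  ng <- nrow(gts)
  rec <- tp_c / ng
  prec <- tp_c / (tp_c + fp_c)
  ap <- 0
  if (length(rec)) {
    # all-point interpolation: running max of precision from the right
    pint <- rev(cummax(rev(prec)))
    r_prev <- 0
    for (k in seq_along(rec)) {
      if (rec[k] > r_prev) {
        ap <- ap + (rec[k] - r_prev) * pint[k]
        r_prev <- rec[k]
      }
    }
  }
  mm <- list(TP = sum(tp_flag), FP = sum(!tp_flag), FN = ng - sum(tp_flag))
  prf <- precision_recall_f1(structure(mm, class = "match_result"))
  structure(list(ap50 = ap, precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
                 pr_curve = data.frame(recall = rec, precision = prec)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AP50 %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$ap50, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Write detections to the minimal JSON interchange format
#'
#' @param dets Data frame `image,x1,y1,x2,y2,confidence`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_detections_json <- function(dets, path) {
  recs <- lapply(seq_len(nrow(dets)), function(i) {
    list(image = dets$image[i], x1 = dets$x1[i], y1 = dets$y1[i],
         x2 = dets$x2[i], y2 = dets$y2[i], score = dets$confidence[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from the minimal JSON interchange format
#'
#' @param path JSON file written by [write_detections_json()].
#' @return Data frame `image,x1,y1,x2,y2,confidence`.
#' @export
read_detections_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0L) {
    return(data.frame(image = character(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), confidence = numeric()))
  }
  data.frame(image = x$image, x1 = x$x1, y1 = x$y1, x2 = x$x2, y2 = x$y2,
             confidence = x$score)
}
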