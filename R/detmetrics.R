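# Detection post-processing and evaluation: greedy per-class NMS, greedy
# confidence-ordered matching, precision/recall/F1, interpolated AP, mAP50,
# mAP50-95 and confusion matrices.
#
# A detection set for one image is a data.frame with columns
# x1, y1, x2, y2 (corner coordinates, pixels, half-open intervals),
# score in [0,1] and class (integer id, 0-based). Ground truth uses the same
# columns without score.

#' Pairwise IoU between two sets of corner-format boxes
#'
#' @param a,b Matrices (n x 4 and m x 4) of (x1, y1, x2, y2).
#' @return n x m matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4); b <- matrix(as.numeric(b), ncol = 4)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(aa, ab, "+") - inter)
}

#' Greedy per-class non-maximum suppression
#'
#' Within each class, detections are taken in order of decreasing score; a
#' box is kept if its IoU with every already-kept box of that class is at or
#' below `iou_thr`. Score ties are broken by original box index (lower index
#' first) for determinism. Detections below `conf_thr` are dropped first.
#'
#' @param det Detection data.frame (columns x1, y1, x2, y2, score, class).
#' @param conf_thr Confidence threshold (default 0.25).
#' @param iou_thr IoU suppression threshold (default 0.45).
#' @return Filtered detection data.frame, sorted by decreasing score.
#' @export
nms_postprocess <- function(det, conf_thr = 0.25, iou_thr = 0.45) {
  if (nrow(det) == 0L) return(det)
  stopifnot(all(det$score >= 0), all(det$score <= 1))
  det <- det[det$score >= conf_thr, , drop = FALSE]
  if (nrow(det) == 0L) return(det)
  keep_all <- logical(nrow(det))
  for (cl in unique(det$class)) {
    idx <- which(det$class == cl)
    ord <- idx[order(-det$score[idx], idx)]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0L) { kept <- i; keep_all[i] <- TRUE; next }
      ious <- iou_matrix(as.matrix(det[i, 1:4]), as.matrix(det[kept, 1:4]))
      if (all(ious <= iou_thr)) { kept <- c(kept, i); keep_all[i] <- TRUE }
    }
  }
  out <- det[keep_all, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]   # stable: ties keep original order
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per class across an image set: detections are
#' processed in order of decreasing confidence; each is matched to the
#' unmatched ground-truth box of the same class and image with the highest
#' IoU, provided that IoU >= `iou_thr`. Unmatched detections are false
#' positives, unmatched truths false negatives.
#'
#' @param preds List of detection data.frames (one per image).
#' @param truths List of truth data.frames (columns x1, y1, x2, y2, class).
#' @param iou_thr Matching IoU threshold.
#' @param nc Number of classes.
#' @return List with `tally` (data.frame class/TP/FP/FN) and `records`
#'   (per-detection data.frame with score, class, matched flag) for PR
#'   curves.
#' @export
match_detections <- function(preds, truths, iou_thr = 0.5, nc = 5L) {
  stopifnot(length(preds) == length(truths))
  recs <- list()
  fn_count <- integer(nc)
  gt_count <- integer(nc)
  for (im in seq_along(preds)) {
    p <- preds[[im]]; g <- truths[[im]]
    for (cl in 0:(nc - 1L)) {
      gi <- which(g$class == cl)
      gt_count[cl + 1L] <- gt_count[cl + 1L] + length(gi)
      pi_ <- which(p$class == cl)
      if (length(pi_) == 0L) next
      pi_ <- pi_[order(-p$score[pi_])]
      taken <- logical(length(gi))
      matched <- logical(length(pi_))
      if (length(gi) > 0L) {
        iom <- iou_matrix(as.matrix(p[pi_, 1:4]), as.matrix(g[gi, 1:4]))
        for (k in seq_along(pi_)) {
          free <- which(!taken)
          if (length(free) == 0L) break
          j <- free[which.max(iom[k, free])]
          if (iom[k, j] >= iou_thr) { taken[j] <- TRUE; matched[k] <- TRUE }
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        score = p$score[pi_], class = cl, matched = matched)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
  else data.frame(score = numeric(0), class = integer(0), matched = logical(0))
  tp <- fp <- integer(nc)
  for (cl in 0:(nc - 1L)) {
    rc <- records[records$class == cl, , drop = FALSE]
    tp[cl + 1L] <- sum(rc$matched)
    fp[cl + 1L] <- sum(!rc$matched)
  }
  tally <- data.frame(class = 0:(nc - 1L), TP = tp, FP = fp,
                      FN = gt_count - tp, support = gt_count)
  list(tally = tally, records = records)
}

#' Precision and recall from a tally
#'
#' `P = TP / (TP + FP) * 100`, `R = TP / (TP + FN) * 100`. A zero denominator
#' yields 0 with `zero_div` flagged.
#'
#' @param tally Data.frame with TP, FP, FN columns (or a one-row version).
#' @return List with `precision`, `recall` (percent) and `zero_div` flag.
#' @export
precision_recall <- function(tally) {
  tp <- sum(tally$TP); fp <- sum(tally$FP); fn <- sum(tally$FN)
  zd <- FALSE
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else { zd <- TRUE; 0 }
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else { zd <- TRUE; 0 }
  list(precision = p, recall = r, zero_div = zd)
}

#' F1 score
#'
#' Harmonic mean of precision and recall (inputs and output in percent).
#'
#' @param p,r Precision and recall in percent.
#' @return F1 in percent; 0 when both inputs are 0.
#' @export
f1_score <- function(p, r) {
  if (p + r <= 0) return(0)
  2 * p * r / (p + r)
}

#' Average precision from match records of one class
#'
#' Area under the precision-recall curve swept over descending confidence,
#' using 101-point monotone-envelope interpolation.
#'
#' @param records Data.frame with `score` and `matched` for one class.
#' @param n_gt Number of ground-truth instances of the class.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(records, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (nrow(records) == 0L) return(0)
  ord <- order(-records$score)
  tp <- cumsum(records$matched[ord])
  fp <- cumsum(!records$matched[ord])
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  # monotone envelope, 101 recall points
  rp <- seq(0, 1, by = 0.01)
  env <- rev(cummax(rev(prec)))
  ap <- 0
  for (r0 in rp) {
    i <- which(rec >= r0)
    ap <- ap + (if (length(i)) env[i[1]] else 0)
  }
  ap / length(rp)
}

#' Mean average precision over classes
#'
#' @param per_class_ap Numeric vector of per-class AP values (NA entries,
#'   from classes absent in the ground truth, are dropped).
#' @return Unweighted mean AP.
#' @export
mean_ap <- function(per_class_ap) {
  mean(per_class_ap[!is.na(per_class_ap)])
}

#' Detection mAP at one or several IoU thresholds
#'
#' @param preds,truths Lists of per-image data.frames (see
#'   [match_detections()]).
#' @param iou_thrs IoU thresholds; `0.5` gives mAP50, `seq(0.5, 0.95, 0.05)`
#'   gives mAP50-95.
#' @param nc Number of classes.
#' @return List with `map` (mean over classes and thresholds), `per_class`
#'   (AP matrix, thresholds x classes) and `map_per_thr`.
#' @export
detection_map <- function(preds, truths, iou_thrs = 0.5, nc = 5L) {
  apm <- matrix(NA_real_, length(iou_thrs), nc)
  for (t in seq_along(iou_thrs)) {
    m <- match_detections(preds, truths, iou_thrs[t], nc)
    for (cl in 0:(nc - 1L)) {
      rc <- m$records[m$records$class == cl, , drop = FALSE]
      apm[t, cl + 1L] <- average_precision(rc, m$tally$support[cl + 1L])
    }
  }
  per_thr <- apply(apm, 1, function(z) mean(z[!is.na(z)]))
  list(map = mean(per_thr), per_class = apm, map_per_thr = per_thr)
}

#' Confusion matrix of a detector
#'
#' Rows are predicted classes plus a background row; columns are true classes
#' plus a background column. Detections above `conf_thr` are matched per
#' class-agnostic IoU >= `iou_thr` (greedy, by confidence); a matched pair
#' increments (pred class, true class); unmatched detections fall in the
#' background column, unmatched truths in the background row's cell of their
#' class.
#'
#' @param preds,truths Per-image lists as in [match_detections()].
#' @param nc Number of classes.
#' @param conf_thr,iou_thr Confidence and IoU thresholds.
#' @return (nc+1) x (nc+1) integer matrix; last row/column = background.
#' @export
confusion_matrix <- function(preds, truths, nc = 5L, conf_thr = 0.25,
                             iou_thr = 0.45) {
  cm <- matrix(0L, nc + 1L, nc + 1L,
               dimnames = list(pred = c(0:(nc - 1L), "bg"),
                               true = c(0:(nc - 1L), "bg")))
  for (im in seq_along(preds)) {
    p <- preds[[im]]
    p <- p[p$score >= conf_thr, , drop = FALSE]
    g <- truths[[im]]
    taken <- logical(nrow(g))
    if (nrow(p) > 0L) {
      ord <- order(-p$score)
      iom <- if (nrow(g) > 0L)
        iou_matrix(as.matrix(p[, 1:4]), as.matrix(g[, 1:4]))
      else matrix(0, nrow(p), 0)
      for (k in ord) {
        j <- 0L
        if (nrow(g) > 0L) {
          free <- which(!taken)
          if (length(free) > 0L) {
            jj <- free[which.max(iom[k, free])]
            if (iom[k, jj] >= iou_thr) j <- jj
          }
        }
        if (j > 0L) {
          taken[j] <- TRUE
          cm[p$class[k] + 1L, g$class[j] + 1L] <- cm[p$class[k] + 1L, g$class[j] + 1L] + 1L
        } else {
          cm[p$class[k] + 1L, nc + 1L] <- cm[p$class[k] + 1L, nc + 1L] + 1L
        }
      }
    }
    if (nrow(g) > 0L) for (j in which(!taken))
      cm[nc + 1L, g$class[j] + 1L] <- cm[nc + 1L, g$class[j] + 1L] + 1L
  }
  cm
}
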