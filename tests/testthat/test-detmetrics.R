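# Matching, precision/recall/F1, AP and confusion matrices.

mk_truth <- function(boxes, classes) {
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], class = classes)
}
mk_det <- function(boxes, classes, scores) {
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], score = scores, class = classes)
}

test_that("matching reproduces perfect, empty and oracle-checked tallies", {
  b <- cbind(c(0, 20, 40), c(0, 20, 40), c(10, 30, 50), c(10, 30, 50))
  tr <- list(mk_truth(b, c(0L, 1L, 1L)))
  pd <- list(mk_det(b, c(0L, 1L, 1L), c(0.9, 0.8, 0.7)))
  m <- match_detections(pd, tr, 0.5, nc = 2L)
  expect_equal(sum(m$tally$TP), 3L)
  expect_equal(sum(m$tally$FP), 0L)
  expect_equal(sum(m$tally$FN), 0L)

  m0 <- match_detections(list(mk_det(b[0, , drop = FALSE], integer(0),
                                     numeric(0))), tr, 0.5, nc = 2L)
  expect_equal(sum(m0$tally$FN), 3L)

  # greedy tally equals the exhaustive maximum one-to-one assignment when
  # objects are well separated (each detection overlaps at most one truth)
  max_matching <- function(iom, thr = 0.5) {
    np <- nrow(iom); ng <- ncol(iom)
    best <- 0L
    recurse <- function(k, used, cnt) {
      if (k > np) { best <<- max(best, cnt); return(invisible(NULL)) }
      recurse(k + 1L, used, cnt)                      # leave pred k unmatched
      for (j in seq_len(ng))
        if (!used[j] && iom[k, j] >= thr) {
          used[j] <- TRUE
          recurse(k + 1L, used, cnt + 1L)
          used[j] <- FALSE
        }
    }
    recurse(1L, logical(ng), 0L)
    best
  }
  set.seed(41)
  for (rep in 1:20) {
    ng <- sample(2:4, 1)
    centers <- cbind(20 * seq_len(ng), 20 * sample(seq_len(ng)))
    gt <- cbind(centers[, 1] - 5, centers[, 2] - 5,
                centers[, 1] + 5, centers[, 2] + 5)
    hit <- sample(ng, sample(1:ng, 1))               # detected subset
    pr <- gt[hit, , drop = FALSE] + runif(4 * length(hit), -1, 1)
    far <- cbind(200, 200, 212, 212)                 # a clear false positive
    pr <- rbind(pr, far)
    tr1 <- list(mk_truth(gt, rep(0L, ng)))
    pd1 <- list(mk_det(pr, rep(0L, nrow(pr)), runif(nrow(pr))))
    got <- sum(match_detections(pd1, tr1, 0.5, nc = 1L)$tally$TP)
    expect_equal(got, max_matching(iou_matrix(pr, gt)))
    expect_equal(got, length(hit))
  }
})

test_that("precision, recall and F1 follow the printed formulas", {
  t1 <- data.frame(TP = 8L, FP = 2L, FN = 2L)
  pr <- precision_recall(t1)
  expect_equal(pr$precision, 80)
  expect_equal(pr$recall, 80)
  expect_equal(f1_score(80, 80), 80)

  pr2 <- precision_recall(data.frame(TP = 5L, FP = 0L, FN = 0L))
  expect_equal(pr2$precision, 100)
  expect_equal(pr2$recall, 100)

  pr3 <- precision_recall(data.frame(TP = 0L, FP = 3L, FN = 0L))
  expect_equal(pr3$precision, 0)
  expect_true(pr3$zero_div)

  expect_equal(f1_score(100, 0), 0)
  # direct harmonic-mean evaluation on the headline operating point
  expect_equal(f1_score(86.76, 79.94), 83.21, tolerance = 5e-3)
  # F1 never exceeds the arithmetic mean
  set.seed(42)
  for (i in 1:50) {
    p <- runif(1, 0, 100); r <- runif(1, 0, 100)
    expect_lte(f1_score(p, r), (p + r) / 2 + 1e-12)
  }
})

test_that("AP matches hand-enumerated step functions and degrades monotonically", {
  # perfect detector
  rec <- data.frame(score = c(0.9, 0.8), matched = c(TRUE, TRUE))
  expect_equal(average_precision(rec, 2L), 1)

  # 3 detections, one interleaved FP, 2 truths:
  # sweep: TP(0.9) -> P=1, R=0.5; FP(0.8) -> P=0.5; TP(0.7) -> P=2/3, R=1
  # 101-point envelope: P=1 for r<=0.5, P=2/3 above
  rec <- data.frame(score = c(0.9, 0.8, 0.7),
                    matched = c(TRUE, FALSE, TRUE))
  got <- average_precision(rec, 2L)
  expected <- (51 * 1 + 50 * 2 / 3) / 101
  expect_equal(got, expected, tolerance = 1e-12)

  # deleting a true positive never increases AP
  rec2 <- rec[-1, ]
  expect_lte(average_precision(rec2, 2L), got)

  # mAP is the unweighted mean of per-class APs
  expect_equal(mean_ap(c(0.794, 0.628, 0.989, 0.989, 0.853)),
               mean(c(0.794, 0.628, 0.989, 0.989, 0.853)))
  expect_true(all(c(got, expected) >= 0 & c(got, expected) <= 1))
})

test_that("confusion matrices place mass on the diagonal, background and swaps", {
  b <- cbind(c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  tr <- list(mk_truth(b, c(0L, 1L)))
  pd <- list(mk_det(b, c(0L, 1L), c(0.9, 0.9)))
  cm <- confusion_matrix(pd, tr, nc = 2L)
  expect_equal(diag(cm)[1:2], c(`0` = 1L, `1` = 1L))
  expect_equal(sum(cm), 2)

  cm0 <- confusion_matrix(list(pd[[1]][0, ]), tr, nc = 2L)
  expect_equal(sum(cm0[3, 1:2]), 2)        # all truths unmatched -> bg row
  expect_equal(sum(cm0), 2)

  pd_swap <- list(mk_det(b, c(1L, 0L), c(0.9, 0.9)))
  cm_swap <- confusion_matrix(pd_swap, tr, nc = 2L)
  expect_equal(cm_swap[2, 1], 1L)          # predicted 1, true 0
  expect_equal(cm_swap[1, 2], 1L)
  expect_equal(sum(diag(cm_swap)[1:2]), 0L)
})
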