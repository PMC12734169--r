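# Bounding-box regression losses: IoU, Wise-IoU v1 and Wise-IoU v3 with the
# dynamic non-monotonic focusing mechanism.
#
# Boxes are stored in center format (cx, cy, w, h) as numeric vectors or
# n x 4 matrices; width and height must be positive. Geometry is continuous
# (no pixel quantisation). The focusing mechanism rates each anchor by its
# outlier degree beta = L_IoU / mean(L_IoU), where the mean is an exponential
# moving average maintained outside the gradient path; the gradient gain
# gamma(beta) = beta / (delta * alpha^(beta - delta)) rises and then falls,
# so that anchors of average quality receive the largest gain while
# low-quality (high-beta) anchors are damped.

.as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop("boxes must have 4 columns (cx, cy, w, h)")
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (any(b[, 3] <= 0) || any(b[, 4] <= 0))
    stop("box width and height must be positive")
  b
}

.corners <- function(b) {
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' Intersection over union of box pairs
#'
#' @param pred,gt Boxes in center format (cx, cy, w, h): vectors of length 4
#'   or n x 4 matrices (rows are paired).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(pred, gt) {
  p <- .as_box_matrix(pred); g <- .as_box_matrix(gt)
  pc <- .corners(p); gc <- .corners(g)
  iw <- pmax(0, pmin(pc[, 3], gc[, 3]) - pmax(pc[, 1], gc[, 1]))
  ih <- pmax(0, pmin(pc[, 4], gc[, 4]) - pmax(pc[, 2], gc[, 2]))
  inter <- iw * ih
  union <- p[, 3] * p[, 4] + g[, 3] * g[, 4] - inter
  unname(inter / union)
}

#' Wise-IoU distance attention term
#'
#' `RWIoU = exp(((cx - cx_gt)^2 + (cy - cy_gt)^2) / (Wg^2 + Hg^2))`, where
#' `Wg`, `Hg` are the sides of the smallest box enclosing the pair. The
#' denominator is treated as a constant in gradient computations (detached),
#' which this value-level function does not need to represent. For centers
#' inside the enclosure the value lies in `[1, e)`.
#'
#' @inheritParams box_iou
#' @return Numeric vector of attention factors (>= 1).
#' @export
rwiou <- function(pred, gt) {
  p <- .as_box_matrix(pred); g <- .as_box_matrix(gt)
  pc <- .corners(p); gc <- .corners(g)
  wg <- pmax(pc[, 3], gc[, 3]) - pmin(pc[, 1], gc[, 1])
  hg <- pmax(pc[, 4], gc[, 4]) - pmin(pc[, 2], gc[, 2])
  if (any(wg <= 0) || any(hg <= 0)) stop("degenerate enclosing box")
  d2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  unname(exp(d2 / (wg^2 + hg^2)))
}

#' Wise-IoU v1 loss
#'
#' `L = RWIoU * (1 - IoU)`: the distance attention amplifies the IoU loss of
#' anchors whose centers are far from the target.
#'
#' @inheritParams box_iou
#' @return Numeric vector of losses in `[0, e)`.
#' @export
wiou_v1 <- function(pred, gt) {
  rwiou(pred, gt) * (1 - box_iou(pred, gt))
}

#' Focusing parameters of the non-monotonic gain mapping
#'
#' @param alpha Gain decay base (> 1); default 1.9.
#' @param delta Gain pivot (> 0); default 3. `gamma(delta) = 1` exactly.
#' @return List of class `pd_focusing`.
#' @export
focusing_params <- function(alpha = 1.9, delta = 3) {
  if (alpha <= 0) stop("focusing configuration error: alpha must be positive")
  if (delta <= 0) stop("focusing configuration error: delta must be positive")
  structure(list(alpha = alpha, delta = delta), class = "pd_focusing")
}

#' Non-monotonic focusing coefficient
#'
#' `gamma(beta) = beta / (delta * alpha^(beta - delta))`. The mapping
#' increases, peaks at `beta = 1 / log(alpha)`, then decays to zero; at
#' `beta = delta` it equals 1 exactly.
#'
#' @param beta Outlier degree (>= 0), vectorised.
#' @param fp Parameters from [focusing_params()].
#' @return Positive numeric vector of gradient gains.
#' @export
focusing_gamma <- function(beta, fp = focusing_params()) {
  if (any(beta < 0)) stop("outlier degree beta must be nonnegative")
  unname(beta / (fp$delta * fp$alpha^(beta - fp$delta)))
}

#' Running-mean state of the outlier normaliser
#'
#' Holds the exponential moving average of the IoU loss that the dynamic
#' focusing mechanism divides by. Updated outside the gradient path; warm
#' started from the first observed batch mean.
#'
#' @param momentum Smoothing factor m in `[0, 1)`; the mean moves by
#'   `(1 - m)` toward each new batch mean.
#' @return Environment of class `pd_outlier_state`.
#' @export
outlier_state <- function(momentum = 0.99) {
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  e <- new.env(parent = emptyenv())
  e$l_mean <- NULL
  e$momentum <- momentum
  class(e) <- "pd_outlier_state"
  e
}

#' Wise-IoU v3 loss with dynamic non-monotonic focusing
#'
#' Per pair: `beta = L_IoU / l_mean` (no gradient through beta), loss =
#' `gamma(beta) * RWIoU * L_IoU`. After the losses are computed the running
#' mean is updated with the batch mean of `L_IoU`:
#' `l_mean <- m * l_mean + (1 - m) * mean(L_IoU)`. An uninitialised state is
#' warm-started at the current batch mean (so the first batch has beta
#' centred at 1).
#'
#' @inheritParams box_iou
#' @param state State from [outlier_state()]; updated in place and returned.
#' @param fp Parameters from [focusing_params()].
#' @return List with `loss` (numeric vector), `beta`, `gamma` and `state`.
#' @export
wiou_v3 <- function(pred, gt, state = outlier_state(),
                    fp = focusing_params()) {
  liou <- 1 - box_iou(pred, gt)
  lm <- state$l_mean %||% mean(liou)
  if (lm <= 0) lm <- max(mean(liou), 1e-8)
  beta <- liou / lm
  gam <- focusing_gamma(beta, fp)
  loss <- gam * rwiou(pred, gt) * liou
  state$l_mean <- (state$momentum * lm + (1 - state$momentum) * mean(liou))
  list(loss = loss, beta = beta, gamma = gam, state = state)
}

# ---- analytic gradients for training ---------------------------------------

# d(IoU)/d(pred cx,cy,w,h) and helper quantities, vectorised over rows.
.iou_with_grad <- function(p, g) {
  pc <- .corners(p); gc <- .corners(g)
  ix1 <- pmax(pc[, 1], gc[, 1]); ix2 <- pmin(pc[, 3], gc[, 3])
  iy1 <- pmax(pc[, 2], gc[, 2]); iy2 <- pmin(pc[, 4], gc[, 4])
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  a1 <- p[, 3] * p[, 4]; a2 <- g[, 3] * g[, 4]
  union <- a1 + a2 - inter
  iou <- inter / union
  act <- inter > 0
  # dI/d(corner): active only when the pred corner is the binding one
  dI_px1 <- ifelse(act & pc[, 1] >= gc[, 1], -ih, 0)
  dI_px2 <- ifelse(act & pc[, 3] <= gc[, 3], ih, 0)
  dI_py1 <- ifelse(act & pc[, 2] >= gc[, 2], -iw, 0)
  dI_py2 <- ifelse(act & pc[, 4] <= gc[, 4], iw, 0)
  dI <- cbind(cx = dI_px1 + dI_px2,
              cy = dI_py1 + dI_py2,
              w = (dI_px2 - dI_px1) / 2,
              h = (dI_py2 - dI_py1) / 2)
  dA <- cbind(cx = 0, cy = 0, w = p[, 4], h = p[, 3])
  diou <- (dI * union - inter * (dA - dI)) / union^2
  list(iou = iou, diou = diou, pc = pc, gc = gc)
}

#' Box-regression loss with analytic gradient
#'
#' Computes the selected box loss and its gradient with respect to the
#' predicted boxes, for use in the training loop. For `wiou_v3` the outlier
#' degree and the enclosure diagonal are detached, matching the loss
#' definition; the running mean in `state` is updated as a side effect.
#'
#' @inheritParams wiou_v3
#' @param kind One of `"ciou"`, `"wiou_v1"`, `"wiou_v3"`.
#' @return List with `loss` (vector), `grad` (n x 4 matrix, d loss / d pred)
#'   and `beta` (for `wiou_v3`, else `NULL`).
#' @export
box_loss_grad <- function(pred, gt, kind = c("wiou_v3", "wiou_v1", "ciou"),
                          state = NULL, fp = focusing_params()) {
  kind <- match.arg(kind)
  p <- .as_box_matrix(pred); g <- .as_box_matrix(gt)
  ig <- .iou_with_grad(p, g)
  liou <- 1 - ig$iou
  if (kind == "ciou") {
    # enclosure diagonal
    cw <- pmax(ig$pc[, 3], ig$gc[, 3]) - pmin(ig$pc[, 1], ig$gc[, 1])
    chh <- pmax(ig$pc[, 4], ig$gc[, 4]) - pmin(ig$pc[, 2], ig$gc[, 2])
    c2 <- cw^2 + chh^2
    rho2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
    datan <- atan(g[, 3] / g[, 4]) - atan(p[, 3] / p[, 4])
    v <- 4 / pi^2 * datan^2
    al <- v / (1 - ig$iou + v + 1e-9)          # detached mixing weight
    loss <- liou + rho2 / c2 + al * v
    # gradients: enclosure treated as constant (dominant, stable form)
    drho <- cbind(2 * (p[, 1] - g[, 1]), 2 * (p[, 2] - g[, 2]), 0, 0) / c2
    wh2 <- p[, 3]^2 + p[, 4]^2
    dv <- cbind(0, 0, -(8 / pi^2) * datan * (p[, 4] / wh2),
                (8 / pi^2) * datan * (p[, 3] / wh2))
    grad <- -ig$diou + drho + al * dv
    return(list(loss = loss, grad = grad, beta = NULL))
  }
  # Wise-IoU family
  wg <- pmax(ig$pc[, 3], ig$gc[, 3]) - pmin(ig$pc[, 1], ig$gc[, 1])
  hg <- pmax(ig$pc[, 4], ig$gc[, 4]) - pmin(ig$pc[, 2], ig$gc[, 2])
  d2den <- wg^2 + hg^2                          # detached (*)
  d2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  rw <- exp(d2 / d2den)
  drw <- rw * cbind(2 * (p[, 1] - g[, 1]), 2 * (p[, 2] - g[, 2]), 0, 0) / d2den
  loss1 <- rw * liou
  grad1 <- drw * liou - rw * ig$diou
  if (kind == "wiou_v1")
    return(list(loss = loss1, grad = grad1, beta = NULL))
  if (is.null(state)) state <- outlier_state()
  lm <- state$l_mean %||% mean(liou)
  if (lm <= 0) lm <- max(mean(liou), 1e-8)
  beta <- liou / lm                             # detached
  gam <- focusing_gamma(beta, fp)
  state$l_mean <- state$momentum * lm + (1 - state$momentum) * mean(liou)
  list(loss = gam * loss1, grad = gam * grad1, beta = beta)
}
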