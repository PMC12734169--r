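# Training and evaluation workbench: configuration, the composite detection
# loss (classification BCE + distribution-focal box regression + the
# selectable IoU-family box loss), a center-cell label assigner, SGD with
# warmup/cosine schedule, and batched inference with decoding + NMS.

#' Training configuration
#'
#' Defaults follow the study's published settings: SGD with momentum 0.937,
#' initial learning rate 0.01, weight decay 0.0005, batch size 8, 640 px
#' images, 100 epochs. Warmup (3 epochs, linear) and cosine decay are
#' config-overridable.
#'
#' @param epochs,imgsz,batch,momentum,lr,weight_decay,warmup_epochs,lr_final
#'   Optimiser/loop settings.
#' @param box_gain,cls_gain,dfl_gain Loss-term weights.
#' @param seed RNG seed controlling init, shuffling and augmentation.
#' @return List of class `pd_trainconfig`.
#' @export
train_config <- function(epochs = 100L, imgsz = 640L, batch = 8L,
                         momentum = 0.937, lr = 0.01, weight_decay = 5e-4,
                         warmup_epochs = 3L, lr_final = 1e-3,
                         box_gain = 7.5, cls_gain = 0.5, dfl_gain = 1.5,
                         seed = 0L) {
  stopifnot(epochs >= 1, imgsz %% 32 == 0, batch >= 1, lr > 0)
  structure(as.list(environment()), class = "pd_trainconfig")
}

scenes_to_input <- function(scenes) {
  s <- scenes[[1]]$size
  x <- array(0, dim = c(s, s, 3, length(scenes)))
  for (i in seq_along(scenes)) x[, , , i] <- scenes[[i]]$image
  x
}

# Assign each ground-truth box to one (scale, cell): the scale whose stride
# best fits the box size (closest to size = 4 * stride) and the cell holding
# the box center. Returns a list per scale of data.frames.
assign_targets <- function(scenes, imgsz, strides = c(8L, 16L, 32L)) {
  out <- lapply(strides, function(s) data.frame(
    b = integer(0), i = integer(0), j = integer(0), cls = integer(0),
    cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0)))
  for (bi in seq_along(scenes)) {
    lb <- scenes[[bi]]$labels
    if (nrow(lb) == 0L) next
    for (r in seq_len(nrow(lb))) {
      cx <- lb$cx[r] * imgsz; cy <- lb$cy[r] * imgsz
      w <- lb$w[r] * imgsz; h <- lb$h[r] * imgsz
      size <- max(w, h)
      sc <- which.min(abs(log2(pmax(size, 1) / (4 * strides))))
      st <- strides[sc]
      ncell <- imgsz %/% st
      j <- min(max(floor(cx / st), 0), ncell - 1L)   # column (x)
      i <- min(max(floor(cy / st), 0), ncell - 1L)   # row (y)
      df <- out[[sc]]
      if (any(df$b == bi & df$i == i & df$j == j)) next  # cell taken
      out[[sc]][nrow(df) + 1L, ] <- list(bi, i, j, lb$class[r], cx, cy, w, h)
    }
  }
  out
}

# Composite loss on raw maps; returns scalar components and per-scale
# gradient arrays (d loss / d raw map).
detection_loss <- function(map_vals, targets, imgsz, nc,
                           box_kind = "wiou_v3", wiou_state = NULL,
                           fp = focusing_params(),
                           gains = c(box = 7.5, cls = 0.5, dfl = 1.5),
                           reg_max = 16L) {
  strides <- c(8L, 16L, 32L)
  npos <- max(1L, sum(vapply(targets, nrow, integer(1))))
  grads <- lapply(map_vals, function(v) array(0, dim = dim(v)))
  loss_box <- loss_dfl <- loss_cls <- 0
  beta_all <- numeric(0)
  bins <- 0:(reg_max - 1L)
  # collect box predictions/targets across scales for a single running-mean
  # update (batch-level), matching the outlier-normaliser semantics
  pend <- list()
  for (sc in 1:3) {
    v <- map_vals[[sc]]
    d <- dim(v)
    st <- strides[sc]
    tg <- targets[[sc]]
    # classification BCE over every cell and class
    zc <- v[, , 4L * reg_max + seq_len(nc), , drop = FALSE]
    pc <- 1 / (1 + exp(-zc))
    tgt <- array(0, dim = dim(zc))
    if (nrow(tg) > 0L)
      for (r in seq_len(nrow(tg)))
        tgt[tg$i[r] + 1L, tg$j[r] + 1L, tg$cls[r] + 1L, tg$b[r]] <- 1
    eps <- 1e-7
    loss_cls <- loss_cls +
      -sum(tgt * log(pc + eps) + (1 - tgt) * log(1 - pc + eps))
    grads[[sc]][, , 4L * reg_max + seq_len(nc), ] <-
      gains["cls"] / npos * (pc - tgt)
    if (nrow(tg) == 0L) next
    for (r in seq_len(nrow(tg))) {
      i <- tg$i[r] + 1L; j <- tg$j[r] + 1L; bi <- tg$b[r]
      ax <- (tg$j[r] + 0.5) * st; ay <- (tg$i[r] + 0.5) * st
      # target side distances in stride units, clamped into the bin range
      ltrb_t <- c(ax - (tg$cx[r] - tg$w[r] / 2), ay - (tg$cy[r] - tg$h[r] / 2),
                  (tg$cx[r] + tg$w[r] / 2) - ax, (tg$cy[r] + tg$h[r] / 2) - ay) / st
      ltrb_t <- pmin(pmax(ltrb_t, 0), reg_max - 1 - 1e-3)
      z <- matrix(v[i, j, seq_len(4L * reg_max), bi], reg_max, 4L)
      zs <- sweep(z, 2, apply(z, 2, max), "-")
      p <- sweep(exp(zs), 2, colSums(exp(zs)), "/")
      ltrb_p <- colSums(p * bins)
      # DFL cross-entropy against the two adjacent integer bins
      tl <- floor(ltrb_t); wu <- ltrb_t - tl; wl <- 1 - wu
      ce <- 0; gdfl <- matrix(0, reg_max, 4L)
      for (s4 in 1:4) {
        ce <- ce - wl[s4] * log(p[tl[s4] + 1L, s4] + 1e-12) -
          wu[s4] * log(p[tl[s4] + 2L, s4] + 1e-12)
        tvec <- numeric(reg_max)
        tvec[tl[s4] + 1L] <- wl[s4]; tvec[tl[s4] + 2L] <- wu[s4]
        gdfl[, s4] <- p[, s4] - tvec
      }
      loss_dfl <- loss_dfl + ce
      pend[[length(pend) + 1L]] <- list(
        sc = sc, i = i, j = j, bi = bi, st = st, ax = ax, ay = ay,
        p = p, ltrb_p = ltrb_p, gdfl = gdfl,
        pred = c(ax + (ltrb_p[3] - ltrb_p[1]) / 2 * st,
                 ay + (ltrb_p[4] - ltrb_p[2]) / 2 * st,
                 max((ltrb_p[1] + ltrb_p[3]) * st, 1e-3),
                 max((ltrb_p[2] + ltrb_p[4]) * st, 1e-3)),
        gt = c(tg$cx[r], tg$cy[r], tg$w[r], tg$h[r]))
    }
  }
  if (length(pend) > 0L) {
    pm <- t(vapply(pend, function(e) e$pred, numeric(4)))
    gm <- t(vapply(pend, function(e) e$gt, numeric(4)))
    bl <- box_loss_grad(pm, gm, box_kind, state = wiou_state, fp = fp)
    loss_box <- sum(bl$loss)
    if (!is.null(bl$beta)) beta_all <- bl$beta
    for (k in seq_along(pend)) {
      e <- pend[[k]]
      gb <- bl$grad[k, ]                      # d loss / d (cx, cy, w, h)
      # chain to side distances (stride units)
      gl <- c(-gb[1] / 2 + gb[3], -gb[2] / 2 + gb[4],
               gb[1] / 2 + gb[3],  gb[2] / 2 + gb[4]) * e$st
      # through the softmax expectation, plus the DFL term
      gz <- matrix(0, nrow(e$p), 4L)
      for (s4 in 1:4)
        gz[, s4] <- gains["box"] / npos * gl[s4] *
          e$p[, s4] * (bins - e$ltrb_p[s4]) +
          gains["dfl"] / npos * e$gdfl[, s4]
      grads[[e$sc]][e$i, e$j, seq_len(4L * nrow(e$p)), e$bi] <-
        grads[[e$sc]][e$i, e$j, seq_len(4L * nrow(e$p)), e$bi] + as.vector(gz)
    }
  }
  list(box = gains["box"] * loss_box / npos,
       cls = gains["cls"] * loss_cls / npos,
       dfl = gains["dfl"] * loss_dfl / npos,
       grads = grads, npos = npos, beta = beta_all)
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0 && !is.null(dim(p$val)) && length(dim(p$val)) == 4L)
      g <- g + weight_decay * p$val
    if (is.null(p$mom)) p$mom <- g else p$mom <- momentum * p$mom + g
    p$val <- p$val - lr * p$mom
  }
  invisible(NULL)
}

lr_at <- function(cfg, epoch) {
  if (epoch <= cfg$warmup_epochs)
    return(cfg$lr * epoch / cfg$warmup_epochs)
  t <- (epoch - cfg$warmup_epochs) / max(1, cfg$epochs - cfg$warmup_epochs)
  cfg$lr_final + (cfg$lr - cfg$lr_final) * (1 + cos(pi * t)) / 2
}

#' Train a detector variant on labelled scenes
#'
#' Standard single-stage detection training: center-cell assignment to the
#' best-fitting scale, BCE classification, distribution-focal regression and
#' the configured IoU-family box loss (`wiou_v3` when the variant's wiou
#' flag is set, else complete-IoU). The Wise-IoU running mean is updated
#' once per batch.
#'
#' @param scenes List of `pd_scene` training images.
#' @param flags Variant flags from [variant_flags()].
#' @param cfg Configuration from [train_config()].
#' @param model Optional pre-built model (for resuming); defaults to a fresh
#'   [build_model()] of the variant.
#' @return List of class `pd_run`: `model`, `log` (per-epoch data.frame with
#'   loss components, mean beta and learning rate) and `config`.
#' @export
train_detector <- function(scenes, flags = variant_flags(),
                           cfg = train_config(), model = NULL) {
  set.seed(cfg$seed)
  spec <- build_variant(flags, nc = 5L)
  if (is.null(model)) model <- build_model(spec, seed = cfg$seed)
  params <- model_params(model)
  box_kind <- if (isTRUE(flags$wiou)) "wiou_v3" else "ciou"
  wstate <- outlier_state()
  gains <- c(box = cfg$box_gain, cls = cfg$cls_gain, dfl = cfg$dfl_gain)
  log <- data.frame()
  n <- length(scenes)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    lr <- lr_at(cfg, epoch)
    ep <- c(box = 0, cls = 0, dfl = 0)
    nb <- 0L
    beta_ep <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1L, n)]
      batch <- scenes[idx]
      x <- scenes_to_input(batch)
      out <- model_forward(model, x, training = TRUE)
      mv <- lapply(out$maps, node_val)
      tg <- assign_targets(batch, cfg$imgsz)
      ls <- detection_loss(mv, tg, cfg$imgsz, nc = 5L, box_kind = box_kind,
                           wiou_state = wstate, gains = gains)
      total <- ls$box + ls$cls + ls$dfl
      if (!is.finite(total)) stop("divergent loss (non-finite) at epoch ",
                                  epoch)
      zero_grads(params)
      tape_backward_multi(out$maps, ls$grads)
      sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
      ep <- ep + c(ls$box, ls$cls, ls$dfl)
      beta_ep <- c(beta_ep, ls$beta)
      nb <- nb + 1L
    }
    log <- rbind(log, data.frame(
      epoch = epoch, lr = lr, box = ep[["box"]] / nb, cls = ep[["cls"]] / nb,
      dfl = ep[["dfl"]] / nb,
      total = sum(ep) / nb,
      beta_mean = if (length(beta_ep)) mean(beta_ep) else NA_real_))
  }
  structure(list(model = model, log = log, config = cfg, flags = flags),
            class = "pd_run")
}

# ---- inference --------------------------------------------------------------

decode_predictions <- function(map_vals, imgsz, nc, conf_thr = 0.25,
                               reg_max = 16L) {
  strides <- c(8L, 16L, 32L)
  b <- dim(map_vals[[1]])[4]
  bins <- 0:(reg_max - 1L)
  dets <- lapply(seq_len(b), function(i) list())
  for (sc in 1:3) {
    v <- map_vals[[sc]]
    d <- dim(v)
    st <- strides[sc]
    hs <- d[1]; ws <- d[2]
    # softmax expectation over the 16 bins for each of the 4 sides
    zb <- aperm(v[, , seq_len(4L * reg_max), , drop = FALSE], c(3, 1, 2, 4))
    dim(zb) <- c(reg_max, 4L * hs * ws * d[4])
    zb <- sweep(zb, 2, apply(zb, 2, max), "-")
    pb <- sweep(exp(zb), 2, colSums(exp(zb)), "/")
    ltrb <- colSums(pb * bins)                  # (4*hs*ws*b)
    dim(ltrb) <- c(4L, hs, ws, d[4])
    zc <- v[, , 4L * reg_max + seq_len(nc), , drop = FALSE]
    pc <- 1 / (1 + exp(-zc))
    ii <- matrix(seq_len(hs), hs, ws)          # row index (y)
    jj <- matrix(seq_len(ws), hs, ws, byrow = TRUE)
    ax <- (jj - 0.5) * st; ay <- (ii - 0.5) * st
    for (bi in seq_len(d[4])) {
      sc_mat <- matrix(pc[, , , bi], hs * ws, nc)
      best <- max.col(sc_mat, ties.method = "first")
      score <- sc_mat[cbind(seq_len(hs * ws), best)]
      keep <- which(score >= conf_thr)
      if (length(keep) == 0L) next
      l <- ltrb[1, , , bi][keep]; tt <- ltrb[2, , , bi][keep]
      r <- ltrb[3, , , bi][keep]; bb <- ltrb[4, , , bi][keep]
      x1 <- pmax(as.vector(ax)[keep] - l * st, 0)
      y1 <- pmax(as.vector(ay)[keep] - tt * st, 0)
      x2 <- pmin(as.vector(ax)[keep] + r * st, imgsz)
      y2 <- pmin(as.vector(ay)[keep] + bb * st, imgsz)
      dets[[bi]][[length(dets[[bi]]) + 1L]] <- data.frame(
        x1 = x1, y1 = y1, x2 = x2, y2 = y2,
        score = score[keep], class = best[keep] - 1L)
    }
  }
  lapply(dets, function(ds) {
    if (length(ds) == 0L)
      return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                        y2 = numeric(0), score = numeric(0),
                        class = integer(0)))
    do.call(rbind, ds)
  })
}

#' Run inference on scenes
#'
#' Forward pass (running statistics), raw-map decoding and greedy per-class
#' NMS.
#'
#' @param model Trained model.
#' @param scenes List of `pd_scene`.
#' @param conf_thr Score threshold before NMS.
#' @param iou_thr NMS IoU threshold.
#' @param batch Images per forward pass.
#' @return List of detection data.frames (x1, y1, x2, y2, score, class).
#' @export
predict_scenes <- function(model, scenes, conf_thr = 0.25, iou_thr = 0.45,
                           batch = 8L) {
  out <- vector("list", length(scenes))
  imgsz <- scenes[[1]]$size
  for (start in seq(1L, length(scenes), by = batch)) {
    idx <- start:min(start + batch - 1L, length(scenes))
    x <- scenes_to_input(scenes[idx])
    maps <- lapply(model_forward(model, x, training = FALSE)$maps, node_val)
    dec <- decode_predictions(maps, imgsz, model$spec$nc, conf_thr)
    for (k in seq_along(idx))
      out[[idx[k]]] <- nms_postprocess(dec[[k]], conf_thr, iou_thr)
  }
  out
}

#' Evaluate a detector on labelled scenes
#'
#' Runs inference (with a low score threshold so the PR sweep is complete)
#' and computes precision, recall, F1, mAP50, mAP50-95 and per-class AP.
#'
#' @param model Trained model.
#' @param scenes List of `pd_scene` with labels.
#' @param conf_thr Score threshold for the P/R/F1 operating point.
#' @param iou_thr NMS IoU threshold.
#' @return List with `precision`, `recall`, `f1`, `map50`, `map50_95`,
#'   `per_class_ap50` and `confusion`.
#' @export
evaluate_detector <- function(model, scenes, conf_thr = 0.25,
                              iou_thr = 0.45) {
  if (length(scenes) == 0L) stop("empty evaluation split")
  imgsz <- scenes[[1]]$size
  preds <- predict_scenes(model, scenes, conf_thr = 0.001,
                          iou_thr = iou_thr)
  truths <- lapply(scenes, function(sc) {
    co <- labels_to_corners(sc$labels, imgsz)
    data.frame(x1 = co[, 1], y1 = co[, 2], x2 = co[, 3], y2 = co[, 4],
               class = sc$labels$class)
  })
  nc <- model$spec$nc
  m50 <- detection_map(preds, truths, 0.5, nc)
  m5095 <- detection_map(preds, truths, seq(0.5, 0.95, by = 0.05), nc)
  hi <- lapply(preds, function(p) p[p$score >= conf_thr, , drop = FALSE])
  tally <- match_detections(hi, truths, 0.5, nc)$tally
  pr <- precision_recall(tally)
  list(precision = pr$precision, recall = pr$recall,
       f1 = f1_score(pr$precision, pr$recall),
       map50 = m50$map, map50_95 = m5095$map,
       per_class_ap50 = m50$per_class[1, ],
       confusion = confusion_matrix(hi, truths, nc, conf_thr, iou_thr))
}
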