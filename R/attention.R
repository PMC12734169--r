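# Attention blocks: EMA (efficient multi-scale attention with cross-spatial
# learning) and ECA (efficient channel attention).
#
# Feature maps are 4-D arrays, dim (h, w, c, b); see `?feature_map`.

#' Validate a feature map
#'
#' A feature map is a real-valued 4-D array with dimensions
#' (height, width, channels, batch). All dimensions must be >= 1 and all
#' values finite.
#'
#' @param x Array to validate.
#' @return `x`, invisibly, after validation.
#' @export
feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("feature map must be a 4-D array (h, w, c, b)")
  if (any(dim(x) < 1L)) stop("feature map dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature map values must be finite")
  invisible(x)
}

#' Directional average pooling along the horizontal axis
#'
#' Averages each channel over the image width, producing one value per row:
#' the output has spatial shape h x 1 (dimension c x h x 1 per batch item).
#'
#' @param x Feature map, dim (h, w, c, b).
#' @return Array of dim (h, 1, c, b).
#' @export
directional_pool_h <- function(x) {
  feature_map(x)
  if (dim(x)[2] < 1L) stop("empty spatial dimension")
  node_val(t_mean_w(t_const(x)))
}

#' Directional average pooling along the vertical axis
#'
#' Averages each channel over the image height, producing one value per
#' column: the output has spatial shape 1 x w (dimension c x 1 x w per batch
#' item).
#'
#' @param x Feature map, dim (h, w, c, b).
#' @return Array of dim (1, w, c, b).
#' @export
directional_pool_w <- function(x) {
  feature_map(x)
  if (dim(x)[1] < 1L) stop("empty spatial dimension")
  node_val(t_mean_h(t_const(x)))
}

# -- parameter initialisation -------------------------------------------------

init_conv_w <- function(k, cin_g, cout) {
  sd <- sqrt(2 / (k * k * cin_g))
  new_param(array(stats::rnorm(k * k * cin_g * cout, sd = sd),
                  dim = c(k, k, cin_g, cout)))
}

# -- EMA ----------------------------------------------------------------------

#' Construct an EMA attention block
#'
#' Efficient multi-scale attention: the input channels are divided into
#' `groups` sub-groups. A 1x1 branch encodes directional (row/column) global
#' context, a 3x3 branch captures local detail, and two cross-spatial
#' attention maps are formed by matrix products between each branch's global
#' descriptor (softmax over channels) and the other branch's spatial map. The
#' group output is the input rescaled by the sigmoid of the summed maps.
#'
#' @param channels Number of input channels `c`.
#' @param groups Number of channel sub-groups `g`; must divide `channels`.
#'   Defaults to 8 when `c >= 8`, else `c`.
#' @return Object of class `pd_ema`.
#' @export
new_ema <- function(channels, groups = if (channels >= 8) 8L else channels) {
  if (channels %% groups != 0L)
    stop("EMA configuration error: groups must divide channels")
  cg <- channels %/% groups
  list(
    kind = "ema", c = channels, g = groups, cg = cg,
    gn_g = new_param(rep(1, cg)), gn_b = new_param(rep(0, cg)),
    w1 = init_conv_w(1L, cg, cg), b1 = new_param(rep(0, cg)),
    w3 = init_conv_w(3L, cg, cg), b3 = new_param(rep(0, cg))
  ) |> structure(class = "pd_ema")
}

# per-(channel, sample) instance norm with affine per channel (GroupNorm with
# one channel per group)
t_inorm <- function(x, gp, bp, eps = 1e-5) {
  xv <- node_val(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  mu <- colSums(matrix(xv, hw, d[3] * d[4])) / hw
  xc <- xv - rep(mu, each = hw)
  va <- colSums(matrix(xc * xc, hw, d[3] * d[4])) / hw
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = hw)
  dim(xhat) <- d
  gn <- t_param(gp); bn_ <- t_param(bp)
  gex <- rep_len(rep(gp$val, each = hw), prod(d))
  out <- xhat * gex + rep_len(rep(bp$val, each = hw), prod(d))
  dim(out) <- d
  gamma <- gp$val
  new_node(out, list(x, gn, bn_), function(g) {
    cb_sum <- function(z) colSums(matrix(z, hw, d[3] * d[4]))
    dgamma_cb <- cb_sum(g * xhat)
    dbeta_cb <- cb_sum(g)
    dgamma <- rowSums(matrix(dgamma_cb, d[3], d[4]))
    dbeta <- rowSums(matrix(dbeta_cb, d[3], d[4]))
    gx <- g * gex * rep(istd, each = hw)
    m1 <- rep(cb_sum(g * gex) / hw, each = hw) * rep(istd, each = hw)
    m2 <- rep(cb_sum(g * gex * xhat) / hw, each = hw) * rep(istd, each = hw)
    dx <- gx - m1 - xhat * m2
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

ema_forward_node <- function(blk, x) {
  d <- dim(node_val(x))
  h <- d[1]; w <- d[2]; cc <- d[3]; b <- d[4]
  if (cc != blk$c) stop("EMA configuration error: channel mismatch")
  g <- blk$g; cg <- blk$cg; gb <- g * b
  gx <- t_reshape(x, c(h, w, cg, gb))
  # 1x1 branch: directional pooling, joint 1x1 conv, split, sigmoid gates
  ph <- t_mean_w(gx)                       # (h,1,cg,gb)
  pw <- t_mean_h(gx)                       # (1,w,cg,gb)
  pwv <- t_reshape(pw, c(w, 1L, cg, gb))   # stack along first axis
  cat_hw <- new_node_cat2(ph, pwv, h, w, cg, gb)
  hw_enc <- t_conv(cat_hw, blk$w1, blk$b1) # (h+w,1,cg,gb)
  eh <- t_reshape(t_slice_rows(hw_enc, 1L, h), c(h, 1L, cg, gb))
  ew <- t_reshape(t_slice_rows(hw_enc, h + 1L, h + w), c(1L, w, cg, gb))
  x1 <- t_mul_bcast(t_mul_bcast(gx, t_sigmoid(eh)), t_sigmoid(ew))
  x1 <- t_inorm(x1, blk$gn_g, blk$gn_b)
  # 3x3 branch
  x2 <- t_conv(gx, blk$w3, blk$b3, pad = 1L)
  # cross-spatial aggregation
  a1 <- t_softmax1(t_reshape(t_gap(x1), c(cg, 1L, gb)))   # (cg,1,gb)
  a2 <- t_softmax1(t_reshape(t_gap(x2), c(cg, 1L, gb)))
  f1 <- t_reshape(x1, c(h * w, cg, gb))
  f2 <- t_reshape(x2, c(h * w, cg, gb))
  m1 <- t_bmm(f2, a1)                      # (hw,1,gb): branch2 spatial x branch1 desc
  m2 <- t_bmm(f1, a2)
  wts <- t_sigmoid(t_reshape(t_add(m1, m2), c(h, w, 1L, gb)))
  out <- t_mul_bcast(gx, wts)
  t_reshape(out, c(h, w, cc, b))
}

# concat along the first (row) axis for (r,1,c,b)-shaped descriptors
new_node_cat2 <- function(a, b, h, w, cg, gb) {
  av <- node_val(a); bv <- node_val(b)
  out <- array(0, dim = c(h + w, 1L, cg, gb))
  out[1:h, , , ] <- av
  out[(h + 1L):(h + w), , , ] <- bv
  new_node(out, list(a, b), function(g)
    list(g[1:h, , , , drop = FALSE], g[(h + 1L):(h + w), , , , drop = FALSE]))
}

t_slice_rows <- function(x, from, to) {
  xv <- node_val(x)
  d <- dim(xv)
  new_node(xv[from:to, , , , drop = FALSE], list(x), function(g) {
    out <- array(0, dim = d)
    out[from:to, , , ] <- g
    list(out)
  })
}

#' Apply an EMA block to a feature map
#'
#' @param blk EMA block from [new_ema()].
#' @param x Feature map, dim (h, w, c, b), with `c` matching the block.
#' @return Feature map of the same shape.
#' @export
ema_forward <- function(blk, x) {
  feature_map(x)
  node_val(ema_forward_node(blk, t_const(x)))
}

# -- ECA ----------------------------------------------------------------------

#' Adaptive ECA kernel size
#'
#' The 1-D convolution width is derived from the channel count as
#' `k = |log2(c)/gamma + b/gamma|` rounded to the nearest odd integer
#' (truncation toward zero, then +1 if even).
#'
#' @param channels Channel count.
#' @param gamma,b Mapping parameters (defaults 2 and 1).
#' @return Odd integer kernel size.
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  t <- as.integer(abs((log2(channels) + b) / gamma))
  if (t %% 2L == 1L) t else t + 1L
}

#' Construct an ECA channel-attention block
#'
#' Global average pooling per channel, a 1-D convolution of width `k` across
#' the channel axis, and a sigmoid gate rescaling each channel.
#'
#' @param channels Number of channels.
#' @param k Odd kernel width, or `"adaptive"` (default) for the
#'   channel-derived rule of [eca_kernel_size()].
#' @return Object of class `pd_eca`.
#' @export
new_eca <- function(channels, k = "adaptive") {
  if (identical(k, "adaptive")) k <- eca_kernel_size(channels)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop("ECA configuration error: k must be odd")
  list(kind = "eca", c = channels, k = k,
       w = new_param(rep(1 / k, k))) |> structure(class = "pd_eca")
}

# 1-D convolution across channels of a (1,1,c,b) descriptor. Replicate
# (edge) padding so that a uniform channel descriptor yields a uniform gate.
t_conv1d_ch <- function(x, wp) {
  xv <- node_val(x)
  d <- dim(xv)
  cc <- d[3]; b <- d[4]; k <- length(wp$val)
  half <- (k - 1L) %/% 2L
  m <- matrix(xv, cc, b)
  idx <- function(j) pmin(pmax(seq_len(cc) + j - 1L - half, 1L), cc)
  out <- matrix(0, cc, b)
  for (j in seq_len(k))
    out <- out + wp$val[j] * m[idx(j), , drop = FALSE]
  wn <- t_param(wp)
  wval <- wp$val
  new_node(array(out, dim = d), list(x, wn), function(g) {
    gm <- matrix(g, cc, b)
    dx <- matrix(0, cc, b)
    dw <- numeric(k)
    for (j in seq_len(k)) {
      ij <- idx(j)
      sc <- rowsum(wval[j] * gm, ij)
      dx[as.integer(rownames(sc)), ] <- dx[as.integer(rownames(sc)), ] + sc
      dw[j] <- sum(gm * m[ij, , drop = FALSE])
    }
    list(array(dx, dim = d), dw)
  })
}

eca_forward_node <- function(blk, x) {
  gate <- t_sigmoid(t_conv1d_ch(t_gap(x), blk$w))
  t_mul_bcast(x, gate)
}

#' Apply an ECA block to a feature map
#'
#' @param blk ECA block from [new_eca()].
#' @param x Feature map, dim (h, w, c, b).
#' @return Feature map of the same shape.
#' @export
eca_forward <- function(blk, x) {
  feature_map(x)
  node_val(eca_forward_node(blk, t_const(x)))
}
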