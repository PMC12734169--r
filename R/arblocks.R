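# Adaptive residual blocks (ARBlock) and the C3k2-B container that replaces
# the baseline C3k2 feature-extraction block.
#
# ARBlock pipeline: depthwise-separable 3x3 stem (dw conv + BN, pointwise
# conv + BN + SiLU), three parallel separable branches whose depthwise convs
# use dilation rates 1/3/5 (the receptive field grows without extra
# parameters), channel concatenation, batch norm, ECA channel attention, a
# 1x1 fusion projection back to the block width, and an adaptive gate:
#
#   x_out = gate(x_residual) * x_conv + (1 - gate(x_residual)) * x_residual
#
# where gate() is a 1x1 convolution + sigmoid computed from the residual
# stream, emitting one weight in (0,1) per spatial position.

#' Construct an adaptive residual block
#'
#' @param channels Block width `c` (input and output channels).
#' @param dilations Dilation rates of the three parallel depthwise branches.
#' @return Object of class `pd_arblock`.
#' @export
new_arblock <- function(channels, dilations = c(1L, 3L, 5L)) {
  if (any(dilations < 1L)) stop("dilation rates must be strictly positive")
  c <- channels
  br <- lapply(dilations, function(d) list(
    dw = init_conv_w(3L, 1L, c),             # depthwise, dilated
    pw = init_conv_w(1L, c, c)))             # pointwise, no norm
  list(kind = "arblock", c = c, dil = as.integer(dilations),
       stem_dw = m_conv(c, c, 3L, g = c, act = FALSE),
       stem_pw = m_conv(c, c, 1L),
       branches = br,
       cat_g = new_param(rep(1, 3L * c)), cat_b = new_param(rep(0, 3L * c)),
       cat_st = new.env(parent = emptyenv()),
       eca = new_eca(3L * c),
       proj = m_conv(3L * c, c, 1L),
       gate_w = init_conv_w(1L, c, 1L), gate_b = new_param(0),
       fwd = function(self, x, tr) {
         cc <- self$c
         if (dim(node_val(x))[3] != cc)
           stop("ARBlock configuration error: channel mismatch")
         s <- fwd_run(self$stem_pw, fwd_run(self$stem_dw, x, tr), tr)
         outs <- lapply(seq_along(self$branches), function(i) {
           b <- self$branches[[i]]
           d <- self$dil[i]
           y <- t_conv(s, b$dw, NULL, 1L, autopad(3L, d), d, cc)
           t_conv(y, b$pw, NULL)
         })
         y <- t_concat_c(outs)
         y <- t_bn(y, self$cat_g, self$cat_b, self$cat_st, tr)
         y <- eca_forward_node(self$eca, y)
         xconv <- fwd_run(self$proj, y, tr)
         gate <- t_sigmoid(t_conv(x, self$gate_w, self$gate_b))
         t_add(x, t_mul_bcast(t_sub(xconv, x), gate))
       })
}

#' Apply an ARBlock to a feature map
#'
#' @param blk Block from [new_arblock()].
#' @param x Feature map, dim (h, w, c, b) with matching channel count.
#' @param gate Optional override: a constant in `[0, 1]` replacing the learned
#'   gate (useful for inspecting the blend limits of the gating equation).
#' @return Feature map of the same shape.
#' @export
arblock_forward <- function(blk, x, gate = NULL) {
  feature_map(x)
  if (is.null(gate)) return(node_val(blk$fwd(blk, t_const(x), FALSE)))
  # gate override: recompute the blend with a fixed coefficient
  cc <- blk$c
  s <- fwd_run(blk$stem_pw, fwd_run(blk$stem_dw, t_const(x), FALSE), FALSE)
  outs <- lapply(seq_along(blk$branches), function(i) {
    b <- blk$branches[[i]]
    d <- blk$dil[i]
    t_conv(t_conv(s, b$dw, NULL, 1L, autopad(3L, d), d, cc), b$pw, NULL)
  })
  y <- t_bn(t_concat_c(outs), blk$cat_g, blk$cat_b, blk$cat_st, FALSE)
  y <- eca_forward_node(blk$eca, y)
  xconv <- node_val(fwd_run(blk$proj, y, FALSE))
  gate * xconv + (1 - gate) * x
}

#' Construct a C3k2-B block
#'
#' Transition 1x1 convolution producing `2 * hidden` channels, split into two
#' halves; the right half passes through `n` stacked ARBlocks; the halves are
#' concatenated and fused by a final 1x1 convolution to `c_out`.
#'
#' @param c_in,c_out Input and output channel counts.
#' @param n Number of stacked ARBlocks (>= 0).
#' @param e Hidden-width ratio: `hidden = as.integer(c_out * e)`.
#' @return Object of class `pd_c3k2b`.
#' @export
new_c3k2b <- function(c_in, c_out, n = 1L, e = 0.5) {
  if (n < 0L) stop("C3k2-B configuration error: n must be >= 0")
  ch <- as.integer(c_out * e)
  list(kind = "c3k2b", c_in = c_in, c_out = c_out, ch = ch, n = n,
       trans = m_conv(c_in, 2L * ch, 1L),
       m = lapply(seq_len(n), function(i) new_arblock(ch)),
       fuse = m_conv(2L * ch, c_out, 1L),
       fwd = function(self, x, tr) {
         if (dim(node_val(x))[3] != self$c_in)
           stop("C3k2-B configuration error: channel mismatch")
         y <- fwd_run(self$trans, x, tr)
         left <- t_slice_c(y, 1L, self$ch)
         right <- t_slice_c(y, self$ch + 1L, 2L * self$ch)
         for (blk in self$m) right <- fwd_run(blk, right, tr)
         fwd_run(self$fuse, t_concat_c(list(left, right)), tr)
       })
}

#' Apply a C3k2-B block to a feature map
#'
#' @param blk Block from [new_c3k2b()].
#' @param x Feature map with `c_in` channels.
#' @return Feature map with `c_out` channels, spatial size preserved.
#' @export
c3k2b_forward <- function(blk, x) {
  feature_map(x)
  node_val(blk$fwd(blk, t_const(x), FALSE))
}
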