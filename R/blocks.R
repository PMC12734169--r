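# Network building blocks for the nano-scale detector: standard conv stacks,
# split-transform-concat blocks, area attention, and the detection head.
# Each block is a list with a `fwd(self, x, tr)` closure operating on tape
# nodes; `tr` switches batch-norm between batch and running statistics.

autopad <- function(k, d = 1L) ((k - 1L) * d) %/% 2L

# conv + batch norm + (optional) SiLU; bias-free conv
m_conv <- function(c1, c2, k = 1L, s = 1L, g = 1L, d = 1L, act = TRUE) {
  list(kind = "conv", c1 = c1, c2 = c2, k = k, s = s, g = g, d = d, act = act,
       w = init_conv_w(k, c1 %/% g, c2),
       bng = new_param(rep(1, c2)), bnb = new_param(rep(0, c2)),
       bnst = new.env(parent = emptyenv()),
       fwd = function(self, x, tr) {
         y <- t_conv(x, self$w, NULL, self$s, autopad(self$k, self$d),
                     self$d, self$g)
         y <- t_bn(y, self$bng, self$bnb, self$bnst, tr)
         if (self$act) t_silu(y) else y
       })
}

# plain conv with bias, no norm or activation
m_conv_raw <- function(c1, c2, k = 1L, s = 1L, g = 1L, d = 1L,
                       bias_init = 0) {
  list(kind = "conv_raw", c1 = c1, c2 = c2, k = k, s = s, g = g, d = d,
       w = init_conv_w(k, c1 %/% g, c2),
       b = new_param(rep(bias_init, c2)),
       fwd = function(self, x, tr)
         t_conv(x, self$w, self$b, self$s, autopad(self$k, self$d),
                self$d, self$g))
}

fwd_run <- function(m, x, tr) m$fwd(m, x, tr)

m_bottleneck <- function(c1, c2, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(c2 * e)
  list(kind = "bottleneck", add = shortcut && c1 == c2,
       cv1 = m_conv(c1, ch, 3L), cv2 = m_conv(ch, c2, 3L),
       fwd = function(self, x, tr) {
         y <- fwd_run(self$cv2, fwd_run(self$cv1, x, tr), tr)
         if (self$add) t_add(x, y) else y
       })
}

m_c3k <- function(c1, c2, n = 2L, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(c2 * e)
  list(kind = "c3k",
       cv1 = m_conv(c1, ch, 1L), cv2 = m_conv(c1, ch, 1L),
       cv3 = m_conv(2L * ch, c2, 1L),
       m = lapply(seq_len(n), function(i) m_bottleneck(ch, ch, shortcut, 1.0)),
       fwd = function(self, x, tr) {
         a <- fwd_run(self$cv1, x, tr)
         for (blk in self$m) a <- fwd_run(blk, a, tr)
         b <- fwd_run(self$cv2, x, tr)
         fwd_run(self$cv3, t_concat_c(list(a, b)), tr)
       })
}

m_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5, shortcut = TRUE) {
  ch <- as.integer(c2 * e)
  list(kind = "c3k2", ch = ch,
       cv1 = m_conv(c1, 2L * ch, 1L),
       cv2 = m_conv((2L + n) * ch, c2, 1L),
       m = lapply(seq_len(n), function(i)
         if (c3k) m_c3k(ch, ch, 2L, shortcut) else
           m_bottleneck(ch, ch, shortcut, 0.5)),
       fwd = function(self, x, tr) {
         y <- fwd_run(self$cv1, x, tr)
         parts <- list(t_slice_c(y, 1L, self$ch),
                       t_slice_c(y, self$ch + 1L, 2L * self$ch))
         for (blk in self$m)
           parts[[length(parts) + 1L]] <- fwd_run(blk, parts[[length(parts)]], tr)
         fwd_run(self$cv2, t_concat_c(parts), tr)
       })
}

# -- area attention -----------------------------------------------------------

# Single-head-group area attention block: qkv/proj 1x1 convs, 5x5 depthwise
# positional conv on v, token attention within `area` vertical strips, then a
# two-layer MLP; both sublayers are residual.
m_ablock <- function(dim, num_heads, mlp_ratio = 2, area = 1L) {
  hd <- dim %/% num_heads
  mh <- as.integer(dim * mlp_ratio)
  list(kind = "ablock", dim = dim, nh = num_heads, hd = hd, area = area,
       qkv = m_conv(dim, 3L * dim, 1L, act = FALSE),
       proj = m_conv(dim, dim, 1L, act = FALSE),
       pe = m_conv(dim, dim, 5L, g = dim, act = FALSE),
       mlp1 = m_conv(dim, mh, 1L), mlp2 = m_conv(mh, dim, 1L, act = FALSE),
       fwd = function(self, x, tr) {
         d <- dim(node_val(x))
         h <- d[1]; w <- d[2]; b <- d[4]
         cc <- self$dim; hd <- self$hd; nh <- self$nh
         area <- if (w %% self$area == 0L) self$area else 1L
         qkv <- fwd_run(self$qkv, x, tr)
         q <- t_slice_c(qkv, 1L, cc)
         k <- t_slice_c(qkv, cc + 1L, 2L * cc)
         v <- t_slice_c(qkv, 2L * cc + 1L, 3L * cc)
         na <- h * w %/% area
         tok <- function(z) {
           # (h,w,cc,b) -> tokens (na, hd, area*nh*b); area = vertical strips
           z <- t_reshape(z, c(na, area, hd, nh, b))
           z <- t_aperm(z, c(1L, 3L, 2L, 4L, 5L))
           t_reshape(z, c(na, hd, area * nh * b))
         }
         qt <- tok(q); kt <- tok(k); vt <- tok(v)
         st <- t_scale(t_bmm(kt, t_aperm(qt, c(2L, 1L, 3L))), 1 / sqrt(hd))
         p <- t_softmax1(st)                      # softmax over keys
         ot <- t_bmm(t_aperm(p, c(2L, 1L, 3L)), vt)
         o <- t_reshape(ot, c(na, hd, area, nh, b))
         o <- t_aperm(o, c(1L, 3L, 2L, 4L, 5L))
         o <- t_reshape(o, c(h, w, cc, b))
         o <- t_add(o, fwd_run(self$pe, v, tr))
         x <- t_add(x, fwd_run(self$proj, o, tr))
         t_add(x, fwd_run(self$mlp2, fwd_run(self$mlp1, x, tr), tr))
       })
}

m_a2c2f <- function(c1, c2, n = 1L, a2 = TRUE, area = 1L, e = 0.5) {
  ch <- as.integer(c2 * e)
  if (a2 && ch %% 32L != 0L) stop("attention width must be a multiple of 32")
  list(kind = "a2c2f",
       cv1 = m_conv(c1, ch, 1L),
       cv2 = m_conv((1L + n) * ch, c2, 1L),
       m = lapply(seq_len(n), function(i)
         if (a2) list(m_ablock(ch, ch %/% 32L, 2, area),
                      m_ablock(ch, ch %/% 32L, 2, area))
         else list(m_c3k(ch, ch, 2L))),
       fwd = function(self, x, tr) {
         y <- list(fwd_run(self$cv1, x, tr))
         for (blks in self$m) {
           z <- y[[length(y)]]
           for (blk in blks) z <- fwd_run(blk, z, tr)
           y[[length(y) + 1L]] <- z
         }
         fwd_run(self$cv2, t_concat_c(y), tr)
       })
}

# -- detection head -----------------------------------------------------------

# Decoupled anchor-free head: box branch regresses 4*reg_max distribution
# bins, class branch uses depthwise-separable stacks. Outputs per scale are
# (h, w, 4*reg_max + nc, b) raw maps.
m_detect <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  cls_bias <- log(0.01 / 0.99)   # rare-positive prior for stable warm-up
  branches <- lapply(ch, function(x) list(
    box1 = m_conv(x, c2, 3L), box2 = m_conv(c2, c2, 3L),
    box3 = m_conv_raw(c2, 4L * reg_max, 1L),
    cls1 = m_conv(x, x, 3L, g = x), cls2 = m_conv(x, c3, 1L),
    cls3 = m_conv(c3, c3, 3L, g = c3), cls4 = m_conv(c3, c3, 1L),
    cls5 = m_conv_raw(c3, nc, 1L, bias_init = cls_bias)))
  list(kind = "detect", nc = nc, reg_max = reg_max, branches = branches,
       fwd = function(self, xs, tr) {
         lapply(seq_along(xs), function(i) {
           br <- self$branches[[i]]
           x <- xs[[i]]
           box <- fwd_run(br$box3, fwd_run(br$box2, fwd_run(br$box1, x, tr), tr), tr)
           cl <- fwd_run(br$cls1, x, tr)
           cl <- fwd_run(br$cls2, cl, tr)
           cl <- fwd_run(br$cls3, cl, tr)
           cl <- fwd_run(br$cls4, cl, tr)
           cl <- fwd_run(br$cls5, cl, tr)
           t_concat_c(list(box, cl))
         })
       })
}

# -- parameter collection -----------------------------------------------------

collect_params <- function(m) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "pd_param")) out[[length(out) + 1L]] <<- x
    else if (is.list(x) && !is.function(x)) for (el in x) walk(el)
  }
  walk(m)
  out
}

n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$val), numeric(1)))
}
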