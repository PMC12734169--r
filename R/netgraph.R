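# Explicit layer-graph assembly of the nano-scale detector and its ablation
# variants, analytic parameter/FLOP profiling, instantiation and forward
# inference.
#
# The baseline follows the nano scaling (width 0.25, depth 0.5, max 1024) of
# the reference single-stage architecture: a Conv/C3k2 stem, area-attention
# A2C2f stages at P4/P5, a PAN-style neck and an anchor-free decoupled head
# with distribution-focal box regression at strides 8/16/32. Variant flags:
#  * ema    - insert two EMA attention blocks at the backbone tail (after the
#             last Conv and after the last A2C2f),
#  * fusion - advance the bottom-up P4 fusion stage to P3 resolution: the
#             stride-2 conv before the concat is dropped, a three-way concat
#             fuses the P3 head feature, the shallow backbone P3 feature and
#             the upsampled top-down feature at 80x80, the fusion block runs
#             there, and a strided pointwise conv projects to the P4 scale,
#  * c3k2b  - substitute C3k2-B (ARBlock-based) at the three C3k2 sites,
#  * wiou   - swap the box-regression loss (graph unchanged).

nano_width <- function(c) as.integer(8 * ceiling(min(c, 1024) * 0.25 / 8))

#' Variant flags
#'
#' @param ema,fusion,wiou,c3k2b Logical switches for the four improvements.
#'   Any combination is valid.
#' @return List of class `pd_flags`.
#' @export
variant_flags <- function(ema = FALSE, fusion = FALSE, wiou = FALSE,
                          c3k2b = FALSE) {
  structure(list(ema = ema, fusion = fusion, wiou = wiou, c3k2b = c3k2b),
            class = "pd_flags")
}

#' Build a detector variant as an explicit layer graph
#'
#' @param flags Flags from [variant_flags()] (or a list with the same names).
#' @param nc Number of object classes (>= 1).
#' @param ema_groups Channel groups of inserted EMA blocks.
#' @return A `pd_graphspec`: ordered layer list with from-indices (0 denotes
#'   the network input), plus the detect sources.
#' @export
build_variant <- function(flags = variant_flags(), nc = 5L, ema_groups = 8L) {
  stopifnot(nc >= 1L)
  c64 <- nano_width(64); c128 <- nano_width(128); c256 <- nano_width(256)
  c512 <- nano_width(512); c1024 <- nano_width(1024)
  L <- list(); id <- 0L
  add <- function(.from, .kind, ...) {
    id <<- id + 1L
    L[[id]] <<- list(id = id, from = as.integer(.from), kind = .kind,
                     args = list(...))
    id
  }
  c3k2_kind <- if (isTRUE(flags$c3k2b)) "c3k2b" else "c3k2"
  i <- add(0L, "conv", c2 = c64, k = 3L, s = 2L)
  i <- add(i, "conv", c2 = c128, k = 3L, s = 2L)
  i <- add(i, c3k2_kind, c2 = c256, n = 1L, c3k = FALSE, e = 0.25)
  i <- add(i, "conv", c2 = c256, k = 3L, s = 2L, g = 4L)
  p3b <- add(i, c3k2_kind, c2 = c512, n = 1L, c3k = FALSE, e = 0.25)
  i <- add(p3b, "conv", c2 = c512, k = 3L, s = 2L)
  p4b <- add(i, "a2c2f", c2 = c512, n = 2L, a2 = TRUE, area = 4L)
  i <- add(p4b, "conv", c2 = c1024, k = 3L, s = 2L)
  if (isTRUE(flags$ema)) i <- add(i, "ema", groups = ema_groups)
  i <- add(i, "a2c2f", c2 = c1024, n = 2L, a2 = TRUE, area = 1L)
  if (isTRUE(flags$ema)) i <- add(i, "ema", groups = ema_groups)
  p5b <- i
  # top-down
  i <- add(p5b, "upsample")
  i <- add(c(i, p4b), "concat")
  td4 <- add(i, "a2c2f", c2 = c512, n = 1L, a2 = FALSE)
  up3 <- add(td4, "upsample")
  i <- add(c(up3, p3b), "concat")
  p3 <- add(i, "a2c2f", c2 = c256, n = 1L, a2 = FALSE)
  # bottom-up
  if (!isTRUE(flags$fusion)) {
    i <- add(p3, "conv", c2 = c256, k = 3L, s = 2L)
    i <- add(c(i, td4), "concat")
    p4 <- add(i, "a2c2f", c2 = c512, n = 1L, a2 = FALSE)
    i <- add(p4, "conv", c2 = c512, k = 3L, s = 2L)
  } else {
    i <- add(c(p3, p3b, up3), "concat")
    i <- add(i, "a2c2f", c2 = c512, n = 1L, a2 = FALSE)
    p4 <- add(i, "conv", c2 = c512, k = 1L, s = 2L)
    i <- add(p4, "conv", c2 = c512, k = 3L, s = 2L)
  }
  i <- add(c(i, p5b), "concat")
  p5 <- add(i, c3k2_kind, c2 = c1024, n = 1L, c3k = TRUE, e = 0.5)
  det <- add(c(p3, p4, p5), "detect", nc = as.integer(nc))
  structure(list(layers = L, nc = as.integer(nc),
                 flags = flags, detect_id = det,
                 detect_from = c(p3, p4, p5)),
            class = "pd_graphspec")
}

# ---- analytic profiling -----------------------------------------------------

# Accounting conventions: parameters are trainable scalars (conv weights and
# biases, norm affine pairs). FLOPs count one multiply-add as two operations
# for every convolution (at its output size) plus 4 ops/element for affine
# batch-norm outputs, matching the unfused-model profiling convention of the
# mainstream detection frameworks whose published figures use it; activations,
# pooling, upsampling and attention matrix products are not counted.
.acct <- function() {
  e <- new.env(parent = emptyenv()); e$p <- 0; e$f <- 0; e
}
.aconv <- function(a, c1, c2, k, hw, g = 1L, bn = TRUE, bias = FALSE) {
  w <- k * k * (c1 %/% g) * c2
  a$p <- a$p + w + (if (bn) 2 * c2 else 0) + (if (bias) c2 else 0)
  a$f <- a$f + 2 * w * hw + (if (bn) 4 * c2 * hw else 0)
}
.abottleneck <- function(a, c1, c2, hw, e = 0.5) {
  ch <- as.integer(c2 * e)
  .aconv(a, c1, ch, 3L, hw); .aconv(a, ch, c2, 3L, hw)
}
.ac3k <- function(a, c1, c2, hw, n = 2L, e = 0.5) {
  ch <- as.integer(c2 * e)
  .aconv(a, c1, ch, 1L, hw); .aconv(a, c1, ch, 1L, hw)
  .aconv(a, 2L * ch, c2, 1L, hw)
  for (i in seq_len(n)) .abottleneck(a, ch, ch, hw, 1.0)
}
.ac3k2 <- function(a, c1, c2, hw, n, c3k, e) {
  ch <- as.integer(c2 * e)
  .aconv(a, c1, 2L * ch, 1L, hw); .aconv(a, (2L + n) * ch, c2, 1L, hw)
  for (i in seq_len(n))
    if (c3k) .ac3k(a, ch, ch, hw, 2L) else .abottleneck(a, ch, ch, hw, 0.5)
}
.aablock <- function(a, dm, hw) {
  .aconv(a, dm, 3L * dm, 1L, hw)
  .aconv(a, dm, dm, 1L, hw)
  .aconv(a, dm, dm, 5L, hw, g = dm)
  .aconv(a, dm, 2L * dm, 1L, hw); .aconv(a, 2L * dm, dm, 1L, hw)
}
.aa2c2f <- function(a, c1, c2, hw, n, a2, e = 0.5) {
  ch <- as.integer(c2 * e)
  .aconv(a, c1, ch, 1L, hw); .aconv(a, (1L + n) * ch, c2, 1L, hw)
  for (i in seq_len(n))
    if (a2) { .aablock(a, ch, hw); .aablock(a, ch, hw) }
    else .ac3k(a, ch, ch, hw, 2L)
}
.aarblock <- function(a, cc, hw) {
  .aconv(a, cc, cc, 3L, hw, g = cc)
  .aconv(a, cc, cc, 1L, hw)
  for (i in 1:3) {
    .aconv(a, cc, cc, 3L, hw, g = cc, bn = FALSE)
    .aconv(a, cc, cc, 1L, hw, bn = FALSE)
  }
  a$p <- a$p + 2 * 3 * cc                 # concat BN
  a$f <- a$f + 4 * 3 * cc * hw
  k <- eca_kernel_size(3L * cc)
  a$p <- a$p + k; a$f <- a$f + 2 * k * 3 * cc
  .aconv(a, 3L * cc, cc, 1L, hw)
  .aconv(a, cc, 1L, 1L, hw, bn = FALSE, bias = TRUE)
}
.ac3k2b <- function(a, c1, c2, hw, n, e) {
  ch <- as.integer(c2 * e)
  .aconv(a, c1, 2L * ch, 1L, hw)
  for (i in seq_len(n)) .aarblock(a, ch, hw)
  .aconv(a, 2L * ch, c2, 1L, hw)
}
.aema <- function(a, cc, h, w, groups) {
  cg <- cc %/% groups
  a$p <- a$p + 2 * cg
  .aconv(a, cg, cg, 1L, (h + w) * groups, bn = FALSE, bias = TRUE)
  .aconv(a, cg, cg, 3L, h * w * groups, bn = FALSE, bias = TRUE)
}
.adetect <- function(a, nc, ch, hws, reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  for (i in seq_along(ch)) {
    x <- ch[i]; hw <- hws[i]
    .aconv(a, x, c2, 3L, hw); .aconv(a, c2, c2, 3L, hw)
    .aconv(a, c2, 4L * reg_max, 1L, hw, bn = FALSE, bias = TRUE)
    .aconv(a, x, x, 3L, hw, g = x); .aconv(a, x, c3, 1L, hw)
    .aconv(a, c3, c3, 3L, hw, g = c3); .aconv(a, c3, c3, 1L, hw)
    .aconv(a, c3, nc, 1L, hw, bn = FALSE, bias = TRUE)
  }
}

profile_graph <- function(spec, imgsz = 640L) {
  a <- .acct()
  ch <- c(`0` = 3L); res <- c(`0` = as.integer(imgsz))
  getc <- function(i) ch[[as.character(i)]]
  getr <- function(i) res[[as.character(i)]]
  for (ly in spec$layers) {
    key <- as.character(ly$id)
    f1 <- ly$from[1]
    cin <- getc(f1); rin <- getr(f1)
    ar <- ly$args
    switch(ly$kind,
      conv = {
        rout <- if (ar$s == 2L) rin %/% 2L else rin
        .aconv(a, cin, ar$c2, ar$k, rout^2, g = ar$g %||% 1L)
        ch[[key]] <- ar$c2; res[[key]] <- rout
      },
      c3k2 = {
        .ac3k2(a, cin, ar$c2, rin^2, ar$n, ar$c3k, ar$e)
        ch[[key]] <- ar$c2; res[[key]] <- rin
      },
      c3k2b = {
        .ac3k2b(a, cin, ar$c2, rin^2, ar$n, ar$e)
        ch[[key]] <- ar$c2; res[[key]] <- rin
      },
      a2c2f = {
        .aa2c2f(a, cin, ar$c2, rin^2, ar$n, ar$a2)
        ch[[key]] <- ar$c2; res[[key]] <- rin
      },
      ema = {
        .aema(a, cin, rin, rin, ar$groups)
        ch[[key]] <- cin; res[[key]] <- rin
      },
      upsample = { ch[[key]] <- cin; res[[key]] <- rin * 2L },
      concat = {
        rs <- vapply(ly$from, getr, integer(1))
        if (length(unique(rs)) != 1L) stop("concat inputs differ in size")
        ch[[key]] <- sum(vapply(ly$from, getc, integer(1)))
        res[[key]] <- rin
      },
      detect = {
        .adetect(a, ar$nc, vapply(ly$from, getc, integer(1)),
                 vapply(ly$from, getr, integer(1))^2)
        ch[[key]] <- 0L; res[[key]] <- rin
      },
      stop("unknown layer kind: ", ly$kind))
  }
  list(acct = a, ch = ch, res = res)
}

#' Count trainable parameters of a graph
#'
#' @param spec Graph from [build_variant()].
#' @return Exact integer count of trainable scalars.
#' @export
count_params <- function(spec) {
  as.integer(round(profile_graph(spec)$acct$p))
}

#' Forward-pass FLOPs of a graph
#'
#' One multiply-add counts as two operations; affine batch norm on the
#' unfused model contributes 4 ops/element; activations, pooling, upsampling
#' and attention matrix products are not counted.
#'
#' @param spec Graph from [build_variant()].
#' @param imgsz Square input size in pixels (default 640).
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
count_flops <- function(spec, imgsz = 640L) {
  profile_graph(spec, imgsz)$acct$f / 1e9
}

#' Profile a variant
#'
#' @param flags Variant flags (see [variant_flags()]).
#' @param nc Number of classes.
#' @param imgsz Input size for the FLOP count.
#' @return List with `params` (integer), `params_m` (millions, 2 dp),
#'   `gflops` (1 dp) and the unrounded `gflops_raw`.
#' @export
profile_variant <- function(flags = variant_flags(), nc = 5L, imgsz = 640L) {
  spec <- build_variant(flags, nc)
  p <- count_params(spec)
  f <- count_flops(spec, imgsz)
  list(params = p,
       params_m = floor(p / 1e6 * 100 + 0.5) / 100,
       gflops = floor(f * 10 + 0.5) / 10,
       gflops_raw = f)
}

# ---- instantiation and forward ----------------------------------------------

#' Instantiate a graph into a trainable model
#'
#' @param spec Graph from [build_variant()].
#' @param seed Optional RNG seed for weight initialisation.
#' @return Object of class `pd_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- profile_graph(spec)
  mods <- list()
  for (ly in spec$layers) {
    cin <- prof$ch[[as.character(ly$from[1])]]
    ar <- ly$args
    mods[[ly$id]] <- switch(ly$kind,
      conv = m_conv(cin, ar$c2, ar$k, ar$s, ar$g %||% 1L),
      c3k2 = m_c3k2(cin, ar$c2, ar$n, ar$c3k, ar$e),
      c3k2b = new_c3k2b(cin, ar$c2, ar$n, ar$e),
      a2c2f = m_a2c2f(cin, ar$c2, ar$n, ar$a2, ar$area %||% 1L),
      ema = new_ema(cin, ar$groups),
      upsample = list(kind = "upsample"),
      concat = list(kind = "concat"),
      detect = m_detect(ar$nc, vapply(ly$from, function(i)
        prof$ch[[as.character(i)]], integer(1))))
  }
  structure(list(spec = spec, mods = mods,
                 strides = c(8L, 16L, 32L)), class = "pd_model")
}

#' Run the model forward
#'
#' @param model Model from [build_model()].
#' @param x Input images, array dim (h, w, 3, b); `h`, `w` divisible by 32.
#' @param training Use batch statistics in the normalisation layers.
#' @return List with `maps`: per-scale raw prediction nodes
#'   (h_s, w_s, 4*reg_max + nc, b) at strides 8/16/32, and `input` node.
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[3] != 3L)
    stop("input must be (h, w, 3, b)")
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input size must be divisible by the maximum stride (32)")
  outs <- vector("list", length(model$mods))
  xin <- t_const(x)
  getn <- function(i) if (i == 0L) xin else outs[[i]]
  for (ly in model$spec$layers) {
    m <- model$mods[[ly$id]]
    outs[[ly$id]] <- switch(ly$kind,
      upsample = t_upsample2(getn(ly$from[1])),
      concat = t_concat_c(lapply(ly$from, getn)),
      ema = ema_forward_node(m, getn(ly$from[1])),
      detect = m$fwd(m, lapply(ly$from, getn), training),
      m$fwd(m, getn(ly$from[1]), training))
  }
  list(maps = outs[[model$spec$detect_id]], input = xin)
}

#' Collect all trainable parameters of a model
#'
#' @param model Model from [build_model()].
#' @return List of parameter environments.
#' @export
model_params <- function(model) collect_params(model$mods)
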