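# Reverse-mode autodiff over dense arrays.
#
# Feature maps are 4-D arrays with dim (h, w, c, b): height varies fastest
# (column-major), batch slowest. A tape node is an environment holding the
# forward value, its parents and a pullback closure; `tape_backward()` walks
# the graph in reverse topological order. Parameters live in their own
# environments (`new_param()`) so gradients accumulate across a batch and
# persist for the optimiser.

.node_counter <- new.env(parent = emptyenv())
.node_counter$i <- 0L

new_node <- function(val, parents = list(), pullback = NULL) {
  n <- new.env(parent = emptyenv())
  .node_counter$i <- .node_counter$i + 1L
  n$id <- .node_counter$i
  n$val <- val
  n$parents <- parents
  n$pullback <- pullback
  n$grad <- NULL
  class(n) <- "pd_node"
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a trainable parameter
#'
#' Parameters are environments so that gradient accumulation and optimiser
#' state survive across forward passes.
#'
#' @param val Numeric array of initial values.
#' @return Environment with fields `val`, `grad`, `mom`; class `pd_param`.
#' @keywords internal
new_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$mom <- NULL
  class(p) <- "pd_param"
  p
}

t_param <- function(p) {
  n <- new_node(p$val)
  n$param <- p
  n
}

t_const <- function(val) new_node(val)

node_val <- function(x) if (inherits(x, "pd_node")) x$val else x

needs_grad <- function(x) {
  inherits(x, "pd_node") && (!is.null(x$param) || length(x$parents) > 0L)
}

#' Run reverse-mode accumulation from a root node
#'
#' @param root Output node.
#' @param grad Gradient of the objective w.r.t. the root value; defaults to 1.
#' @keywords internal
tape_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = dim(root$val) %||% 1L)
  tape_backward_multi(list(root), list(grad))
}

#' Reverse-mode accumulation from several roots at once
#'
#' Used when independent outputs (e.g. the three detection scales) share the
#' same upstream graph: gradients are seeded at every root and pulled back in
#' one global reverse-topological sweep.
#'
#' @param roots List of output nodes.
#' @param grads List of gradient arrays, one per root.
#' @keywords internal
tape_backward_multi <- function(roots, grads) {
  order <- vector("list", 512L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- vector("list", 64L); ns <- 0L
  push <- function(n, st) {
    ns <<- ns + 1L
    if (ns > length(stack)) stack <<- c(stack, vector("list", length(stack)))
    stack[[ns]] <<- list(n = n, stage = st)
  }
  for (r in roots) push(r, 1L)
  while (ns > 0L) {
    top <- stack[[ns]]; ns <- ns - 1L
    n <- top$n
    key <- as.character(n$id)
    if (top$stage == 1L) {
      if (isTRUE(seen[[key]])) next
      seen[[key]] <- TRUE
      push(n, 2L)
      for (p in n$parents)
        if (inherits(p, "pd_node") && !isTRUE(seen[[as.character(p$id)]]))
          push(p, 1L)
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- n
    }
  }
  for (k in seq_along(roots)) {
    r <- roots[[k]]
    if (is.null(r$grad)) r$grad <- grads[[k]] else r$grad <- r$grad + grads[[k]]
  }
  for (i in seq(norder, 1L)) {
    n <- order[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$param)) {
      if (is.null(n$param$grad)) n$param$grad <- n$grad
      else n$param$grad <- n$param$grad + n$grad
    }
    if (!is.null(n$pullback)) {
      gs <- n$pullback(n$grad)
      for (j in seq_along(gs)) {
        p <- n$parents[[j]]
        if (inherits(p, "pd_node") && !is.null(gs[[j]])) {
          if (is.null(p$grad)) p$grad <- gs[[j]] else p$grad <- p$grad + gs[[j]]
        }
      }
      n$grad <- NULL   # free interior activations as we go; leaves keep theirs
    }
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- broadcast helpers ------------------------------------------------------

.bcast <- function(a, dims) {
  da <- dim(a)
  if (all(da == dims)) return(a)
  idx <- lapply(seq_along(dims), function(k)
    if (da[k] == 1L) rep.int(1L, dims[k]) else seq_len(dims[k]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

.reduce_to <- function(g, dims) {
  dg <- dim(g)
  for (k in seq_along(dims)) {
    if (dims[k] == 1L && dg[k] > 1L) {
      kept <- setdiff(seq_along(dg), k)
      g <- array(apply(g, kept, sum), dim = replace(dg, k, 1L))
      dg <- dim(g)
    }
  }
  g
}

# channel helpers: v is length-c vector, x is (h,w,c,b)
.ch_expand <- function(v, d) {
  rep_len(rep(v, each = d[1] * d[2]), prod(d))
}
.ch_sum <- function(x, d) {  # per-channel sums over h,w,b
  m <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(m, d[3], d[4]))
}

# ---- elementwise ops --------------------------------------------------------

t_add <- function(a, b)
  new_node(node_val(a) + node_val(b), list(a, b), function(g) list(g, g))

t_sub <- function(a, b)
  new_node(node_val(a) - node_val(b), list(a, b), function(g) list(g, -g))

t_mul <- function(a, b) {
  av <- node_val(a); bv <- node_val(b)
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

t_scale <- function(a, s)
  new_node(node_val(a) * s, list(a), function(g) list(g * s))

t_silu <- function(a) {
  av <- node_val(a)
  new_node(cpp_silu(av), list(a), function(g) list(cpp_silu_backward(av, g)))
}

t_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-node_val(a)))
  new_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# x (h,w,c,b) times gate with singleton dims broadcast
t_mul_bcast <- function(x, gate) {
  xv <- node_val(x); gv <- node_val(gate)
  dx <- dim(xv); dg <- dim(gv)
  stopifnot(length(dx) == 4L, length(dg) == 4L, all(dg == dx | dg == 1L))
  new_node(cpp_bcast_mul(xv, dx, gv, dg), list(x, gate), function(g)
    list(cpp_bcast_mul(g, dx, gv, dg),
         cpp_reduce_to(cpp_bcast_mul(g, dx, xv, dx), dx, dg)))
}

# ---- structural ops ---------------------------------------------------------

t_concat_c <- function(nodes) {
  vals <- lapply(nodes, node_val)
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  ends <- cumsum(cs); starts <- ends - cs + 1L
  d <- dim(vals[[1]])
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  for (i in seq_along(vals)) out[, , starts[i]:ends[i], ] <- vals[[i]]
  new_node(out, nodes, function(g)
    lapply(seq_along(cs), function(i)
      g[, , starts[i]:ends[i], , drop = FALSE]))
}

t_slice_c <- function(x, from, to) {
  xv <- node_val(x)
  d <- dim(xv)
  new_node(xv[, , from:to, , drop = FALSE], list(x), function(g) {
    out <- array(0, dim = d)
    out[, , from:to, ] <- g
    list(out)
  })
}

t_aperm <- function(x, perm) {
  xv <- node_val(x)
  inv <- order(perm)
  new_node(aperm(xv, perm), list(x), function(g) list(aperm(g, inv)))
}

t_reshape <- function(x, dims) {
  xv <- node_val(x)
  d0 <- dim(xv) %||% length(xv)
  out <- xv
  dim(out) <- dims
  new_node(out, list(x), function(g) { dim(g) <- d0; list(g) })
}

# ---- pooling / resampling ---------------------------------------------------

t_gap <- function(x) {
  xv <- node_val(x); d <- dim(xv)
  hw <- d[1] * d[2]
  m <- colSums(matrix(xv, hw, d[3] * d[4])) / hw
  out <- array(m, dim = c(1, 1, d[3], d[4]))
  new_node(out, list(x), function(g) list(.bcast(g / hw, d)))
}

# mean over width -> (h, 1, c, b)
t_mean_w <- function(x) {
  xv <- node_val(x); d <- dim(xv)
  p <- aperm(xv, c(2, 1, 3, 4))
  m <- colSums(matrix(p, d[2], d[1] * d[3] * d[4])) / d[2]
  out <- array(m, dim = c(d[1], 1, d[3], d[4]))
  new_node(out, list(x), function(g) list(.bcast(g / d[2], d)))
}

# mean over height -> (1, w, c, b)
t_mean_h <- function(x) {
  xv <- node_val(x); d <- dim(xv)
  m <- colSums(matrix(xv, d[1], d[2] * d[3] * d[4])) / d[1]
  out <- array(m, dim = c(1, d[2], d[3], d[4]))
  new_node(out, list(x), function(g) list(.bcast(g / d[1], d)))
}

t_upsample2 <- function(x) {
  xv <- node_val(x)
  new_node(cpp_upsample2(xv, dim(xv)), list(x), function(g)
    list(cpp_upsample2_backward(g, dim(g))))
}

# ---- batched matmul / softmax ----------------------------------------------

# A: (m,k,nb), B: (k,n,nb) -> (m,n,nb)
t_bmm <- function(a, b) {
  av <- node_val(a); bv <- node_val(b)
  da <- dim(av); db <- dim(bv)
  nb <- da[3]
  out <- array(0, dim = c(da[1], db[2], nb))
  for (i in seq_len(nb))
    out[, , i] <- matrix(av[, , i], da[1], da[2]) %*%
      matrix(bv[, , i], db[1], db[2])
  new_node(out, list(a, b), function(g) {
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (i in seq_len(nb)) {
      gi <- matrix(g[, , i], da[1], db[2])
      ga[, , i] <- gi %*% t(matrix(bv[, , i], db[1], db[2]))
      gb[, , i] <- t(matrix(av[, , i], da[1], da[2])) %*% gi
    }
    list(ga, gb)
  })
}

# softmax over the first dimension
t_softmax1 <- function(x) {
  xv <- node_val(x)
  d <- dim(xv)
  m <- matrix(xv, d[1])
  m <- sweep(m, 2, apply(m, 2, max), "-")
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  pv <- array(p, dim = d)
  new_node(pv, list(x), function(g) {
    gm <- matrix(g, d[1])
    dot <- colSums(gm * p)
    list(array(p * sweep(gm, 2, dot, "-"), dim = d))
  })
}

# ---- convolution / batch norm ----------------------------------------------

t_conv <- function(x, wp, bp = NULL, stride = 1L, pad = 0L, dil = 1L,
                   groups = 1L) {
  xv <- node_val(x)
  wd <- dim(wp$val)
  k <- wd[1]; cout <- wd[4]
  wn <- t_param(wp)
  parents <- list(x, wn)
  has_bias <- !is.null(bp)
  if (has_bias) parents <- c(parents, list(t_param(bp)))
  out <- cpp_conv2d(xv, dim(xv), wp$val, k, cout, stride, pad, dil, groups,
                    if (has_bias) bp$val else NULL)
  wval <- wp$val
  need_dx <- needs_grad(x)
  new_node(out, parents, function(g) {
    r <- cpp_conv2d_backward(xv, dim(xv), wval, k, cout, stride, pad, dil,
                             groups, g, need_dx, has_bias)
    dx <- if (need_dx) r$dx else NULL
    if (has_bias) list(dx, r$dw, r$db) else list(dx, r$dw)
  })
}

# Batch normalisation per channel over (h, w, b). Training mode uses batch
# statistics and updates running moments in `st` outside the gradient path.
t_bn <- function(x, gp, bp, st, training, momentum = 0.03, eps = 1e-5) {
  xv <- node_val(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  nel <- hw * d[4]
  gn <- t_param(gp); bn_ <- t_param(bp)
  if (training) {
    mu <- cpp_ch_sum(xv, hw, d[3], d[4]) / nel
    va <- cpp_ch_dot(xv, xv, hw, d[3], d[4]) / nel - mu^2
    va <- pmax(va, 0)
    if (is.null(st$rmean)) {
      st$rmean <- mu
      st$rvar <- va * nel / max(nel - 1, 1)
    } else {
      st$rmean <- (1 - momentum) * st$rmean + momentum * mu
      st$rvar <- (1 - momentum) * st$rvar +
        momentum * va * nel / max(nel - 1, 1)
    }
  } else {
    mu <- st$rmean %||% numeric(d[3])
    va <- st$rvar %||% rep(1, d[3])
  }
  istd <- 1 / sqrt(va + eps)
  fw <- cpp_bn_fwd(xv, mu, istd, gp$val, bp$val, hw, d[3], d[4])
  xhat <- fw$xhat
  out <- fw$out
  gamma <- gp$val
  new_node(out, list(x, gn, bn_), function(g) {
    dgamma <- cpp_ch_dot(g, xhat, hw, d[3], d[4])
    dbeta <- cpp_ch_sum(g, hw, d[3], d[4])
    gx <- cpp_ch_axpb(g, gamma * istd, numeric(d[3]), hw, d[3], d[4])
    if (training) {
      m1 <- cpp_ch_sum(gx, hw, d[3], d[4]) / nel
      m2 <- cpp_ch_dot(gx, xhat, hw, d[3], d[4]) / nel
      dx <- cpp_bn_dx(gx, xhat, m1, m2, hw, d[3], d[4])
    } else {
      dx <- gx
    }
    list(dx, dgamma, dbeta)
  })
}
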