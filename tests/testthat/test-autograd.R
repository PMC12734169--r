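# Gradient correctness of the array autodiff against central differences.

test_that("convolution gradients match finite differences across configs", {
  set.seed(1)
  cases <- list(
    list(h = 5, w = 4, c = 4, b = 2, k = 3, cout = 6, s = 1, d = 1, g = 1),
    list(h = 6, w = 6, c = 4, b = 2, k = 3, cout = 6, s = 2, d = 1, g = 2),
    list(h = 7, w = 7, c = 3, b = 1, k = 3, cout = 3, s = 1, d = 3, g = 3),
    list(h = 5, w = 5, c = 4, b = 2, k = 1, cout = 8, s = 2, d = 1, g = 1))
  for (cs in cases) {
    x <- rand_fmap(cs$h, cs$w, cs$c, cs$b)
    wt <- array(rnorm(cs$k^2 * (cs$c / cs$g) * cs$cout, sd = 0.3),
                dim = c(cs$k, cs$k, cs$c / cs$g, cs$cout))
    bb <- rnorm(cs$cout)
    wp <- pestdet:::new_param(wt)
    bp <- pestdet:::new_param(bb)
    pad <- pestdet:::autopad(cs$k, cs$d)
    fwd <- function(xv, wv, bv)
      sum(pestdet:::cpp_conv2d(xv, dim(xv), wv, cs$k, cs$cout, cs$s, pad,
                               cs$d, cs$g, bv)^2)
    xn <- pestdet:::t_const(x)
    xn$parents <- list(pestdet:::t_const(0))   # mark as needing a gradient
    out <- pestdet:::t_conv(xn, wp, bp, cs$s, pad, cs$d, cs$g)
    pestdet:::tape_backward(out, 2 * out$val)
    expect_lt(rel_err(xn$grad, num_grad(function(z) fwd(z, wt, bb), x)), 1e-6)
    expect_lt(rel_err(wp$grad,
                      num_grad(function(z) fwd(x, array(z, dim(wt)), bb), wt)),
              1e-6)
    expect_lt(rel_err(bp$grad, num_grad(function(z) fwd(x, wt, z), bb)), 1e-6)
  }
})

test_that("batch-norm gradients match finite differences in training mode", {
  set.seed(2)
  x <- rand_fmap(3, 4, 5, 2)
  gp <- pestdet:::new_param(runif(5, 0.5, 1.5))
  bp <- pestdet:::new_param(rnorm(5))
  ref <- function(xv, gv, bv) {
    mu <- apply(xv, 3, mean)
    xc <- sweep(xv, 3, mu, "-")
    va <- apply(xc^2, 3, mean)
    xh <- sweep(xc, 3, 1 / sqrt(va + 1e-5), "*")
    sum(sweep(sweep(xh, 3, gv, "*"), 3, bv, "+")^3)
  }
  xn <- pestdet:::t_const(x)
  xn$parents <- list(pestdet:::t_const(0))
  out <- pestdet:::t_bn(xn, gp, bp, new.env(), training = TRUE)
  pestdet:::tape_backward(out, 3 * out$val^2)
  expect_lt(rel_err(xn$grad,
                    num_grad(function(z) ref(array(z, dim(x)), gp$val, bp$val), x)),
            1e-6)
  expect_lt(rel_err(gp$grad, num_grad(function(z) ref(x, z, bp$val), gp$val)),
            1e-6)
  expect_lt(rel_err(bp$grad, num_grad(function(z) ref(x, gp$val, z), bp$val)),
            1e-6)
})

test_that("softmax/batched-matmul/pooling/gating composite backpropagates", {
  set.seed(3)
  a <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  b <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
  wg <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  an <- pestdet:::t_const(a); an$parents <- list(pestdet:::t_const(0))
  bn <- pestdet:::t_const(b); bn$parents <- list(pestdet:::t_const(0))
  out <- pestdet:::t_bmm(pestdet:::t_softmax1(an), bn)
  pestdet:::tape_backward(out, wg)
  ref <- function(av, bv) {
    s <- 0
    for (i in 1:5) {
      m <- matrix(av[, , i], 3, 4)
      m <- apply(m, 2, function(cc) { e <- exp(cc - max(cc)); e / sum(e) })
      s <- s + sum((m %*% matrix(bv[, , i], 4, 2)) * wg[, , i])
    }
    s
  }
  expect_lt(rel_err(an$grad,
                    num_grad(function(z) ref(array(z, dim(a)), b), a)), 1e-6)
  expect_lt(rel_err(bn$grad,
                    num_grad(function(z) ref(a, array(z, dim(b))), b)), 1e-6)

  x <- rand_fmap(4, 6, 3, 2)
  xn <- pestdet:::t_const(x); xn$parents <- list(pestdet:::t_const(0))
  out <- pestdet:::t_silu(pestdet:::t_upsample2(
    pestdet:::t_mul_bcast(xn, pestdet:::t_sigmoid(pestdet:::t_gap(xn)))))
  pestdet:::tape_backward(out, array(1, dim(out$val)))
  ref2 <- function(xv) {
    d <- dim(xv)
    gm <- array(apply(xv, c(3, 4), mean), c(1, 1, d[3], d[4]))
    o <- xv * pestdet:::.bcast(1 / (1 + exp(-gm)), d)
    u <- pestdet:::cpp_upsample2(o, dim(o))
    sum(u / (1 + exp(-u)))
  }
  expect_lt(rel_err(xn$grad, num_grad(ref2, x)), 1e-6)
})
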