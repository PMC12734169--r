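# EMA / ECA attention blocks and directional pooling.

test_that("directional pooling matches the stated examples and shapes", {
  v <- array(3.7, dim = c(4, 6, 2, 1))
  expect_equal(as.vector(directional_pool_h(v)), rep(3.7, 8))
  expect_equal(as.vector(directional_pool_w(v)), rep(3.7, 12))

  # 1-channel 2x2 map with rows (1,3) and (5,7)
  x <- array(0, dim = c(2, 2, 1, 1))
  x[1, , 1, 1] <- c(1, 3)
  x[2, , 1, 1] <- c(5, 7)
  expect_equal(as.vector(directional_pool_h(x)), c(2, 6))   # per-row means
  expect_equal(as.vector(directional_pool_w(x)), c(3, 5))   # per-column means

  # output dimensions: c x h x 1 and c x 1 x w per batch item
  x <- rand_fmap(5, 9, 3, 2, seed = 1)
  expect_equal(dim(directional_pool_h(x)), c(5L, 1L, 3L, 2L))
  expect_equal(dim(directional_pool_w(x)), c(1L, 9L, 3L, 2L))
})

test_that("directional pooling agrees with a brute-force mean and is row-permutation equivariant", {
  x <- rand_fmap(5, 7, 3, 2, seed = 2)
  ph <- directional_pool_h(x)
  pw <- directional_pool_w(x)
  for (b in 1:2) for (cc in 1:3) {
    for (i in 1:5) expect_equal(ph[i, 1, cc, b], mean(x[i, , cc, b]))
    for (j in 1:7) expect_equal(pw[1, j, cc, b], mean(x[, j, cc, b]))
  }
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(directional_pool_h(x[perm, , , , drop = FALSE]),
               ph[perm, , , , drop = FALSE])
})

test_that("EMA preserves shape, gates zeros to zeros, and validates groups", {
  set.seed(4)
  blk <- new_ema(8, groups = 2)
  x <- rand_fmap(4, 5, 8, 2)
  y <- ema_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(ema_forward(blk, array(0, dim(x))) == 0))
  expect_error(new_ema(10, groups = 4), "divide")

  set.seed(5)
  blk64 <- new_ema(64, groups = 32)   # per-group channel dim 2
  x64 <- rand_fmap(3, 3, 64, 1)
  expect_equal(dim(ema_forward(blk64, x64)), dim(x64))
})

test_that("EMA matches a straight-line step-by-step reference of its dataflow", {
  set.seed(6)
  h <- 4L; w <- 5L; cc <- 8L; g <- 2L; b <- 2L
  cg <- cc / g
  blk <- new_ema(cc, groups = g)
  x <- rand_fmap(h, w, cc, b)
  got <- ema_forward(blk, x)

  sig <- function(z) 1 / (1 + exp(-z))
  w1 <- blk$w1$val; b1 <- blk$b1$val
  w3 <- blk$w3$val; b3 <- blk$b3$val
  expected <- array(NA_real_, dim(x))
  for (bi in seq_len(b)) for (gi in seq_len(g)) {
    slab <- x[, , ((gi - 1) * cg + 1):(gi * cg), bi, drop = FALSE]
    dim(slab) <- c(h, w, cg)
    # directional pooling
    ph <- apply(slab, c(1, 3), mean)               # (h, cg)
    pw <- apply(slab, c(2, 3), mean)               # (w, cg)
    s <- rbind(ph, pw)                             # (h+w, cg)
    # shared 1x1 conv over the stacked descriptor
    enc <- matrix(0, h + w, cg)
    for (co in seq_len(cg)) {
      acc <- rep(b1[co], h + w)
      for (ci in seq_len(cg)) acc <- acc + w1[1, 1, ci, co] * s[, ci]
      enc[, co] <- acc
    }
    eh <- enc[1:h, , drop = FALSE]
    ew <- enc[(h + 1):(h + w), , drop = FALSE]
    # gated map, then per-channel normalisation over (h, w)
    x1 <- array(0, c(h, w, cg))
    for (ci in seq_len(cg))
      x1[, , ci] <- slab[, , ci] * sig(eh[, ci]) %o% rep(1, w) *
        rep(1, h) %o% sig(ew[, ci])
    for (ci in seq_len(cg)) {
      m <- mean(x1[, , ci]); v <- mean((x1[, , ci] - m)^2)
      x1[, , ci] <- (x1[, , ci] - m) / sqrt(v + 1e-5) *
        blk$gn_g$val[ci] + blk$gn_b$val[ci]
    }
    # 3x3 conv branch (zero padding), written out longhand
    x2 <- array(0, c(h, w, cg))
    for (co in seq_len(cg)) for (i in 1:h) for (j in 1:w) {
      acc <- b3[co]
      for (ci in seq_len(cg)) for (ki in -1:1) for (kj in -1:1) {
        ii <- i + ki; jj <- j + kj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
          acc <- acc + w3[ki + 2, kj + 2, ci, co] * slab[ii, jj, ci]
      }
      x2[i, j, co] <- acc
    }
    # cross-spatial aggregation
    sm <- function(z) { e <- exp(z - max(z)); e / sum(e) }
    a1 <- sm(apply(x1, 3, mean))
    a2 <- sm(apply(x2, 3, mean))
    wts <- matrix(0, h, w)
    for (ci in seq_len(cg))
      wts <- wts + x2[, , ci] * a1[ci] + x1[, , ci] * a2[ci]
    wts <- sig(wts)
    for (ci in seq_len(cg))
      expected[, , (gi - 1) * cg + ci, bi] <- slab[, , ci] * wts
  }
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("ECA gates channels as specified", {
  # uniform channels -> one common weight; output = input * weight
  set.seed(7)
  blk <- new_eca(16)
  v <- array(2.5, dim = c(3, 3, 16, 2))
  y <- eca_forward(blk, v)
  wts <- unique(round(as.vector(y / v), 12))
  expect_length(wts, 1L)
  common <- 1 / (1 + exp(-sum(blk$w$val) * 2.5))
  expect_equal(y[1, 1, 1, 1], 2.5 * common)

  # adaptive kernel rule (gamma = 2, b = 1): c = 256 -> k = 5
  expect_equal(eca_kernel_size(256), 5L)
  expect_equal(new_eca(256)$k, 5L)
  expect_error(new_eca(16, k = 4), "odd")

  # zero input -> zero output; bounded gating shrinks magnitudes
  x <- rand_fmap(4, 4, 16, 2)
  expect_true(all(eca_forward(blk, array(0, dim(x))) == 0))
  y <- eca_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))
})
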