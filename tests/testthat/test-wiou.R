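# IoU / Wise-IoU losses and the dynamic non-monotonic focusing mechanism.

test_that("IoU handles the canonical cases and matches a rasterization oracle", {
  b <- c(3, 4, 2, 2)
  expect_equal(box_iou(b, b), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(10, 10, 1, 1)), 0)
  # corner boxes (0,0)-(2,2) and (1,1)-(3,3): intersection 1, union 7
  expect_equal(box_iou(c(1, 1, 2, 2), c(2, 2, 2, 2)), 1 / 7)
  expect_error(box_iou(c(0, 0, -1, 1), b), "positive")

  set.seed(21)
  devs <- vapply(1:300, function(i) {
    p <- rand_boxes_grid(1); g <- rand_boxes_grid(1)
    abs(box_iou(p, g) - raster_iou(p[1, ], g[1, ]))
  }, numeric(1))
  expect_lt(max(devs), 1e-3)
})

test_that("RWIoU evaluates the distance attention exactly", {
  expect_equal(rwiou(c(5, 5, 2, 3), c(5, 5, 4, 1)), 1)   # coincident centers
  # centers (0,0) and (3,4); enclosure 10 x 5
  expect_equal(rwiou(c(0, 0, 10, 1), c(3, 4, 2, 1)), exp(25 / 125))
  set.seed(22)
  for (i in 1:100) {
    v <- rwiou(rand_boxes(1), rand_boxes(1))
    expect_gte(v, 1)
    expect_lt(v, exp(1))
  }
})

test_that("Wise-IoU v1 is the product of its two factors", {
  b <- c(3, 3, 2, 2)
  expect_equal(wiou_v1(b, b), 0)
  # coincident centers, IoU = 0.5: 2x1 inside 2x2 -> IoU 0.5
  expect_equal(wiou_v1(c(1, 1, 2, 1), c(1, 1, 2, 2)), 0.5)
  set.seed(23)
  p <- rand_boxes(40); g <- rand_boxes(40)
  expect_equal(wiou_v1(p, g), rwiou(p, g) * (1 - box_iou(p, g)))
})

test_that("the focusing coefficient is non-monotonic with the stated landmarks", {
  fp <- focusing_params(alpha = 1.9, delta = 3)
  expect_identical(focusing_gamma(3, fp), 1)        # beta = delta -> exactly 1
  expect_lt(focusing_gamma(50, fp), 1e-3)           # large-outlier suppression
  # unique maximum at beta = 1 / log(alpha), confirmed by dense grid search
  grid <- seq(0.01, 20, by = 0.001)
  gv <- focusing_gamma(grid, fp)
  expect_equal(grid[which.max(gv)], 1 / log(1.9), tolerance = 1e-3)
  # rises then falls around the peak
  pk <- which.max(gv)
  expect_true(all(diff(gv[1:pk]) > 0))
  expect_true(all(diff(gv[pk:length(gv)]) < 0))
  expect_error(focusing_params(alpha = -1), "positive")
  expect_error(focusing_gamma(-0.5, fp), "nonnegative")
})

test_that("Wise-IoU v3 applies the focusing gain over the running mean", {
  fp <- focusing_params()
  # current loss equal to the running mean -> beta = 1, gamma = 1.9^2 / 3
  st <- outlier_state(momentum = 0.9)
  p <- c(2, 2, 2, 2); g <- c(2.5, 2, 2, 2)
  l1 <- wiou_v1(p, g)
  st$l_mean <- 1 - box_iou(p, g)
  r <- wiou_v3(p, g, st, fp)
  expect_equal(r$beta, 1)
  expect_equal(r$loss, (1 / 3) * 1.9^2 * l1, tolerance = 1e-12)

  # identical boxes -> zero loss for any state
  st$l_mean <- 0.37
  expect_equal(wiou_v3(g, g, st, fp)$loss, 0)

  # constant loss stream: the running mean converges, beta -> 1
  st <- outlier_state(momentum = 0.8)
  for (i in 1:60) r <- wiou_v3(p, g, st, fp)
  expect_equal(st$l_mean, 1 - box_iou(p, g), tolerance = 1e-4)
  expect_equal(r$beta, 1, tolerance = 1e-3)
})

test_that("the quality classification criterion is scale-free (dynamic)", {
  # scaling every pair's IoU-loss stream by a constant leaves the long-run
  # beta distribution unchanged, because the running mean rescales with it
  set.seed(24)
  losses <- runif(200, 0.05, 0.9)
  run_betas <- function(scale) {
    m <- 0.9; lm <- NULL; betas <- numeric(0)
    for (l in losses * scale) {
      if (is.null(lm)) lm <- l
      betas <- c(betas, l / lm)
      lm <- m * lm + (1 - m) * l
    }
    betas
  }
  expect_equal(run_betas(1), run_betas(7.3), tolerance = 1e-10)
})

test_that("box-loss gradients are analytic-exact and detach the stated terms", {
  set.seed(25)
  p <- rand_boxes(6); g <- rand_boxes(6)
  # frozen-denominator reference for the Wise-IoU family: the enclosure
  # diagonal is a constant in the gradient
  pc <- pestdet:::.corners(p); gc <- pestdet:::.corners(g)
  wg <- pmax(pc[, 3], gc[, 3]) - pmin(pc[, 1], gc[, 1])
  hg <- pmax(pc[, 4], gc[, 4]) - pmin(pc[, 2], gc[, 2])
  d2den <- wg^2 + hg^2
  ref <- function(pp) {
    d2 <- (pp[, 1] - g[, 1])^2 + (pp[, 2] - g[, 2])^2
    exp(d2 / d2den) * (1 - box_iou(pp, g))
  }
  bl <- box_loss_grad(p, g, "wiou_v1")
  ng <- matrix(0, 6, 4)
  for (r in 1:6) for (k in 1:4) {
    e <- 1e-6
    pp <- p; pp[r, k] <- pp[r, k] + e
    pm <- p; pm[r, k] <- pm[r, k] - e
    ng[r, k] <- (ref(pp)[r] - ref(pm)[r]) / (2 * e)
  }
  expect_lt(max(abs(bl$grad - ng)), 1e-6)

  # enlarging the enclosure (through the partner box) changes the loss value
  # but the beta of v3 carries no gradient: v3 grad is exactly gamma * v1 grad
  st <- outlier_state()
  bl3 <- box_loss_grad(p, g, "wiou_v3", state = st)
  gam <- focusing_gamma(bl3$beta)
  expect_equal(bl3$grad, gam * bl$grad, tolerance = 1e-12)
  expect_equal(bl3$loss, gam * bl$loss, tolerance = 1e-12)
})
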