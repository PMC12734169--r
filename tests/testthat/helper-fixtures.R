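# Shared fixtures: small random feature maps and scenes, and a numeric
# gradient helper used by the autograd checks.

rand_fmap <- function(h, w, c, b, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * b), dim = c(h, w, c, b))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

# random center-format boxes guaranteed valid
rand_boxes <- function(n, lim = 10) {
  cbind(cx = stats::runif(n, 0, lim), cy = stats::runif(n, 0, lim),
        w = stats::runif(n, 0.5, lim / 2), h = stats::runif(n, 0.5, lim / 2))
}

# pixel-rasterization IoU oracle: cells of size `cell` over the joint
# bounding region, counted at cell centers with half-open box intervals.
# Exact (up to float) when all box corners lie on the cell lattice.
raster_iou <- function(p, g, cell = 0.25) {
  x0 <- min(p[1] - p[3] / 2, g[1] - g[3] / 2) - cell
  x1 <- max(p[1] + p[3] / 2, g[1] + g[3] / 2) + cell
  y0 <- min(p[2] - p[4] / 2, g[2] - g[4] / 2) - cell
  y1 <- max(p[2] + p[4] / 2, g[2] + g[4] / 2) + cell
  xs <- seq(x0 + cell / 2, x1, by = cell)
  ys <- seq(y0 + cell / 2, y1, by = cell)
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  inside <- function(b)
    gx >= b[1] - b[3] / 2 & gx < b[1] + b[3] / 2 &
    gy >= b[2] - b[4] / 2 & gy < b[2] + b[4] / 2
  ip <- inside(p); ig <- inside(g)
  sum(ip & ig) / sum(ip | ig)
}

# boxes whose corners lie on the `cell` lattice (for the exact oracle)
rand_boxes_grid <- function(n, lim = 10, cell = 0.25) {
  q <- function(z) round(z / cell) * cell
  x1 <- q(stats::runif(n, 0, lim)); y1 <- q(stats::runif(n, 0, lim))
  w <- q(stats::runif(n, 2, lim / 2)) + cell
  h <- q(stats::runif(n, 2, lim / 2)) + cell
  cbind(cx = x1 + w / 2, cy = y1 + h / 2, w = w, h = h)
}

tiny_scenes <- function(n, size = 64L, seed = 7L) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_spec(size = size), seed = seed + i))
}
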