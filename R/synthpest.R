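# Synthetic labelled pest scenes.
#
# Emulates the statistical structure of a melon-leaf pest dataset with five
# classes so that detection, training and evaluation are testable without
# external data: dense tiny dark clusters (aphids), elongated pale
# random-walk tunnels whose rectangular boxes are mostly background
# (leafminers), two medium textured blob classes (moths, red beetles) and
# tiny bright scatter (whiteflies). Object counts are Poisson with a
# configurable mean (default 3.5 targets per image); everything is seeded
# and reproducible.

PEST_CLASSES <- c("aphids", "leafminers", "moths", "red_melon_beetles",
                  "whiteflies")

#' Synthetic scene recipe
#'
#' @param size Square image side in pixels (default 160).
#' @param mean_targets Mean number of objects per image (Poisson; default
#'   3.5).
#' @param class_mix Sampling probabilities over the five classes.
#' @param texture Background texture amplitude in `[0, 1]`.
#' @param max_tries Placement retries before giving up.
#' @return List of class `pd_scenespec`.
#' @export
scene_spec <- function(size = 160L, mean_targets = 3.5,
                       class_mix = rep(1 / 5, 5), texture = 0.06,
                       max_tries = 50L) {
  stopifnot(mean_targets > 0, length(class_mix) == 5L, all(class_mix >= 0))
  structure(list(size = as.integer(size), mean_targets = mean_targets,
                 class_mix = class_mix / sum(class_mix), texture = texture,
                 max_tries = as.integer(max_tries)),
            class = "pd_scenespec")
}

.draw_ellipse <- function(img, cx, cy, rx, ry, col, ang = 0) {
  s <- dim(img)[1]
  xs <- pmax(1L, floor(cx - rx - ry)):pmin(s, ceiling(cx + rx + ry))
  ys <- pmax(1L, floor(cy - rx - ry)):pmin(s, ceiling(cy + rx + ry))
  ca <- cos(ang); sa <- sin(ang)
  for (x in xs) for (y in ys) {
    dx <- x - cx; dy <- y - cy
    u <- (dx * ca + dy * sa) / rx
    v <- (-dx * sa + dy * ca) / ry
    if (u * u + v * v <= 1) img[y, x, ] <- col
  }
  img
}

# One object of class `cl` (0-based); returns list(img, box = c(cx,cy,w,h)
# normalized) or NULL if placement failed.
.place_object <- function(img, cl, spec) {
  s <- spec$size
  if (cl == 1L) {                       # leafminer tunnel: random walk
    n <- 18L + stats::rpois(1, 12)
    px <- numeric(n); py <- numeric(n)
    px[1] <- stats::runif(1, 0.15 * s, 0.85 * s)
    py[1] <- stats::runif(1, 0.15 * s, 0.85 * s)
    ang <- stats::runif(1, 0, 2 * pi)
    step <- s * 0.018
    for (i in 2:n) {
      ang <- ang + stats::rnorm(1, 0, 0.7)
      px[i] <- min(max(px[i - 1] + step * cos(ang), 2), s - 1)
      py[i] <- min(max(py[i - 1] + step * sin(ang), 2), s - 1)
    }
    col <- c(0.92, 0.93, 0.72) + stats::rnorm(3, 0, 0.015)
    r <- max(1, s * 0.006)
    for (i in seq_len(n))
      img <- .draw_ellipse(img, px[i], py[i], r, r, pmin(pmax(col, 0), 1))
    x1 <- min(px) - r; x2 <- max(px) + r; y1 <- min(py) - r; y2 <- max(py) + r
    if ((x2 - x1) < 0.04 * s || (y2 - y1) < 0.04 * s) return(NULL)
    box <- c((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1) / s
  } else {
    # elliptical body; area regime per class (fraction of image area)
    area_rng <- switch(as.character(cl),
      "0" = c(0.010, 0.030),            # aphid: tiny dark
      "2" = c(0.020, 0.060),            # moth: medium
      "3" = c(0.020, 0.060),            # red beetle: medium
      "4" = c(0.010, 0.030))            # whitefly: tiny bright
    afrac <- stats::runif(1, area_rng[1], area_rng[2])
    # box area = afrac * s^2; ellipse inscribed in the box
    asp <- exp(stats::rnorm(1, 0, 0.25))
    bw <- sqrt(afrac * asp) * s
    bh <- sqrt(afrac / asp) * s
    cx <- stats::runif(1, bw / 2 + 1, s - bw / 2 - 1)
    cy <- stats::runif(1, bh / 2 + 1, s - bh / 2 - 1)
    col <- switch(as.character(cl),
      "0" = c(0.10, 0.14, 0.06),
      "2" = c(0.45, 0.34, 0.22),
      "3" = c(0.72, 0.12, 0.10),
      "4" = c(0.96, 0.96, 0.93)) + stats::rnorm(3, 0, 0.02)
    img <- .draw_ellipse(img, cx, cy, bw / 2, bh / 2,
                         pmin(pmax(col, 0), 1), stats::runif(1, 0, pi))
    box <- c(cx, cy, bw, bh) / s
  }
  list(img = img, box = box)
}

#' Generate one labelled synthetic scene
#'
#' @param spec Recipe from [scene_spec()].
#' @param seed Optional seed for full reproducibility of this scene.
#' @return List of class `pd_scene` with `image` (h x w x 3 array in
#'   `[0, 1]`), `labels` (data.frame class/cx/cy/w/h, normalized center
#'   format) and `size`.
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- spec$size
  # leaf-like background: green base + low-frequency modulation + grain
  u <- matrix(seq_len(s), s, s); v <- t(u)
  modf <- spec$texture * (sin(2 * pi * u / s * stats::runif(1, 1, 3) +
                                stats::runif(1, 0, 2 * pi)) +
                          cos(2 * pi * v / s * stats::runif(1, 1, 3) +
                                stats::runif(1, 0, 2 * pi))) / 2
  base <- c(0.32, 0.55, 0.25) * stats::runif(1, 0.85, 1.1)
  img <- array(0, dim = c(s, s, 3))
  for (k in 1:3)
    img[, , k] <- pmin(pmax(base[k] + modf +
      matrix(stats::rnorm(s * s, 0, spec$texture / 3), s, s), 0), 1)
  n_obj <- stats::rpois(1, spec$mean_targets)
  labels <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0))
  placed <- 0L; tries <- 0L
  while (placed < n_obj) {
    tries <- tries + 1L
    if (tries > spec$max_tries + n_obj)
      stop("object placement failed: scene too dense")
    cl <- sample.int(5L, 1, prob = spec$class_mix) - 1L
    res <- .place_object(img, cl, spec)
    if (is.null(res)) next
    img <- res$img
    labels[nrow(labels) + 1L, ] <- c(cl, res$box)
    placed <- placed + 1L
  }
  labels$class <- as.integer(labels$class)
  structure(list(image = img, labels = labels, size = s),
            class = "pd_scene")
}

#' Flip-based augmentation that doubles a scene set
#'
#' Each scene receives exactly one augmented copy; the horizontal and
#' vertical flips are sampled independently with probability 0.5 each, and
#' if both come out as identity a horizontal flip is forced so the copy
#' never duplicates its source. Labels transform as `cx -> 1 - cx`
#' (horizontal) and `cy -> 1 - cy` (vertical).
#'
#' @param scenes List of `pd_scene` objects.
#' @return List of length `2 * length(scenes)`: originals then copies.
#' @export
flip_augment <- function(scenes) {
  aug <- lapply(scenes, function(sc) {
    hf <- stats::runif(1) < 0.5
    vf <- stats::runif(1) < 0.5
    if (!hf && !vf) hf <- TRUE
    flip_scene(sc, hf, vf)
  })
  c(scenes, aug)
}

#' Flip one scene deterministically
#'
#' @param sc A `pd_scene`.
#' @param horizontal,vertical Which flips to apply.
#' @return Flipped `pd_scene`.
#' @export
flip_scene <- function(sc, horizontal = FALSE, vertical = FALSE) {
  img <- sc$image
  lb <- sc$labels
  if (horizontal) {
    img <- img[, dim(img)[2]:1, , drop = FALSE]
    lb$cx <- 1 - lb$cx
  }
  if (vertical) {
    img <- img[dim(img)[1]:1, , , drop = FALSE]
    lb$cy <- 1 - lb$cy
  }
  structure(list(image = img, labels = lb, size = sc$size),
            class = "pd_scene")
}

#' Stratified 8:1:1 split
#'
#' Scenes are split per category before any augmentation: within each class,
#' validation and test each receive `floor(0.1 n)` scenes and the training
#' split takes the rest (floor-then-distribute, so 101 scenes of one class
#' give 81/10/10). No scene appears in two splits.
#'
#' @param classes Integer or factor vector: the category of each scene.
#' @param ratios Split ratios (must sum to 1); default `c(0.8, 0.1, 0.1)`.
#' @param seed Seed for the within-class shuffle.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(classes, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3L)
  set.seed(seed)
  tr <- va <- te <- integer(0)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_va <- floor(ratios[2] * n)
    n_te <- floor(ratios[3] * n)
    n_tr <- n - n_va - n_te             # floors + leftover go to train
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    te <- c(te, idx[n_tr + n_va + seq_len(n_te)])
  }
  list(train = sort(tr), val = sort(va), test = sort(te))
}

# ---- YOLO text I/O ----------------------------------------------------------

#' Write labels of one image in YOLO text format
#'
#' One line per object: `class cx cy w h`, normalized center coordinates.
#'
#' @param labels Data.frame with class/cx/cy/w/h.
#' @param path Output file path.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class, labels$cx,
                   labels$cy, labels$w, labels$h)
  writeLines(lines, path)
}

#' Read YOLO-format labels
#'
#' @param path Label text file.
#' @return Data.frame with class/cx/cy/w/h (0 rows if the file is empty).
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  m <- as.matrix(utils::read.table(path))
  data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write a dataset in the standard YOLO layout
#'
#' Creates `images/{train,val,test}` and `labels/{train,val,test}` under
#' `dir`, plus a `data.yaml` manifest with the class names. Images are
#' written as PNG when the png package is available, otherwise as flat CSV
#' grids (one file per channel row-block).
#'
#' @param scenes List of `pd_scene`.
#' @param split List with train/val/test index vectors from
#'   [split_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_yolo_dataset <- function(scenes, split, dir) {
  for (sp in names(split)) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE,
               showWarnings = FALSE)
    for (i in split[[sp]]) {
      stem <- sprintf("scene_%04d", i)
      sc <- scenes[[i]]
      if (requireNamespace("png", quietly = TRUE)) {
        png::writePNG(sc$image,
                      file.path(dir, "images", sp, paste0(stem, ".png")))
      } else {
        utils::write.csv(matrix(sc$image, nrow = dim(sc$image)[1]),
                         file.path(dir, "images", sp, paste0(stem, ".csv")),
                         row.names = FALSE)
      }
      write_yolo_labels(sc$labels,
                        file.path(dir, "labels", sp, paste0(stem, ".txt")))
    }
  }
  writeLines(c(paste0("path: ", dir), "train: images/train",
               "val: images/val", "test: images/test", "nc: 5",
               paste0("names: [", paste(PEST_CLASSES, collapse = ", "), "]")),
             file.path(dir, "data.yaml"))
  invisible(dir)
}

#' Convert normalized center labels to pixel corner boxes
#'
#' @param labels Data.frame with cx/cy/w/h in `[0, 1]`.
#' @param size Image side in pixels.
#' @return Matrix with columns x1, y1, x2, y2.
#' @export
labels_to_corners <- function(labels, size) {
  cbind(x1 = (labels$cx - labels$w / 2) * size,
        y1 = (labels$cy - labels$h / 2) * size,
        x2 = (labels$cx + labels$w / 2) * size,
        y2 = (labels$cy + labels$h / 2) * size)
}
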