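# Synthetic scene generation, flip augmentation and stratified splitting.

test_that("scene generation is seed-reproducible and respects label bounds", {
  sp <- scene_spec(size = 64)
  a <- generate_scene(sp, seed = 99)
  b <- generate_scene(sp, seed = 99)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)

  set.seed(1)
  for (i in 1:30) {
    sc <- generate_scene(sp)
    if (nrow(sc$labels) == 0) next
    expect_true(all(sc$labels$class %in% 0:4))
    expect_true(all(sc$labels$w > 0 & sc$labels$h > 0))
    expect_true(all(sc$labels$cx - sc$labels$w / 2 >= -1e-9))
    expect_true(all(sc$labels$cx + sc$labels$w / 2 <= 1 + 1e-9))
    expect_true(all(sc$labels$cy - sc$labels$h / 2 >= -1e-9))
    expect_true(all(sc$labels$cy + sc$labels$h / 2 <= 1 + 1e-9))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("object counts follow the configured mean density", {
  set.seed(2)
  sp <- scene_spec(size = 32, mean_targets = 3.5)
  counts <- vapply(1:400, function(i) nrow(generate_scene(sp)$labels),
                   numeric(1))
  se <- sqrt(3.5 / length(counts))
  expect_lt(abs(mean(counts) - 3.5), 3 * se)
})

test_that("whitefly boxes occupy 1-3% of the image area", {
  set.seed(3)
  sp <- scene_spec(size = 96, mean_targets = 4,
                   class_mix = c(0, 0, 0, 0, 1))    # whiteflies only
  areas <- unlist(lapply(1:25, function(i) {
    lb <- generate_scene(sp)$labels
    lb$w * lb$h
  }))
  expect_true(all(areas >= 0.01 - 1e-9 & areas <= 0.03 + 1e-9))
})

test_that("flip augmentation doubles the set with exact label transforms", {
  set.seed(4)
  scenes <- lapply(1:40, function(i)
    generate_scene(scene_spec(size = 16, mean_targets = 2)))
  aug <- flip_augment(scenes)
  expect_length(aug, 80L)

  # deterministic flips: cx -> 1 - cx, cy -> 1 - cy; sizes unchanged
  sc <- scenes[[which(vapply(scenes, function(s) nrow(s$labels) > 0,
                             logical(1)))[1]]]
  hf <- flip_scene(sc, horizontal = TRUE)
  expect_equal(hf$labels$cx, 1 - sc$labels$cx)
  expect_equal(hf$labels$cy, sc$labels$cy)
  expect_equal(hf$labels$w, sc$labels$w)
  # flipping twice restores the original
  expect_equal(flip_scene(hf, horizontal = TRUE), sc)
  vf <- flip_scene(sc, vertical = TRUE)
  expect_equal(flip_scene(vf, vertical = TRUE), sc)

  # per-image counts and class histogram preserved; no copy equals its source
  for (i in seq_along(scenes)) {
    expect_equal(nrow(aug[[40 + i]]$labels), nrow(scenes[[i]]$labels))
    expect_equal(sort(aug[[40 + i]]$labels$class),
                 sort(scenes[[i]]$labels$class))
    expect_false(identical(aug[[40 + i]]$image, scenes[[i]]$image))
  }
})

test_that("the 8:1:1 split is stratified, floor-rounded and leak-free", {
  cls <- rep(0L, 100)
  sp <- split_dataset(cls, seed = 1)
  expect_length(sp$train, 80L)
  expect_length(sp$val, 10L)
  expect_length(sp$test, 10L)

  sp2 <- split_dataset(rep(1L, 101), seed = 2)
  expect_length(sp2$train, 81L)  # floors + leftover to train: 81/10/10
  expect_length(sp2$val, 10L)
  expect_length(sp2$test, 10L)

  for (seed in 1:5) {
    cls <- sample(0:4, 137, replace = TRUE)
    sp3 <- split_dataset(cls, seed = seed)
    all_idx <- c(sp3$train, sp3$val, sp3$test)
    expect_equal(sort(all_idx), seq_along(cls))      # disjoint and complete
    for (cl in unique(cls)) {
      n <- sum(cls == cl)
      expect_equal(sum(cls[sp3$val] == cl), floor(0.1 * n))
      expect_equal(sum(cls[sp3$test] == cl), floor(0.1 * n))
    }
  }
})

test_that("YOLO label text round-trips and the dataset layout is written", {
  lb <- data.frame(class = c(0L, 4L), cx = c(0.25, 0.5), cy = c(0.5, 0.75),
                   w = c(0.1, 0.2), h = c(0.05, 0.1))
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(lb, f)
  back <- read_yolo_labels(f)
  expect_equal(back, lb, tolerance = 1e-6)

  set.seed(6)
  scenes <- lapply(1:10, function(i)
    generate_scene(scene_spec(size = 16), seed = i))
  sp <- split_dataset(rep(0L, 10), seed = 1)
  dir <- tempfile()
  write_yolo_dataset(scenes, sp, dir)
  expect_true(file.exists(file.path(dir, "data.yaml")))
  expect_length(list.files(file.path(dir, "labels", "train")), 8L)
  expect_length(list.files(file.path(dir, "images", "val")), 1L)

  co <- labels_to_corners(lb, 100)
  expect_equal(co[1, ], c(x1 = 20, y1 = 47.5, x2 = 30, y2 = 52.5))
})
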