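test_that("binarize marks exactly the pixels above threshold", {
  expect_false(any(binarize(gray_image(matrix(0, 8, 8)), threshold = 10,
                            smooth_sigma = 0)))
  img <- rect_image(rows = 3:6, cols = 2:5, value = 200)
  mask <- binarize(img, threshold = 100, smooth_sigma = 0)
  expect_identical(unclass(mask), img$pixels > 100)
  expect_true(all(binarize(gray_image(matrix(255, 6, 6)), threshold = 254,
                           smooth_sigma = 0)))
  expect_error(binarize(img, threshold = 300), "range")
  expect_error(gray_image(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("morph_clean is identity at zero iterations and opens solids", {
  img <- rect_image()
  mask <- binarize(img, 100, smooth_sigma = 0)
  expect_identical(morph_clean(mask, 0, 0), mask)
  # single isolated pixel vanishes under one erosion
  single <- binarize(rect_image(rows = 5, cols = 5), 100, smooth_sigma = 0)
  expect_false(any(morph_clean(single, 1, 0)))
  # opening recovers a solid convex square
  sq <- binarize(rect_image(20, 20, rows = 6:15, cols = 6:15), 100,
                 smooth_sigma = 0)
  expect_identical(morph_clean(sq, 1, 1), sq)
  # area of a convex solid unchanged under equal erode/dilate counts
  for (it in 1:2) expect_equal(sum(morph_clean(sq, it, it)), sum(sq))
  expect_error(morph_clean(mask, -1, 0), "non-negative")
})

test_that("largest_component_contour returns the biggest component's border", {
  # oracle: border pixels of a filled block computed by set arithmetic
  block_border <- function(rows, cols) {
    pts <- expand.grid(row = rows, col = cols)
    keep <- pts$row %in% range(rows) | pts$col %in% range(cols)
    pts <- pts[keep, ]
    m <- as.matrix(pts[order(pts$row, pts$col), ])
    dimnames(m) <- list(NULL, c("row", "col"))
    m
  }
  mask <- binarize(rect_image(12, 12, rows = 4:8, cols = 3:7), 100, 0)
  expect_equal(largest_component_contour(mask),
               block_border(3:7, 2:6))  # 0-based
  # larger of two components wins
  px <- matrix(0, 15, 15)
  px[2:7, 2:7] <- 200   # 6x6
  px[11:12, 11:12] <- 200  # 2x2
  cont <- largest_component_contour(binarize(gray_image(px), 100, 0))
  expect_true(all(cont[, "row"] <= 6))
  expect_equal(nrow(cont), 20)  # 6x6 block has 20 border pixels
  # degenerate single-pixel component
  single <- binarize(rect_image(rows = 5, cols = 7), 100, 0)
  expect_equal(largest_component_contour(single),
               cbind(row = 4L, col = 6L))
  expect_error(largest_component_contour(
    binarize(gray_image(matrix(0, 4, 4)), 10, 0)), "no foreground")
})

test_that("find_extreme_points picks min/max row and column points", {
  mask <- binarize(rect_image(12, 12, rows = 3:8, cols = 4:10), 100, 0)
  ep <- find_extreme_points(largest_component_contour(mask))
  expect_equal(ep$top[["row"]], 2)
  expect_equal(ep$bottom[["row"]], 7)
  expect_equal(ep$left[["col"]], 3)
  expect_equal(ep$right[["col"]], 9)
  # degenerate single point
  ep1 <- find_extreme_points(cbind(row = 4L, col = 4L))
  for (nm in c("left", "right", "top", "bottom")) {
    expect_equal(unname(ep1[[nm]]), c(4, 4))
  }
  # rasterized disk: left/right separated by 2r columns
  r <- 9
  px <- matrix(0, 30, 30)
  rows <- matrix(1:30, 30, 30); cols <- t(rows)
  px[(rows - 15)^2 + (cols - 15)^2 <= r^2] <- 200
  epd <- find_extreme_points(
    largest_component_contour(binarize(gray_image(px), 100, 0)))
  expect_equal(epd$right[["col"]] - epd$left[["col"]], 2 * r)
  expect_error(find_extreme_points(matrix(numeric(0), 0, 2)), "empty")
})

test_that("crop_to_extremes uses inclusive bounds with clipped margins", {
  img <- rect_image()
  full <- find_extreme_points(cbind(row = c(0L, 19L), col = c(0L, 19L)))
  expect_equal(crop_to_extremes(img, full, 0)$pixels, img$pixels)
  ep <- find_extreme_points(cbind(row = c(5L, 9L, 7L, 7L),
                                  col = c(8L, 8L, 6L, 12L)))
  expect_equal(dim(crop_to_extremes(img, ep, 0)), c(5, 7))
  # margin clipped at the border, no error
  near <- find_extreme_points(cbind(row = c(0L, 3L), col = c(0L, 3L)))
  expect_equal(dim(crop_to_extremes(img, near, 2)), c(6, 6))
  bad <- find_extreme_points(cbind(row = c(0L, 25L), col = c(0L, 3L)))
  expect_error(crop_to_extremes(img, bad, 0), "bounds")
})

test_that("extreme-point crop recovers 50 random rectangles exactly", {
  set.seed(42)
  for (i in 1:50) {
    h <- sample(15:40, 1); w <- sample(15:40, 1)
    r0 <- sample(1:(h - 5), 1); r1 <- sample((r0 + 1):min(r0 + 10, h), 1)
    c0 <- sample(1:(w - 5), 1); c1 <- sample((c0 + 1):min(c0 + 10, w), 1)
    img <- rect_image(h, w, rows = r0:r1, cols = c0:c1)
    out <- crop_brain(img, threshold = 100, smooth_sigma = 0,
                      erode_iters = 0, dilate_iters = 0, margin = 0)
    expect_equal(out$pixels, img$pixels[r0:r1, c0:c1, drop = FALSE])
  }
})

test_that("bicubic resize maps constants to constants at the target shape", {
  const <- resize_bicubic(gray_image(matrix(100, 13, 9)), 224, 224)
  expect_equal(dim(const), c(224, 224))
  expect_true(all(abs(const$pixels - 100) < 1e-9))
  expect_equal(dim(resize_bicubic(rect_image(), 299, 299)), c(299, 299))
  # downscale preserves a smooth gradient's ordering
  g <- gray_image(matrix(rep(seq(0, 255, length.out = 40), each = 40),
                         40, 40))
  small <- resize_bicubic(g, 10, 10)
  expect_true(all(diff(small$pixels[5, ]) > 0))
  expect_error(resize_bicubic(g, 0, 10), "positive")
})

test_that("dihedral augmentation forms the closed 8-element group", {
  a <- augment_dihedral(asym_image(), "exhaustive")
  expect_length(a, 8)
  mats <- lapply(a, function(i) i$pixels)
  expect_equal(length(unique(mats)), 8)  # pairwise distinct on asymmetric
  # rot90^4 = identity, flip^2 = identity
  expect_identical(mats$rot0, asym_image()$pixels)
  expect_identical(a$rot0$pixels,
                   augment_dihedral(a$rot270, "exhaustive")$rot90$pixels)
  flip_twice <- augment_dihedral(a$rot0_flip,
                                 "exhaustive")$rot0_flip$pixels
  expect_identical(flip_twice, asym_image()$pixels)
  # closure: transforming every variant again yields only the original 8
  for (v in a) {
    again <- augment_dihedral(v, "exhaustive")
    for (w in again) {
      expect_true(any(vapply(mats, identical, logical(1), w$pixels)))
    }
  }
  # random mode is seeded and reproducible
  r1 <- augment_dihedral(asym_image(), "random", seed = 5)
  r2 <- augment_dihedral(asym_image(), "random", seed = 5)
  expect_identical(r1, r2)
  expect_length(r1, 1)
})

test_that("split_dataset floors the train size and partitions the ids", {
  ids <- sprintf("s%04d", 1:3000)
  sp <- split_dataset(ids, rep(c("n", "t"), 1500), 0.8, seed = 3)
  expect_length(sp$train_ids, 2400)
  expect_length(sp$test_ids, 600)
  sp2 <- split_dataset(sprintf("s%d", 1:253),
                       rep(c("n", "t"), length.out = 253), 0.8, seed = 3)
  expect_length(sp2$train_ids, 202)
  expect_length(sp2$test_ids, 51)
  sp3 <- split_dataset(letters[1:10], rep(1:2, 5), 0.8, seed = 3)
  expect_length(sp3$train_ids, 8)
  # partition properties and determinism
  expect_setequal(c(sp2$train_ids, sp2$test_ids), sprintf("s%d", 1:253))
  expect_length(intersect(sp2$train_ids, sp2$test_ids), 0)
  again <- split_dataset(sprintf("s%d", 1:253),
                         rep(c("n", "t"), length.out = 253), 0.8, seed = 3)
  expect_identical(sp2, again)
  expect_error(split_dataset("a", "x", 0.8, 1), "at least 2")
  expect_error(split_dataset(letters[1:4], rep(1, 4), 1.2, 1), "\\(0, 1\\)")
})

test_that("stratified splits preserve class proportions within rounding", {
  labels <- rep(c("n", "g", "m", "p"), c(100, 60, 30, 10))
  ids <- sprintf("s%03d", seq_along(labels))
  sp <- split_dataset(ids, labels, 0.8, seed = 11, stratified = TRUE)
  expect_length(sp$train_ids, 160)
  tr_lab <- labels[match(sp$train_ids, ids)]
  for (cl in unique(labels)) {
    expect_lte(abs(sum(tr_lab == cl) - 0.8 * sum(labels == cl)), 1)
  }
})
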