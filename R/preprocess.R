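#' Threshold a grayscale image into a binary mask
#'
#' Optionally smooths the image with an isotropic Gaussian filter, then marks
#' as foreground every pixel whose (smoothed) intensity strictly exceeds the
#' threshold. This is the first step of the extreme-point cropping recipe:
#' the bright brain region is separated from the dark scanner background.
#'
#' @param image a [gray_image()].
#' @param threshold intensity cut, on the image's declared scale. The
#'   default 45 suits 8-bit MR images with near-black background.
#' @param smooth_sigma standard deviation (in pixels) of the Gaussian
#'   pre-smoothing; 0 disables smoothing. Default 2.
#' @return A logical matrix of class `binary_mask` with the image's shape.
#' @export
binarize <- function(image, threshold = 45, smooth_sigma = 2) {
  stopifnot(is_gray_image(image))
  if (threshold < 0 || threshold > image$max_value) {
    stop("invalid input: threshold outside declared intensity range",
         call. = FALSE)
  }
  px <- image$pixels
  if (smooth_sigma > 0) {
    size <- 2L * as.integer(ceiling(2 * smooth_sigma)) + 1L
    # EBImage requires the filter to fit inside the image
    size <- min(size, 2L * (min(dim(px)) %/% 2L) - 1L)
    if (size >= 3L) {
      brush <- EBImage::makeBrush(size, shape = "Gaussian",
                                  sigma = smooth_sigma)
      px <- EBImage::filter2(px, brush, boundary = "replicate")
    }
  }
  structure(px > threshold, class = "binary_mask", dim = dim(px))
}

as_binary_mask <- function(m) {
  stopifnot(is.matrix(m))
  structure(m != 0, class = "binary_mask", dim = dim(m))
}

#' Morphologically clean a binary mask
#'
#' Applies `erode_iters` erosions followed by `dilate_iters` dilations with a
#' 3x3 box structuring element, removing small speckle and thin bridges
#' before the largest contour is traced. Zero iterations of both is the
#' identity.
#'
#' @param mask a `binary_mask` from [binarize()].
#' @param erode_iters,dilate_iters non-negative iteration counts
#'   (defaults 2 and 2).
#' @return A cleaned `binary_mask`.
#' @export
morph_clean <- function(mask, erode_iters = 2, dilate_iters = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (erode_iters < 0 || dilate_iters < 0) {
    stop("invalid input: iteration counts must be non-negative",
         call. = FALSE)
  }
  m <- unclass(mask) * 1
  kern <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(erode_iters)) m <- EBImage::erode(m, kern)
  for (i in seq_len(dilate_iters)) m <- EBImage::dilate(m, kern)
  as_binary_mask(m)
}

#' Boundary of the largest connected foreground component
#'
#' Labels the connected foreground components, keeps the one with the
#' greatest pixel area (ties broken by lowest label, i.e. scan order), and
#' returns its boundary pixels: component pixels with at least one
#' 4-neighbour outside the component (image borders count as outside).
#'
#' @param mask a `binary_mask` with at least one foreground pixel.
#' @return An integer matrix with columns `row`, `col` (0-based), ordered by
#'   row then column; deterministic for a fixed mask.
#' @export
largest_component_contour <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- unclass(mask)
  if (!any(m)) stop("no foreground pixels in mask", call. = FALSE)
  lab <- EBImage::bwlabel(m * 1)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)            # ties -> lowest label
  comp <- lab == keep
  nr <- nrow(comp); nc <- ncol(comp)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- comp & !inner
  idx <- which(boundary, arr.ind = TRUE)
  pts <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  rownames(pts) <- NULL
  pts[order(pts[, "row"], pts[, "col"]), , drop = FALSE]
}

#' Extreme points of a contour
#'
#' The leftmost, rightmost, topmost and bottommost contour pixels, which
#' define the crop box around the brain region. Ties are broken by lowest
#' row then lowest column.
#'
#' @param contour integer matrix of 0-based `(row, col)` points, as returned
#'   by [largest_component_contour()].
#' @return An object of class `extreme_points`: a list with `left`, `right`,
#'   `top`, `bottom`, each a named `c(row, col)` pair.
#' @export
find_extreme_points <- function(contour) {
  if (is.null(dim(contour)) || nrow(contour) < 1L) {
    stop("invalid input: empty contour", call. = FALSE)
  }
  r <- contour[, 1L]; cc <- contour[, 2L]
  pick <- function(keep) {
    i <- which(keep)
    i <- i[order(r[i], cc[i])][1L]
    c(row = r[i], col = cc[i])
  }
  structure(list(
    left   = pick(cc == min(cc)),
    right  = pick(cc == max(cc)),
    top    = pick(r == min(r)),
    bottom = pick(r == max(r))
  ), class = "extreme_points")
}

#' @export
print.extreme_points <- function(x, ...) {
  cat("<extreme_points>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-6s (row %d, col %d)\n", nm, x[[nm]]["row"],
                x[[nm]]["col"]))
  }
  invisible(x)
}

#' Crop an image to its extreme points
#'
#' Extracts the sub-image spanning rows `top.row - margin` to
#' `bottom.row + margin` and columns `left.col - margin` to
#' `right.col + margin`, inclusive at both ends and clipped to the image
#' bounds.
#'
#' @param image a [gray_image()].
#' @param ep an `extreme_points` object whose points lie within the image.
#' @param margin non-negative pixel margin added on every side (default 0).
#' @return The cropped `gray_image`.
#' @export
crop_to_extremes <- function(image, ep, margin = 0) {
  stopifnot(is_gray_image(image), inherits(ep, "extreme_points"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  rows <- c(ep$top["row"], ep$bottom["row"])
  cols <- c(ep$left["col"], ep$right["col"])
  if (any(rows < 0) || any(rows > nr - 1L) ||
      any(cols < 0) || any(cols > nc - 1L)) {
    stop("invalid input: extreme points outside image bounds", call. = FALSE)
  }
  r0 <- max(0L, rows[1L] - margin); r1 <- min(nr - 1L, rows[2L] + margin)
  c0 <- max(0L, cols[1L] - margin); c1 <- min(nc - 1L, cols[2L] + margin)
  gray_image(image$pixels[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L),
                          drop = FALSE],
             max_value = image$max_value)
}

# Bicubic convolution kernel (Keys, a = -0.5), the classical photographic
# resampling kernel; weights over the 4 taps sum to 1 exactly.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# target_n x source_n row-weight matrix for separable bicubic resampling
# with half-pixel centre alignment and border replication.
bicubic_weights <- function(target_n, source_n) {
  scale <- source_n / target_n
  W <- matrix(0, target_n, source_n)
  for (i in seq_len(target_n)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    base <- floor(src)
    taps <- base + (-1:2)
    w <- cubic_kernel(src - taps)
    taps <- pmin(pmax(taps, 0), source_n - 1L)  # replicate borders
    for (k in 1:4) W[i, taps[k] + 1L] <- W[i, taps[k] + 1L] + w[k]
  }
  W
}

#' Resize an image by bicubic interpolation
#'
#' Separable bicubic convolution (Keys kernel, a = -0.5) with half-pixel
#' centre alignment and replicated borders. A constant image maps to the
#' same constant at any target size. Outputs are clipped to the declared
#' intensity range (bicubic over/undershoot).
#'
#' @param image a [gray_image()].
#' @param target_h,target_w positive output dimensions. Backbone-style
#'   pipelines typically use 224 x 224 (299 x 299 for Inception-type
#'   extractors).
#' @return A `gray_image` of shape `target_h` x `target_w`.
#' @export
resize_bicubic <- function(image, target_h, target_w) {
  stopifnot(is_gray_image(image))
  if (target_h < 1 || target_w < 1) {
    stop("invalid input: target dimensions must be positive", call. = FALSE)
  }
  px <- image$pixels
  Wr <- bicubic_weights(as.integer(target_h), nrow(px))
  Wc <- bicubic_weights(as.integer(target_w), ncol(px))
  out <- Wr %*% px %*% t(Wc)
  out <- pmin(pmax(out, 0), image$max_value)
  gray_image(out, max_value = image$max_value)
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
flip_horizontal <- function(m) m[, ncol(m):1, drop = FALSE]

#' Dihedral augmentation: 90-degree rotations and horizontal flips
#'
#' The augmentation group of a raster image: rotations by 0/90/180/270
#' degrees, each with and without horizontal flipping (8 variants, the
#' dihedral group of the square). `mode = "exhaustive"` returns all 8 in a
#' fixed order (for k in 0..3: unflipped then flipped); `mode = "random"`
#' draws one variant (a uniformly random rotation count and flip) under the
#' given seed, mimicking on-the-fly training augmentation.
#'
#' @param image a [gray_image()].
#' @param mode `"exhaustive"` or `"random"`.
#' @param seed integer seed, used by `"random"` mode.
#' @return A named list of `gray_image`s (length 8, or 1 in random mode).
#' @export
augment_dihedral <- function(image, mode = c("exhaustive", "random"),
                             seed = 1L) {
  stopifnot(is_gray_image(image))
  mode <- match.arg(mode)
  variant <- function(k, flip) {
    m <- image$pixels
    for (i in seq_len(k)) m <- rot90_ccw(m)
    if (flip) m <- flip_horizontal(m)
    gray_image(m, max_value = image$max_value)
  }
  if (mode == "exhaustive") {
    out <- list()
    for (k in 0:3) {
      out[[sprintf("rot%d", 90 * k)]] <- variant(k, FALSE)
      out[[sprintf("rot%d_flip", 90 * k)]] <- variant(k, TRUE)
    }
    out
  } else {
    kf <- with_seed(seed, c(sample.int(4L, 1L) - 1L, sample.int(2L, 1L) - 1L))
    nm <- sprintf("rot%d%s", 90 * kf[1L], if (kf[2L]) "_flip" else "")
    stats::setNames(list(variant(kf[1L], kf[2L] == 1L)), nm)
  }
}

#' Full extreme-point crop pipeline
#'
#' Convenience wrapper running [binarize()], [morph_clean()],
#' [largest_component_contour()], [find_extreme_points()] and
#' [crop_to_extremes()] in sequence, optionally followed by
#' [resize_bicubic()].
#'
#' @param image a [gray_image()].
#' @param threshold,smooth_sigma passed to [binarize()].
#' @param erode_iters,dilate_iters passed to [morph_clean()].
#' @param margin passed to [crop_to_extremes()].
#' @param target_size optional `c(h, w)`; when given the crop is resized.
#' @return A cropped (and possibly resized) `gray_image`.
#' @export
crop_brain <- function(image, threshold = 45, smooth_sigma = 2,
                       erode_iters = 2, dilate_iters = 2, margin = 0,
                       target_size = NULL) {
  mask <- morph_clean(binarize(image, threshold, smooth_sigma),
                      erode_iters, dilate_iters)
  ep <- find_extreme_points(largest_component_contour(mask))
  out <- crop_to_extremes(image, ep, margin)
  if (!is.null(target_size)) {
    out <- resize_bicubic(out, target_size[1L], target_size[2L])
  }
  out
}
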