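#' Grayscale image container
#'
#' A minimal container for a 2-D grayscale intensity grid together with its
#' declared intensity range. Pixel `[i, j]` is image row `i` (top to bottom)
#' and column `j` (left to right); coordinates reported by contour and
#' extreme-point operations are 0-based `(row, col)` pairs.
#'
#' @param pixels numeric matrix of intensities.
#' @param max_value upper bound of the declared intensity range (255 for
#'   8-bit images, 1 for unit-scaled images). The lower bound is always 0.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, max_value = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("invalid input: image must have at least one row and column",
         call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("invalid input: image intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > max_value)) {
    stop("invalid input: intensities outside declared range [0, ",
         max_value, "]", call. = FALSE)
  }
  structure(list(pixels = pixels, max_value = max_value),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [0, %s]>\n",
              nrow(x$pixels), ncol(x$pixels), format(x$max_value)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

#' Read and write grayscale PNG images
#'
#' 8-bit grayscale PNG input/output. Colour PNGs are converted to grayscale
#' by channel averaging on read.
#'
#' @param path file path.
#' @param image a [gray_image()].
#' @return `read_gray_png()` returns a `gray_image` on the 0-255 scale;
#'   `write_gray_png()` returns `path` invisibly.
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3])],
                                           c(1L, 2L), mean)
  gray_image(round(arr * 255), max_value = 255)
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is_gray_image(image))
  png::writePNG(image$pixels / image$max_value, target = path)
  invisible(path)
}

#' Read one 2-D slice of a NIfTI volume as a grayscale image
#'
#' Optional adapter for NIfTI input; requires the RNifti package. The slice
#' is min-max rescaled to 0-255.
#'
#' @param path NIfTI file path.
#' @param slice axial slice index (third dimension); defaults to the middle
#'   slice.
#' @return A `gray_image` on the 0-255 scale.
#' @export
read_nifti_slice <- function(path, slice = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input", call. = FALSE)
  }
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 2L) {
    sl <- arr
  } else {
    if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
    sl <- arr[, , slice]
  }
  rng <- range(sl)
  px <- if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) * 255 else sl * 0
  gray_image(px, max_value = 255)
}
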