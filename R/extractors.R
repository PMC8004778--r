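#' Architecture family of a feature extractor
#'
#' Maps an extractor id to its design lineage by normalising the name and
#' stripping depth/width/version suffixes, so that e.g. `densenet121` and
#' `densenet169` share the family `densenet` while `vgg16` and `alexnet` do
#' not. Two extractors from one family ("homogeneous" models) are assumed to
#' span redundant feature spaces, which the selection rule exploits. The 13
#' standard backbone ids partition into 9 families: resnet, densenet, vgg,
#' alexnet, inception, resnext, shufflenet, mobilenet, mnasnet.
#'
#' @param extractor_id extractor name (case and separators ignored).
#' @return The family label; an unknown id is returned unchanged as its own
#'   singleton family (with a message).
#' @export
family_of <- function(extractor_id) {
  stopifnot(is.character(extractor_id), nchar(extractor_id) > 0)
  vapply(extractor_id, function(id) {
    s <- gsub("[^a-z0-9]", "", tolower(id))
    base <- sub("(v?[0-9]+)+$", "", s)
    known <- c("resnet", "densenet", "vgg", "alexnet", "inception",
               "resnext", "shufflenet", "mobilenet", "mnasnet")
    # longest known prefix wins, so "resnext50" is resnext, not resnet
    hit <- known[vapply(known, function(k) startsWith(base, k), logical(1))]
    if (length(hit) > 0) {
      hit[which.max(nchar(hit))]
    } else if (base %in% known) {
      base
    } else {
      message("family_of: unknown extractor '", id,
              "' treated as its own family")
      id
    }
  }, character(1), USE.NAMES = FALSE)
}

#' The 13 standard backbone extractor ids
#'
#' Identifiers for the frozen ImageNet-pretrained backbones commonly used as
#' deep-feature extractors for brain-MR classification benchmarks.
#'
#' @return Character vector of 13 extractor ids.
#' @export
backbone_ids <- function() {
  c("resnet50", "resnet101", "densenet121", "densenet169", "vgg16",
    "vgg19", "alexnet", "inception_v3", "resnext50", "resnext101",
    "shufflenet_v2", "mobilenet_v2", "mnasnet")
}

#' Specify a feature extractor
#'
#' Extractors are pluggable: the built-in "toy" kinds are cheap,
#' deterministic image summaries used for testing and simulation, while
#' `backbone_adapter` wires in a user-supplied function (e.g. a frozen
#' pretrained CNN called through an external runtime) behind the same
#' interface. The core pipeline never requires downloaded weights.
#'
#' Toy kinds:
#' \describe{
#'   \item{`toy_histogram`}{normalised intensity histogram (`bins` bins over
#'     the declared range); invariant under rotations and flips.}
#'   \item{`toy_blockmean`}{mean intensity over a `grid x grid` partition of
#'     the image (d = grid^2).}
#'   \item{`toy_randproj`}{seeded Gaussian random projection of the
#'     flattened image to `dim` components; requires `seed` and a fixed
#'     `input_size`.}
#' }
#'
#' @param extractor_id name; also determines the default family.
#' @param kind one of `"toy_histogram"`, `"toy_blockmean"`,
#'   `"toy_randproj"`, `"backbone_adapter"`.
#' @param input_size `c(h, w)` the images must have been resized to; `NULL`
#'   skips the size check (histogram features are size-agnostic).
#' @param bins histogram bin count (`toy_histogram`).
#' @param grid block grid side (`toy_blockmean`).
#' @param dim output dimension (`toy_randproj`).
#' @param seed integer seed (`toy_randproj`; required).
#' @param family family label override.
#' @param fn function `(images) -> matrix` for `backbone_adapter`.
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(extractor_id,
                           kind = c("toy_histogram", "toy_blockmean",
                                    "toy_randproj", "backbone_adapter"),
                           input_size = NULL, bins = 16L, grid = 4L,
                           dim = 32L, seed = NULL,
                           family = family_of(extractor_id), fn = NULL) {
  kind <- match.arg(kind)
  if (!is.null(input_size) && any(input_size < 1)) {
    stop("invalid input: input_size must be positive", call. = FALSE)
  }
  if (kind == "toy_randproj") {
    if (is.null(seed)) {
      stop("invalid input: toy_randproj requires a seed", call. = FALSE)
    }
    if (is.null(input_size)) {
      stop("invalid input: toy_randproj requires a fixed input_size",
           call. = FALSE)
    }
  }
  if (kind == "backbone_adapter" && !is.function(fn)) {
    stop("invalid input: backbone_adapter requires `fn`", call. = FALSE)
  }
  structure(list(extractor_id = extractor_id, kind = kind,
                 input_size = input_size, bins = as.integer(bins),
                 grid = as.integer(grid), dim = as.integer(dim),
                 seed = seed, family = family, fn = fn),
            class = "extractor_spec")
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf("<extractor_spec '%s' (%s, family %s)>\n",
              x$extractor_id, x$kind, x$family))
  invisible(x)
}

#' Extract features from a list of images
#'
#' Applies the extractor to every image and assembles a [feature_table()].
#' Extraction is a pure function of (spec, images): repeated calls are
#' bit-identical (backbone weights are frozen; toy extractors are seeded).
#'
#' @param spec an [extractor_spec()].
#' @param images list of [gray_image()]s, all matching `spec$input_size`
#'   when one is declared.
#' @param ids,labels sample ids and class labels aligned with `images`.
#' @return A `feature_table` with one row per image.
#' @export
extract_features <- function(spec, images, ids, labels) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (length(images) < 1L) {
    stop("invalid input: no images", call. = FALSE)
  }
  if (length(ids) != length(images) || length(labels) != length(images)) {
    stop("invalid input: ids/labels must align with images", call. = FALSE)
  }
  if (!is.null(spec$input_size)) {
    ok <- vapply(images, function(im) {
      all(dim(im$pixels) == spec$input_size)
    }, logical(1))
    if (!all(ok)) {
      stop("invalid input: image size does not match spec input_size",
           call. = FALSE)
    }
  }
  vals <- switch(spec$kind,
    toy_histogram = t(vapply(images, function(im) {
      breaks <- seq(0, im$max_value, length.out = spec$bins + 1L)
      h <- hist(as.vector(im$pixels), breaks = breaks, plot = FALSE,
                right = TRUE, include.lowest = TRUE)
      h$counts / length(im$pixels)
    }, numeric(spec$bins))),
    toy_blockmean = t(vapply(images, function(im) {
      px <- im$pixels
      ri <- factor(ceiling(seq_len(nrow(px)) / nrow(px) * spec$grid),
                   levels = seq_len(spec$grid))
      ci <- factor(ceiling(seq_len(ncol(px)) / ncol(px) * spec$grid),
                   levels = seq_len(spec$grid))
      as.vector(t(tapply(px, list(ri[row(px)], ci[col(px)]), mean)))
    }, numeric(spec$grid^2))),
    toy_randproj = {
      p <- prod(spec$input_size)
      proj <- with_seed(spec$seed,
                        matrix(stats::rnorm(p * spec$dim) / sqrt(p),
                               p, spec$dim))
      flat <- t(vapply(images, function(im) as.vector(im$pixels),
                       numeric(p)))
      flat %*% proj
    },
    backbone_adapter = {
      out <- spec$fn(images)
      if (!is.matrix(out) || nrow(out) != length(images)) {
        stop("backbone adapter must return one feature row per image",
             call. = FALSE)
      }
      out
    }
  )
  feature_table(vals, spec$extractor_id, spec$family, ids, labels)
}
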