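#' Configure the phantom image generator
#'
#' Phantoms emulate the geometry the crop pipeline assumes in 2-D brain MR
#' slices: a dark background with padding, a mid-intensity filled ellipse
#' (the "brain") at a jittered centre, an optional hyperintense blob (the
#' "tumor") whose presence/position regime encodes the class, and additive
#' Gaussian noise. The 2-class scheme is normal vs tumor; the 4-class
#' scheme distinguishes normal, glioma (one large off-centre blob),
#' meningioma (a blob hugging the brain edge) and pituitary (a small
#' central blob) — a geometric convention with no claim of radiological
#' realism.
#'
#' @param image_size `c(h, w)` in pixels (default 128 x 128).
#' @param classes 2 or 4.
#' @param brain_intensity ellipse intensity (default 120 of 255).
#' @param brain_axes_range range of ellipse semi-axes as a fraction of the
#'   half image size (default `c(0.45, 0.6)`).
#' @param tumor_intensity additive blob brightness (default 80).
#' @param tumor_radius_range blob radius range in pixels (default
#'   `c(6, 12)`).
#' @param noise_sd Gaussian noise standard deviation (default 8).
#' @param border_pad guaranteed dark border in pixels so the crop stage has
#'   work to do (default 16).
#' @param seed master seed for the dataset.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(128L, 128L), classes = 2L,
                           brain_intensity = 120, brain_axes_range = c(0.45, 0.6),
                           tumor_intensity = 80, tumor_radius_range = c(6, 12),
                           noise_sd = 8, border_pad = 16L, seed = 1L) {
  if (!classes %in% c(2L, 4L)) {
    stop("invalid config: classes must be 2 or 4", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("invalid config: noise_sd must be >= 0", call. = FALSE)
  }
  min_half <- (min(image_size) / 2 - border_pad)
  if (max(tumor_radius_range) >= min_half * min(brain_axes_range)) {
    stop("invalid config: tumor does not fit inside the brain ellipse",
         call. = FALSE)
  }
  if (brain_intensity + tumor_intensity > 255) {
    stop("invalid config: intensities exceed the 8-bit range",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 classes = as.integer(classes),
                 brain_intensity = brain_intensity,
                 brain_axes_range = brain_axes_range,
                 tumor_intensity = tumor_intensity,
                 tumor_radius_range = tumor_radius_range,
                 noise_sd = noise_sd, border_pad = as.integer(border_pad),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_classes <- function(config) {
  if (config$classes == 2L) c("normal", "tumor")
  else c("normal", "glioma", "meningioma", "pituitary")
}

#' Generate one phantom image
#'
#' Deterministic per `(config, class_label, instance_seed)`.
#'
#' @param config a [phantom_config()].
#' @param class_label one of the config's class labels (`"normal"`,
#'   `"tumor"` for 2 classes; `"normal"`, `"glioma"`, `"meningioma"`,
#'   `"pituitary"` for 4).
#' @param instance_seed per-image seed.
#' @return A [gray_image()] on the 0-255 scale.
#' @export
generate_phantom <- function(config, class_label, instance_seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (!class_label %in% phantom_classes(config)) {
    stop("invalid input: unknown class label '", class_label, "'",
         call. = FALSE)
  }
  h <- config$image_size[1L]; w <- config$image_size[2L]
  seed <- derive_seed(config$seed, paste0(class_label, "#", instance_seed))
  px <- with_seed(seed, {
    cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
    ax_r <- stats::runif(2, config$brain_axes_range[1L],
                         config$brain_axes_range[2L])
    a <- ax_r[1L] * (h / 2 - config$border_pad)   # semi-axis, rows
    b <- ax_r[2L] * (w / 2 - config$border_pad)   # semi-axis, cols
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
    img <- matrix(0, h, w)
    img[inside] <- config$brain_intensity
    if (class_label != "normal") {
      r <- stats::runif(1, config$tumor_radius_range[1L],
                        config$tumor_radius_range[2L])
      # blob centre regime encodes the class
      offset_frac <- switch(class_label,
                            tumor = stats::runif(1, 0, 0.5),
                            glioma = stats::runif(1, 0.3, 0.5),
                            meningioma = stats::runif(1, 0.65, 0.8),
                            pituitary = stats::runif(1, 0, 0.1))
      if (class_label == "pituitary") r <- max(3, r / 2)
      theta <- stats::runif(1, 0, 2 * pi)
      ty <- cy + offset_frac * (a - r) * sin(theta)
      tx <- cx + offset_frac * (b - r) * cos(theta)
      blob <- (rows - ty)^2 + (cols - tx)^2 <= r^2
      img[blob & inside] <- img[blob & inside] + config$tumor_intensity
    }
    if (config$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    }
    pmin(pmax(img, 0), 255)
  })
  gray_image(px, max_value = 255)
}

#' Generate a balanced phantom dataset
#'
#' `n_per_class` images per class with distinct instance seeds derived from
#' the config's master seed; labels are exactly balanced by construction.
#'
#' @param config a [phantom_config()].
#' @param n_per_class images per class (>= 1).
#' @return List with `images` (list of `gray_image`), `ids`, `labels`.
#' @export
generate_phantom_dataset <- function(config, n_per_class) {
  stopifnot(inherits(config, "phantom_config"), n_per_class >= 1L)
  classes <- phantom_classes(config)
  images <- list(); ids <- character(0); labels <- character(0)
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      images[[length(images) + 1L]] <- generate_phantom(config, cl, i)
      ids <- c(ids, sprintf("%s_%03d", cl, i))
      labels <- c(labels, cl)
    }
  }
  list(images = images, ids = ids, labels = labels)
}

#' Configure and generate a synthetic feature bank
#'
#' Emulates the statistical structure of a bank of per-extractor deep
#' feature tables: for each extractor, features are class-conditional
#' Gaussians in which the informative axes carry a class-mean pattern with
#' separation `class_separation` (in noise-sd units) and all other axes
#' are pure noise. Extractors sharing a family share the same class-mean
#' pattern and informative subspace (up to a small jitter), emulating the
#' redundancy of homogeneous architectures that the selection rule's
#' family exclusion targets. All tables are row-aligned.
#'
#' Each extractor entry is a list with fields `id`, `family` (defaults to
#' [family_of()]), `dim`, `informative_axes`, `class_separation`,
#' `noise_sd` (default 1) and optional `class_pattern`, a
#' `n_classes x length(informative_axes)` matrix of class means in sd
#' units overriding the family default — this is how complementary
#' extractors (each separating a different class boundary) are built.
#'
#' @param n_samples total sample count (balanced over classes).
#' @param n_classes number of classes.
#' @param extractors list of extractor entries (above).
#' @param seed master seed.
#' @return List of row-aligned [feature_table()]s, one per extractor.
#' @export
generate_feature_bank <- function(n_samples, n_classes, extractors,
                                  seed = 1L) {
  stopifnot(n_samples >= n_classes, n_classes >= 2L)
  classes <- paste0("class", seq_len(n_classes))
  labels <- rep(classes, length.out = n_samples)
  labels <- labels[order(labels)]
  ids <- sprintf("s%04d", seq_len(n_samples))
  lapply(extractors, function(ex) {
    stopifnot(!is.null(ex$id), !is.null(ex$dim),
              !is.null(ex$informative_axes),
              !is.null(ex$class_separation))
    if (ex$class_separation < 0 ||
        any(ex$informative_axes > ex$dim | ex$informative_axes < 1)) {
      stop("invalid config: bad extractor entry '", ex$id, "'",
           call. = FALSE)
    }
    fam <- ex$family %||% family_of(ex$id)
    noise_sd <- ex$noise_sd %||% 1
    n_inf <- length(ex$informative_axes)
    pattern <- ex$class_pattern %||% with_seed(
      derive_seed(seed, paste0("family:", fam)), {
        p <- matrix(stats::rnorm(n_classes * n_inf), n_classes, n_inf)
        sweep(p, 2L, colMeans(p))  # centre so separation is between-class
      })
    # small extractor-specific jitter keeps family mates highly
    # correlated but not identical
    pattern <- pattern + with_seed(
      derive_seed(seed, paste0("extractor:", ex$id)),
      matrix(stats::rnorm(length(pattern), 0, 0.05), nrow(pattern)))
    vals <- with_seed(derive_seed(seed, paste0("noise:", ex$id)), {
      m <- matrix(stats::rnorm(n_samples * ex$dim, 0, noise_sd),
                  n_samples, ex$dim)
      for (ci in seq_len(n_classes)) {
        rows <- labels == classes[ci]
        m[rows, ex$informative_axes] <-
          m[rows, ex$informative_axes] +
          matrix(ex$class_separation * noise_sd * pattern[ci, ],
                 sum(rows), n_inf, byrow = TRUE)
      }
      m
    })
    feature_table(vals, ex$id, fam, ids, labels)
  })
}

#' A complementary five-extractor synthetic bank
#'
#' The canonical end-to-end fixture: four classes arranged on two latent
#' binary factors, and five extractors — `alpha1` separates factor one
#' only, `beta1` separates factor two only (so their ensemble is needed to
#' resolve all four classes), `alpha2` is `alpha1`'s weaker family mate
#' (redundant, to be excluded by the family rule), and `gamma1`/`delta1`
#' are pure noise. Selection should pick `alpha1`, `beta1` and a noise
#' extractor, exclude `alpha2`, and the triple ensemble should beat every
#' single extractor.
#'
#' @param n_samples total samples (default 240).
#' @param dim per-extractor feature dimension (default 8).
#' @param separation class separation of the informative extractors in sd
#'   units (default 4).
#' @param seed master seed.
#' @return List of five row-aligned [feature_table()]s.
#' @export
complementary_feature_bank <- function(n_samples = 240L, dim = 8L,
                                       separation = 4, seed = 1L) {
  # factor codes over the 4 classes: class1 = (-,-), class2 = (-,+),
  # class3 = (+,-), class4 = (+,+)
  bit1 <- c(-1, -1, 1, 1) / 2
  bit2 <- c(-1, 1, -1, 1) / 2
  axes <- 1:2
  pat <- function(bit) cbind(bit, bit)   # same code on both informative axes
  generate_feature_bank(
    n_samples, 4L,
    extractors = list(
      list(id = "alpha1", family = "alpha", dim = dim,
           informative_axes = axes, class_separation = separation,
           class_pattern = pat(bit1)),
      list(id = "alpha2", family = "alpha", dim = dim,
           informative_axes = axes, class_separation = 0.8 * separation,
           class_pattern = pat(bit1)),
      list(id = "beta1", family = "beta", dim = dim,
           informative_axes = axes, class_separation = separation,
           class_pattern = pat(bit2)),
      list(id = "gamma1", family = "gamma", dim = dim,
           informative_axes = axes, class_separation = 0),
      list(id = "delta1", family = "delta", dim = dim,
           informative_axes = axes, class_separation = 0)
    ),
    seed = seed)
}
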