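config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    crop = list(threshold = 45, smooth_sigma = 2, erode_iters = 2L,
                dilate_iters = 2L, margin = 0L),
    augment = list(mode = "exhaustive", train_only = TRUE),
    split = list(train_fraction = 0.8, stratified = FALSE),
    extract = list(target_size = c(64L, 64L),
                   extractors = c("toy_histogram", "toy_blockmean",
                                  "toy_randproj")),
    classifiers = list(names = classifier_names(), reduced = TRUE,
                       mode = "holdout"),
    grids = list(knn_k = 1:4,
                 rf_trees = c(10, 25, 50, 75, 100, 125, 150),
                 svm_gamma = c(1e-5, 1e-4, 1e-3, 1e-2),
                 svm_C = c(0.1, 1, 10, 100, 1000, 10000),
                 elm_hidden = c(50, 100, 200)),
    selection = list(k = 3L, digits = 4L),
    simulate = list(kind = "feature_bank", n_samples = 240L,
                    n_per_class = 100L, classes = 2L)
  )
}

# Recursively overlay user values on the defaults, rejecting unknown keys.
merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      stop("config error: unknown key '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates every key against the documented
#' schema (unknown keys are an error naming the key), and materialises all
#' defaults so the returned object is complete and serialisable. A config
#' file containing only a seed is valid.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  if (cfg$split$train_fraction <= 0 || cfg$split$train_fraction >= 1) {
    stop("config error: invalid value for key 'split.train_fraction'",
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Build the classifier bank described by a run configuration
#'
#' Materialises [classifier_spec()]s for the configured classifier names,
#' applying any grid overrides from the config's `grids` section.
#'
#' @param config a `run_config` from [load_config()].
#' @param seed integer seed for the bank.
#' @return Named list of `classifier_spec`s.
#' @export
bank_from_config <- function(config, seed = config$seed) {
  g <- config$grids
  grids <- list(
    knn = list(k = g$knn_k),
    rf = list(n_trees = g$rf_trees),
    svm_linear = list(C = g$svm_C),
    svm_sigmoid = list(gamma = g$svm_gamma, C = g$svm_C),
    svm_rbf = list(gamma = g$svm_gamma, C = g$svm_C),
    elm = list(n_hidden = g$elm_hidden)
  )
  specs <- lapply(config$classifiers$names, function(nm) {
    classifier_spec(nm, grid = grids[[nm]] %||% list(), seed = seed)
  })
  stats::setNames(specs, config$classifiers$names)
}

#' Write a run configuration to YAML
#'
#' Round-trips through [load_config()] unchanged.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
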