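#' Evaluation matrix container
#'
#' An extractor x classifier grid of test accuracies, the object that
#' drives feature selection: each row is one feature extractor, each column
#' one bank classifier, and the row averages rank the extractors.
#'
#' @param accuracies numeric matrix of accuracies in `[0, 1]`.
#' @param extractor_ids row names (ordered).
#' @param classifier_names column names (ordered).
#' @param families per-extractor family labels; defaults to
#'   [family_of()] applied to the ids.
#' @return An object of class `evaluation_matrix`.
#' @export
evaluation_matrix <- function(accuracies, extractor_ids, classifier_names,
                              families = family_of(extractor_ids)) {
  accuracies <- as.matrix(accuracies)
  if (any(accuracies < 0 | accuracies > 1)) {
    stop("invalid input: accuracies must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(accuracies) != length(extractor_ids) ||
      ncol(accuracies) != length(classifier_names) ||
      length(families) != length(extractor_ids)) {
    stop("invalid input: dimensions misaligned with id lists",
         call. = FALSE)
  }
  dimnames(accuracies) <- list(extractor_ids, classifier_names)
  structure(list(accuracies = accuracies,
                 extractor_ids = as.character(extractor_ids),
                 classifier_names = as.character(classifier_names),
                 families = as.character(families)),
            class = "evaluation_matrix")
}

#' @export
print.evaluation_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<evaluation_matrix: %d extractors x %d classifiers>\n",
              nrow(x$accuracies), ncol(x$accuracies)))
  m <- cbind(x$accuracies, Average = rowMeans(x$accuracies))
  print(round(m, digits))
  invisible(x)
}

#' @export
summary.evaluation_matrix <- function(object, ...) {
  rs <- t(vapply(object$extractor_ids, function(e) {
    unlist(row_summary(object, e))
  }, numeric(2)))
  data.frame(extractor = object$extractor_ids,
             family = object$families,
             mean = rs[, 1L], sd = rs[, 2L], row.names = NULL)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Row summary: mean and standard deviation of one extractor's accuracies
#'
#' The arithmetic mean over the row's classifier accuracies (the "Average"
#' column of a benchmark grid) and the population standard deviation
#' (divide by n), both at full precision; rounding happens only at display
#' time.
#'
#' @param matrix an [evaluation_matrix()].
#' @param extractor_id a row name.
#' @return List with `mean` and `sd`.
#' @export
row_summary <- function(matrix, extractor_id) {
  stopifnot(inherits(matrix, "evaluation_matrix"))
  if (!extractor_id %in% matrix$extractor_ids) {
    stop("invalid input: unknown extractor '", extractor_id, "'",
         call. = FALSE)
  }
  v <- matrix$accuracies[extractor_id, ]
  list(mean = mean(v), sd = pop_sd(v))
}

#' Column summary: mean accuracy of one classifier over all extractors
#'
#' @param matrix an [evaluation_matrix()].
#' @param classifier_name a column name.
#' @return The column mean (the "Average" row of a benchmark grid).
#' @export
column_summary <- function(matrix, classifier_name) {
  stopifnot(inherits(matrix, "evaluation_matrix"))
  if (!classifier_name %in% matrix$classifier_names) {
    stop("invalid input: unknown classifier '", classifier_name, "'",
         call. = FALSE)
  }
  mean(matrix$accuracies[, classifier_name])
}

#' Build the evaluation matrix from a bank of feature tables
#'
#' For every (extractor, classifier) pair: grid-search the classifier on
#' the extractor's training rows and score the winner on the test rows.
#' All tables must share sample ids and labels; the partition's ids select
#' the rows. Deterministic under fixed seeds.
#'
#' @param tables list of row-aligned [feature_table()]s.
#' @param specs list of [classifier_spec()]s (the bank).
#' @param partition a [split_dataset()] result.
#' @param mode grid-search protocol, `"holdout"` or `"paper_faithful"`.
#' @return An `evaluation_matrix`.
#' @export
build_evaluation_matrix <- function(tables, specs, partition,
                                    mode = c("holdout", "paper_faithful")) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "split_partition"))
  ref <- tables[[1L]]
  for (tb in tables) {
    if (!identical(tb$sample_ids, ref$sample_ids) ||
        !identical(tb$labels, ref$labels)) {
      stop("invalid input: feature tables are misaligned", call. = FALSE)
    }
  }
  if (!all(c(partition$train_ids, partition$test_ids) %in% ref$sample_ids)) {
    stop("invalid input: partition ids not present in tables",
         call. = FALSE)
  }
  cls_names <- vapply(specs, `[[`, character(1), "name")
  acc <- matrix(NA_real_, length(tables), length(specs))
  for (e in seq_along(tables)) {
    tr <- subset_feature_table(tables[[e]], partition$train_ids)
    te <- subset_feature_table(tables[[e]], partition$test_ids)
    for (k in seq_along(specs)) {
      gs <- grid_search(specs[[k]], tr$values, tr$labels,
                        x_eval = te$values, y_eval = te$labels,
                        mode = mode)
      acc[e, k] <- evaluate_accuracy(gs$classifier, te$values, te$labels)
    }
  }
  evaluation_matrix(acc,
                    vapply(tables, `[[`, character(1), "extractor_id"),
                    cls_names,
                    vapply(tables, `[[`, character(1), "family"))
}

#' Write / read an evaluation matrix as CSV
#'
#' The CSV mirrors the benchmark-table layout: one row per extractor plus a
#' final `Average` row, one column per classifier plus a trailing `Average`
#' column. Families are re-derived from the extractor ids on read.
#'
#' @param matrix an [evaluation_matrix()].
#' @param path CSV path.
#' @return `read_evaluation_matrix()` returns the `evaluation_matrix`;
#'   `write_evaluation_matrix()` returns `path` invisibly.
#' @export
write_evaluation_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "evaluation_matrix"))
  m <- matrix$accuracies
  body <- data.frame(extractor = rownames(m),
                     format(m, digits = 17, trim = TRUE),
                     Average = sprintf("%.17g", rowMeans(m)),
                     check.names = FALSE)
  avg <- c("Average", sprintf("%.17g", colMeans(m)), "")
  utils::write.table(rbind(body, avg), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_evaluation_matrix
#' @export
read_evaluation_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  df <- df[df$extractor != "Average", , drop = FALSE]
  cls <- setdiff(names(df), c("extractor", "Average"))
  vals <- as.matrix(df[, cls, drop = FALSE])
  storage.mode(vals) <- "double"
  evaluation_matrix(vals, df$extractor, cls)
}

#' Benchmark evaluation matrices for the three brain-MRI datasets
#'
#' The published 13-extractor x 9-classifier accuracy grids for the
#' BT-small-2c (253 images, 2 classes), BT-large-2c (3000 images, 2
#' classes) and BT-large-4c (3064 images, 4 classes) brain-MRI benchmarks,
#' shipped as plain-text fixtures. They exercise the selection rule on
#' real-world numbers, including a display-precision mean tie
#' (BT-large-2c) and a homogeneous-family exclusion (BT-large-4c).
#'
#' @param dataset one of `"BT-small-2c"`, `"BT-large-2c"`, `"BT-large-4c"`.
#' @return An [evaluation_matrix()].
#' @export
benchmark_matrix <- function(dataset = c("BT-small-2c", "BT-large-2c",
                                         "BT-large-4c")) {
  dataset <- match.arg(dataset)
  file <- c("BT-small-2c" = "bt_small_2c_matrix.csv",
            "BT-large-2c" = "bt_large_2c_matrix.csv",
            "BT-large-4c" = "bt_large_4c_matrix.csv")[[dataset]]
  path <- system.file("extdata", file, package = "featfuse",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  evaluation_matrix(vals, df$extractor, colnames(vals))
}
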