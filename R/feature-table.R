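#' Feature table container
#'
#' The unit of data passed between extraction, evaluation, selection and
#' ensembling: an `n_samples x d` numeric matrix of features plus the
#' extractor identity, its architecture family, and aligned sample ids and
#' class labels.
#'
#' @param values numeric matrix, one row per sample.
#' @param extractor_id name of the extractor that produced the features.
#' @param family architecture-family label (see [family_of()]).
#' @param sample_ids character vector aligned with the rows.
#' @param labels class labels aligned with the rows.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, extractor_id, family = family_of(extractor_id),
                          sample_ids, labels) {
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) < 1L) {
    stop("invalid input: `values` must be a numeric matrix with d >= 1",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("invalid input: feature values must be finite", call. = FALSE)
  }
  if (length(sample_ids) != nrow(values) || length(labels) != nrow(values)) {
    stop("invalid input: sample_ids and labels must align with rows",
         call. = FALSE)
  }
  structure(list(
    values = values,
    extractor_id = as.character(extractor_id),
    family = as.character(family),
    sample_ids = as.character(sample_ids),
    labels = as.character(labels)
  ), class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table '%s' (family %s): %d samples x %d features>\n",
              x$extractor_id, x$family, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read a feature table
#'
#' Two backends share one interface: a plain-text CSV whose header comment
#' lines carry the `extractor_id`, `family` and dimension metadata (paths
#' ending `.csv`), and a binary container for large dimensions (any other
#' extension, stored via RDS). Round-trips preserve values exactly.
#'
#' @param table a [feature_table()].
#' @param path output path; extension selects the backend.
#' @return `read_feature_table()` returns the `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("#extractor_id=", table$extractor_id),
      paste0("#family=", table$family),
      paste0("#d=", ncol(table$values))
    ), con)
    df <- data.frame(sample_id = table$sample_ids, label = table$labels,
                     stringsAsFactors = FALSE)
    vals <- apply(table$values, 2L, function(v) sprintf("%.17g", v))
    if (nrow(table$values) == 1L) vals <- matrix(vals, nrow = 1L)
    colnames(vals) <- paste0("f", seq_len(ncol(table$values)))
    utils::write.table(cbind(df, vals), con, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    saveRDS(unclass(table), path)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    meta_lines <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (ln in meta_lines) {
      kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1L]]
      meta[[kv[1L]]] <- kv[2L]
    }
    for (field in c("extractor_id", "family", "d")) {
      if (is.null(meta[[field]])) {
        stop("parse error: missing metadata field '", field, "'",
             call. = FALSE)
      }
    }
    df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
    d <- as.integer(meta$d)
    if (ncol(df) != d + 2L) {
      stop("parse error: column count does not match metadata field 'd'",
           call. = FALSE)
    }
    vals <- matrix(as.numeric(as.matrix(df[, -(1:2), drop = FALSE])),
                   nrow = nrow(df))
    feature_table(vals, meta$extractor_id, meta$family,
                  df$sample_id, df$label)
  } else {
    x <- readRDS(path)
    for (field in c("values", "extractor_id", "family", "sample_ids",
                    "labels")) {
      if (is.null(x[[field]])) {
        stop("parse error: missing metadata field '", field, "'",
             call. = FALSE)
      }
    }
    feature_table(x$values, x$extractor_id, x$family, x$sample_ids, x$labels)
  }
}

#' Concatenate feature tables into an ensemble feature
#'
#' Feature-level ensembling: the member tables' columns are concatenated in
#' member order into one wider table. All members must carry identical
#' sample ids and labels in identical row order; misalignment is an error,
#' never a silent reordering.
#'
#' @param tables list of [feature_table()]s in member order.
#' @return A `feature_table` whose dimension is the sum of the member
#'   dimensions and whose `extractor_id` is `"(A + B + ...)"`.
#' @export
concatenate_features <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "feature_table")))
  if (length(tables) == 1L) return(tables[[1L]])
  ref <- tables[[1L]]
  for (tb in tables[-1L]) {
    if (!identical(tb$sample_ids, ref$sample_ids) ||
        !identical(tb$labels, ref$labels)) {
      stop("invalid input: member tables are row-misaligned", call. = FALSE)
    }
  }
  feature_table(
    do.call(cbind, lapply(tables, `[[`, "values")),
    ensemble_id(vapply(tables, `[[`, character(1), "extractor_id")),
    family = "ensemble",
    sample_ids = ref$sample_ids,
    labels = ref$labels
  )
}

ensemble_id <- function(member_ids) {
  if (length(member_ids) == 1L) member_ids else {
    paste0("(", paste(member_ids, collapse = " + "), ")")
  }
}

# Row-subset a feature table by sample ids (order of `ids` is kept).
subset_feature_table <- function(table, ids) {
  idx <- match(ids, table$sample_ids)
  if (anyNA(idx)) {
    stop("invalid input: unknown sample ids in subset", call. = FALSE)
  }
  feature_table(table$values[idx, , drop = FALSE], table$extractor_id,
                table$family, table$sample_ids[idx], table$labels[idx])
}
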