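format4 <- function(v) sprintf("%.4f", v)

render_matrix_csv <- function(em, path) {
  m <- em$accuracies
  best <- max.col(m, ties.method = "first")
  cells <- matrix(format4(m), nrow(m))
  for (i in seq_len(nrow(m))) {
    cells[i, best[i]] <- paste0(cells[i, best[i]], "*")
  }
  body <- data.frame(feature = rownames(m), cells,
                     Average = format4(rowMeans(m)), check.names = FALSE)
  names(body)[2:(ncol(m) + 1L)] <- colnames(m)
  avg <- c("Average", format4(colMeans(m)), "")
  utils::write.table(rbind(body, avg), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render an experiment report to files
#'
#' Writes benchmark-style CSV tables — `style = "matrix"` for the
#' extractor x classifier evaluation grid, `style = "ensemble"` for the
#' seven-row ensemble grid — each with an `Average` row and column and the
#' per-row best cell flagged with `*`, plus a plain-text selection audit
#' and a JSON run manifest (config echo, seed, selection decisions).
#'
#' @param report an [run_experiment()] result.
#' @param dir output directory (created if missing).
#' @param dataset_name non-empty label used in file names.
#' @param style which grids to write; default both.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, dataset_name = "dataset",
                          style = c("matrix", "ensemble")) {
  stopifnot(inherits(report, "experiment_report"))
  if (!nzchar(dataset_name)) {
    stop("render error: empty dataset name", call. = FALSE)
  }
  if (is.null(report$matrix) || is.null(report$ensemble_matrix) ||
      is.null(report$selection)) {
    stop("render error: incomplete report", call. = FALSE)
  }
  style <- match.arg(style, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("matrix" %in% style) {
    p <- file.path(dir, paste0(dataset_name, "_evaluation_matrix.csv"))
    render_matrix_csv(report$matrix, p)
    paths <- c(paths, p)
  }
  if ("ensemble" %in% style) {
    p <- file.path(dir, paste0(dataset_name, "_ensemble_matrix.csv"))
    render_matrix_csv(report$ensemble_matrix, p)
    paths <- c(paths, p)
  }
  audit <- file.path(dir, paste0(dataset_name, "_selection_audit.txt"))
  con <- file(audit, "w")
  writeLines(utils::capture.output(print(report$selection)), con)
  close(con)
  paths <- c(paths, audit)
  manifest <- file.path(dir, paste0(dataset_name, "_manifest.json"))
  jsonlite::write_json(list(
    dataset = dataset_name,
    seed = report$seed,
    config = report$config,
    selected = report$selection$selected,
    ranking = report$selection$ranking,
    excluded = report$selection$excluded,
    train_n = length(report$partition$train_ids),
    test_n = length(report$partition$test_ids)
  ), manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, manifest)
  invisible(paths)
}
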