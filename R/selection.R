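# Ordering key for extractors: higher (display-rounded) mean first, then
# lower std, then lexicographic id. Means are compared at display precision
# (default 4 decimals) so that grids published as rounded tables reproduce
# their own selection decisions; an exact full-precision tie is a fortiori
# a display tie.
rank_extractors <- function(matrix, digits = 4) {
  ids <- matrix$extractor_ids
  means <- vapply(ids, function(e) row_summary(matrix, e)$mean, numeric(1))
  sds <- vapply(ids, function(e) row_summary(matrix, e)$sd, numeric(1))
  key_mean <- if (is.null(digits)) means else round(means, digits)
  ord <- order(-key_mean, sds, ids)
  list(ids = ids[ord], means = means[ord], sds = sds[ord],
       key_mean = key_mean[ord], families = matrix$families[ord])
}

#' Select the top-k feature extractors from an evaluation matrix
#'
#' Implements the accuracy-driven selection rule: extractors are ranked by
#' the mean of their nine classifier accuracies (descending); extractors
#' whose means agree — exactly, or at 4-decimal display precision, the
#' granularity benchmark grids are published at — are ordered by lower
#' population standard deviation, then lexicographic id. Walking down the
#' ranking, an extractor whose architecture family is already represented
#' among the selected ("homogeneous" models such as two DenseNet depths) is
#' excluded and the next-best taken, because family mates are assumed to
#' span redundant feature spaces. Every exclusion and tie-break is
#' recorded in an audit trail.
#'
#' @param matrix an [evaluation_matrix()].
#' @param k number of extractors to select (default 3).
#' @param digits display precision for the mean-tie check; `NULL` compares
#'   at full precision only.
#' @return An object of class `selection_result`: list with `ranking`
#'   (all ids in rank order), `selected` (k ids in rank order), `excluded`
#'   (data frame id/reason), `tie_breaks` (data frame of std-resolved mean
#'   ties) and `summaries`.
#' @export
select_top_k <- function(matrix, k = 3, digits = 4) {
  stopifnot(inherits(matrix, "evaluation_matrix"))
  if (length(unique(matrix$families)) < k) {
    stop("selection infeasible: fewer than k distinct families",
         call. = FALSE)
  }
  rk <- rank_extractors(matrix, digits)
  ties <- data.frame(id_a = character(0), id_b = character(0),
                     winner = character(0), sd_a = numeric(0),
                     sd_b = numeric(0), exact = logical(0))
  for (i in seq_len(length(rk$ids) - 1L)) {
    if (rk$key_mean[i] == rk$key_mean[i + 1L]) {
      ties <- rbind(ties, data.frame(
        id_a = rk$ids[i], id_b = rk$ids[i + 1L],
        winner = rk$ids[i + if (rk$sds[i] <= rk$sds[i + 1L]) 0L else 1L],
        sd_a = rk$sds[i], sd_b = rk$sds[i + 1L],
        exact = rk$means[i] == rk$means[i + 1L]))
    }
  }
  selected <- character(0); sel_fam <- character(0)
  excluded <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(rk$ids)) {
    if (length(selected) == k) break
    if (rk$families[i] %in% sel_fam) {
      excluded <- rbind(excluded, data.frame(
        id = rk$ids[i], reason = "homogeneous-family"))
    } else {
      selected <- c(selected, rk$ids[i])
      sel_fam <- c(sel_fam, rk$families[i])
    }
  }
  structure(list(ranking = rk$ids, selected = selected,
                 excluded = excluded, tie_breaks = ties,
                 summaries = data.frame(id = rk$ids, family = rk$families,
                                        mean = rk$means, sd = rk$sds),
                 k = k, digits = digits),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: top %d of %d extractors>\n", x$k,
              length(x$ranking)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$excluded) > 0) {
    cat("excluded:",
        paste(sprintf("%s (%s)", x$excluded$id, x$excluded$reason),
              collapse = ", "), "\n")
  }
  if (nrow(x$tie_breaks) > 0) {
    for (i in seq_len(nrow(x$tie_breaks))) {
      tb <- x$tie_breaks[i, ]
      cat(sprintf(
        "tie: %s vs %s -> %s (sd %.4f vs %.4f, %s-precision tie)\n",
        tb$id_a, tb$id_b, tb$winner, tb$sd_a, tb$sd_b,
        if (tb$exact) "full" else "display"))
    }
  }
  invisible(x)
}

#' Exhaustive selection oracle
#'
#' Enumerates every k-subset of extractors with pairwise-distinct families,
#' orders each subset internally by the same (mean, std, id) key as
#' [select_top_k()], and returns the subset whose ordered key sequence is
#' lexicographically best. This brute-force search is the independent
#' test oracle for the greedy ranking walk: with at least k families
#' present the two must agree.
#'
#' @inheritParams select_top_k
#' @return A `selection_result` (audit fields empty).
#' @export
brute_force_select <- function(matrix, k = 3, digits = 4) {
  stopifnot(inherits(matrix, "evaluation_matrix"))
  if (length(unique(matrix$families)) < k) {
    stop("selection infeasible: fewer than k distinct families",
         call. = FALSE)
  }
  ids <- matrix$extractor_ids
  means <- vapply(ids, function(e) row_summary(matrix, e)$mean, numeric(1))
  sds <- vapply(ids, function(e) row_summary(matrix, e)$sd, numeric(1))
  key_mean <- if (is.null(digits)) means else round(means, digits)
  fam <- matrix$families
  subsets <- utils::combn(seq_along(ids), k, simplify = FALSE)
  best <- NULL
  for (s in subsets) {
    if (anyDuplicated(fam[s])) next
    s <- s[order(-key_mean[s], sds[s], ids[s])]
    if (is.null(best)) { best <- s; next }
    # lexicographic comparison of ordered member keys
    for (j in seq_len(k)) {
      a <- s[j]; b <- best[j]
      if (key_mean[a] != key_mean[b]) {
        if (key_mean[a] > key_mean[b]) best <- s
        break
      }
      if (sds[a] != sds[b]) {
        if (sds[a] < sds[b]) best <- s
        break
      }
      if (ids[a] != ids[b]) {
        if (ids[a] < ids[b]) best <- s
        break
      }
    }
  }
  structure(list(ranking = ids[best], selected = ids[best],
                 excluded = data.frame(id = character(0),
                                       reason = character(0)),
                 tie_breaks = data.frame(),
                 summaries = data.frame(id = ids[best],
                                        family = fam[best],
                                        mean = means[best], sd = sds[best]),
                 k = k, digits = digits),
            class = "selection_result")
}
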