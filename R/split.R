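#' Split a dataset into training and test partitions
#'
#' Reproducible 80/20-style partitioning. The training set size is always
#' `floor(train_fraction * n)` (so 253 samples at 0.8 give 202 train / 51
#' test, and 3000 give 2400 / 600). In stratified mode per-class training
#' counts are `floor(train_fraction * n_class)` topped up by largest
#' fractional remainder until the global training size is reached, so class
#' proportions are preserved to within rounding.
#'
#' @param ids vector of sample identifiers (unique).
#' @param labels class labels aligned with `ids`.
#' @param train_fraction proportion in (0, 1); default 0.8.
#' @param seed integer seed for the shuffle.
#' @param stratified preserve class proportions? Default `FALSE`.
#' @return An object of class `split_partition`: list with `train_ids`,
#'   `test_ids`, `train_fraction`, `seed`, `stratified`.
#' @export
split_dataset <- function(ids, labels, train_fraction = 0.8, seed = 1L,
                          stratified = FALSE) {
  n <- length(ids)
  if (n < 2L) stop("invalid input: need at least 2 samples", call. = FALSE)
  if (length(labels) != n) {
    stop("invalid input: ids and labels must be aligned", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("invalid input: duplicate sample ids", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("invalid input: train_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_train <- floor(train_fraction * n)
  if (!stratified) {
    perm <- with_seed(seed, sample.int(n))
    train <- ids[perm[seq_len(n_train)]]
  } else {
    labf <- as.character(labels)
    classes <- unique(labf)
    counts <- vapply(classes, function(cl) sum(labf == cl), integer(1))
    base <- floor(train_fraction * counts)
    rem <- train_fraction * counts - base
    short <- n_train - sum(base)
    if (short > 0) {
      top <- order(-rem, seq_along(classes))[seq_len(short)]
      base[top] <- base[top] + 1L
    }
    train <- character(0)
    perm_all <- with_seed(seed, {
      lapply(classes, function(cl) sample(which(labf == cl)))
    })
    train <- unlist(lapply(seq_along(classes), function(i) {
      ids[perm_all[[i]][seq_len(base[i])]]
    }), use.names = FALSE)
  }
  structure(list(
    train_ids = train,
    test_ids = setdiff(ids, train),
    train_fraction = train_fraction,
    seed = as.integer(seed),
    stratified = stratified
  ), class = "split_partition")
}

#' @export
print.split_partition <- function(x, ...) {
  cat(sprintf(
    "<split_partition %d train / %d test (fraction %.2f, seed %d%s)>\n",
    length(x$train_ids), length(x$test_ids), x$train_fraction, x$seed,
    if (x$stratified) ", stratified" else ""))
  invisible(x)
}
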