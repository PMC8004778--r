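# Shared fixtures, all built in code.

# image with a single bright rectangle on black background
rect_image <- function(h = 20, w = 20, rows = 6:10, cols = 7:13,
                       value = 200) {
  px <- matrix(0, h, w)
  px[rows, cols] <- value
  gray_image(px)
}

# asymmetric image: all 8 dihedral variants are pairwise distinct
asym_image <- function() gray_image(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10),
                                           3, 3))

# two origin-symmetric Gaussian blobs; hard-margin separability verified
sep_blobs <- function(n_per = 50, gap = 3, sd = 0.4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, -gap, sd), n_per, 2),
             matrix(rnorm(2 * n_per, gap, sd), n_per, 2))
  y <- rep(c("neg", "pos"), each = n_per)
  proj <- x %*% c(1, 1)
  stopifnot(max(proj[y == "neg"]) < min(proj[y == "pos"]))
  list(x = x, y = y)
}

# concentric circles: RBF-separable, not linearly separable in population
circles_data <- function(n_per = 60, seed = 2) {
  set.seed(seed)
  th <- runif(2 * n_per, 0, 2 * pi)
  r <- c(rep(1, n_per), rep(3, n_per))
  list(x = cbind(r * cos(th), r * sin(th)) +
         matrix(rnorm(4 * n_per, 0, 0.1), 2 * n_per),
       y = rep(c("in", "out"), each = n_per))
}

# XOR pattern, each corner duplicated
xor_data <- function(reps = 10) {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2,
              byrow = TRUE)[rep(1:4, reps), ]
  list(x = x, y = rep(c("a", "b", "b", "a"), reps))
}

# random evaluation matrix with random families; 4-decimal values force
# display ties with positive probability
random_eval_matrix <- function(n_extractors, n_classifiers, seed) {
  set.seed(seed)
  vals <- matrix(round(runif(n_extractors * n_classifiers, 0.5, 1), 4),
                 n_extractors, n_classifiers)
  ids <- sprintf("ext%02d", seq_len(n_extractors))
  fams <- paste0("fam", sample.int(max(3L, n_extractors %/% 2L),
                                   n_extractors, replace = TRUE))
  evaluation_matrix(vals, ids, sprintf("clf%d", seq_len(n_classifiers)),
                    families = fams)
}

# tiny classifier bank for fast end-to-end tests
small_bank <- function(seed = 1L) {
  list(classifier_spec("gaussian_nb", seed = seed),
       classifier_spec("knn", seed = seed),
       classifier_spec("svm_rbf", seed = seed, reduced = TRUE))
}
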