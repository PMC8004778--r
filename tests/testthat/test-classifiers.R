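test_that("softmax head: uniform at zero weights, perfect on separable blobs", {
  d <- sep_blobs()
  # epochs = 0 leaves the zero-initialised model: uniform probabilities
  zero <- train_fc(d$x, d$y, epochs = 0)
  p <- predict(zero, d$x, type = "prob")
  expect_true(all(abs(p - 0.5) < 1e-12))
  fc <- train_fc(d$x, d$y)
  expect_equal(evaluate_accuracy(fc, d$x, d$y), 1.0)
  # probabilities always sum to one
  p2 <- predict(fc, d$x, type = "prob")
  expect_true(all(abs(rowSums(p2) - 1) < 1e-9))
  # 4-class uniform start: probability 1/M
  x4 <- matrix(rnorm(80), 20, 4)
  y4 <- rep(c("a", "b", "c", "d"), 5)
  expect_true(all(abs(predict(train_fc(x4, y4, epochs = 0), x4,
                              type = "prob") - 0.25) < 1e-12))
  expect_error(train_fc(d$x, rep("one", nrow(d$x))), "2 classes")
})

test_that("softmax head agrees with multinomial regression on separable data", {
  skip_if_not_installed("nnet")
  d <- sep_blobs(gap = 4)
  fc <- train_fc(d$x, d$y)
  mn <- nnet::multinom(y ~ ., data = data.frame(d$x, y = factor(d$y)),
                       trace = FALSE)
  mn_pred <- as.character(predict(mn, data.frame(d$x)))
  expect_equal(predict(fc, d$x), mn_pred)
})

test_that("Gaussian NB matches the hand-computed posterior", {
  # class A = {-1, +1} (mu 0, ML var 1); class B = {3, 5} (mu 4, var 1);
  # densities at x = 1: exp(-0.5)/sqrt(2*pi) vs exp(-4.5)/sqrt(2*pi)
  nb <- train_gaussian_nb(matrix(c(-1, 1, 3, 5), 4, 1),
                          c("A", "A", "B", "B"))
  dens_a <- exp(-0.5) / sqrt(2 * pi)
  dens_b <- exp(-4.5) / sqrt(2 * pi)
  expect_equal(dens_a, 0.242, tolerance = 1e-3)
  expect_equal(dens_b, 0.00443, tolerance = 1e-3)
  q <- matrix(1, 1, 1)
  expect_equal(predict(nb, q), "A")
  expect_equal(unname(predict(nb, q, type = "prob")[1, "A"]),
               dens_a / (dens_a + dens_b), tolerance = 1e-6)
  # mirrored classes: posterior 0.5/0.5 at the symmetry point
  nbs <- train_gaussian_nb(matrix(c(-3, -1, 1, 3), 4, 1),
                           c("A", "A", "B", "B"))
  expect_equal(unname(predict(nbs, matrix(0, 1, 1), type = "prob")[1, ]),
               c(0.5, 0.5))
  # posteriors normalise for random queries, multi-feature multi-class
  set.seed(8)
  nbm <- train_gaussian_nb(matrix(rnorm(120), 30, 4),
                           rep(c("a", "b", "c"), 10))
  pr <- predict(nbm, matrix(rnorm(400), 100, 4), type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  # zero-variance feature survives through the smoothing floor
  nbz <- train_gaussian_nb(cbind(c(1, 1, 2, 2), 5), c("A", "A", "B", "B"))
  expect_equal(predict(nbz, cbind(1, 5)), "A")
})

test_that("AdaBoost boosts shallow trees to fit the XOR pattern", {
  d <- xor_data()
  ab <- train_adaboost(d$x, d$y, n_estimators = 150, depth = 3)
  expect_equal(evaluate_accuracy(ab, d$x, d$y), 1.0)
  # staged training error is non-increasing on separable data
  expect_true(all(diff(ab$fit$staged_train_error) <= 1e-12))
  # a single round equals its base tree
  blob <- sep_blobs()
  one <- train_adaboost(blob$x, blob$y, n_estimators = 1)
  tree <- rpart::rpart(
    y ~ ., data = data.frame(blob$x, y = factor(blob$y)),
    method = "class",
    control = rpart::rpart.control(maxdepth = 1, minsplit = 2,
                                   minbucket = 1, cp = -1, xval = 0))
  expect_equal(predict(one, blob$x),
               as.character(predict(tree, data.frame(blob$x),
                                    type = "class")))
  # deterministic across repeated fits
  ab2 <- train_adaboost(d$x, d$y, n_estimators = 150, depth = 3)
  expect_identical(predict(ab, d$x), predict(ab2, d$x))
  expect_error(train_adaboost(d$x, d$y, n_estimators = 0), "n_estimators")
})

test_that("k-NN votes over Euclidean neighbours with the documented tie rules", {
  # memorisation at k = 1
  x <- matrix(c(0, 0, 0, 1, 5, 5), 3, 2, byrow = TRUE)
  y <- c("0", "0", "1")
  expect_equal(predict(train_knn(x, y, k = 1), x), y)
  # 2-1 vote
  expect_equal(predict(train_knn(x, y, k = 3),
                       matrix(c(0.4, 0.4), 1, 2)), "0")
  # k = 2 vote tie resolved by the nearest neighbour's label
  xt <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(predict(train_knn(xt, c("a", "b"), k = 2),
                       matrix(c(0.5, 0), 1, 2)), "a")
  expect_equal(predict(train_knn(xt, c("a", "b"), k = 2),
                       matrix(c(1.5, 0), 1, 2)), "b")
  # k = 1 training accuracy 1 on distinct points
  set.seed(4)
  xr <- matrix(rnorm(60), 30, 2)
  yr <- rep(c("p", "q", "r"), 10)
  expect_equal(evaluate_accuracy(train_knn(xr, yr, k = 1), xr, yr), 1.0)
  expect_error(train_knn(xr, yr, k = 31), "n_train")
})

test_that("random forest uses sqrt(d) feature sampling and is seeded", {
  set.seed(5)
  x <- matrix(rnorm(90), 10, 9)
  x[6:10, ] <- x[6:10, ] + 10
  y <- rep(c("n", "t"), each = 5)
  rf1 <- train_rf(x, y, n_trees = 1, seed = 2)
  expect_equal(evaluate_accuracy(rf1, x, y), 1.0)
  expect_equal(rf1$fit$mtry, 3)  # floor(sqrt(9))
  rf2 <- train_rf(x, y, n_trees = 25, seed = 7)
  rf3 <- train_rf(x, y, n_trees = 25, seed = 7)
  xq <- matrix(rnorm(45), 5, 9)
  expect_identical(predict(rf2, xq), predict(rf3, xq))
})

test_that("SVM kernels behave as their geometry dictates", {
  blob <- sep_blobs()
  lin <- train_svm(blob$x, blob$y, "linear", C = 1)
  expect_equal(evaluate_accuracy(lin, blob$x, blob$y), 1.0)
  circ <- circles_data()
  rbf <- grid_search(classifier_spec("svm_rbf"), circ$x, circ$y,
                     circ$x, circ$y, mode = "paper_faithful")
  linc <- grid_search(classifier_spec("svm_linear"), circ$x, circ$y,
                      circ$x, circ$y, mode = "paper_faithful")
  expect_equal(rbf$accuracy, 1.0)
  expect_lt(linc$accuracy, 0.85)  # rings are not linearly separable
  # RBF reaches >= 0.95 on a two-Gaussian problem with Bayes accuracy ~ 1
  set.seed(9)
  xg <- rbind(matrix(rnorm(160, 0, 1), 80, 2),
              matrix(rnorm(160, 6, 1), 80, 2))
  yg <- rep(c("n", "t"), each = 80)
  tr <- c(1:60, 81:140); te <- setdiff(1:160, tr)
  gs <- grid_search(classifier_spec("svm_rbf"), xg[tr, ], yg[tr],
                    xg[te, ], yg[te], mode = "paper_faithful")
  expect_gte(gs$accuracy, 0.95)
  expect_error(train_svm(matrix(c(1, NA, 2, 3), 2, 2), c("a", "b")),
               "finite")
})

test_that("grid search picks the argmax and matches brute-force re-evaluation", {
  d <- sep_blobs()
  # degenerate single-point grid
  one <- grid_search(classifier_spec("knn", grid = list(k = 3L)),
                     d$x, d$y, d$x, d$y, mode = "paper_faithful")
  expect_equal(one$chosen_params$k, 3L)
  # k-NN grid {1..4}: chosen k equals independent brute-force best
  set.seed(10)
  xs <- matrix(rnorm(200), 100, 2) + 1.2 * rep(c(0, 1), each = 50)
  ys <- rep(c("n", "t"), each = 50)
  tr <- c(1:40, 51:90); te <- setdiff(1:100, tr)
  gs <- grid_search(classifier_spec("knn"), xs[tr, ], ys[tr],
                    xs[te, ], ys[te], mode = "paper_faithful")
  accs <- vapply(1:4, function(k) {
    evaluate_accuracy(train_knn(xs[tr, ], ys[tr], k = k),
                      xs[te, ], ys[te])
  }, numeric(1))
  expect_equal(gs$chosen_params$k, which.max(accs))
  expect_equal(gs$accuracy, max(accs))
  # holdout mode rejects overlapping ids and never touches the eval set
  expect_error(
    grid_search(classifier_spec("knn"), xs[tr, ], ys[tr], mode = "holdout",
                train_ids = c("a", "b"), eval_ids = c("b", "c")),
    "overlap")
  hold <- grid_search(classifier_spec("knn"), xs[tr, ], ys[tr],
                      mode = "holdout")
  expect_true(hold$chosen_params$k %in% 1:4)
})

test_that("accuracy is the fraction of correct predictions", {
  d <- sep_blobs()
  fc <- train_fc(d$x, d$y)
  expect_equal(evaluate_accuracy(fc, d$x, d$y), 1.0)
  # 50 of 51 correct reproduces the 0.9804 granularity of small test sets
  x51 <- matrix(seq(-5, 5, length.out = 51), 51, 1)
  y51 <- c(rep("n", 25), "t", rep("t", 25))
  k1 <- train_knn(matrix(c(-5, 5), 2, 1), c("n", "t"), k = 1)
  acc <- evaluate_accuracy(k1, x51, y51)
  expect_equal(acc, 50 / 51)
  expect_equal(round(acc, 4), 0.9804)
  expect_error(evaluate_accuracy(fc, d$x[0, , drop = FALSE],
                                 character(0)), "empty")
})
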