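test_that("row and column summaries reproduce the benchmark averages", {
  em5 <- benchmark_matrix("BT-large-2c")
  em6 <- benchmark_matrix("BT-large-4c")
  expect_equal(round(row_summary(em5, "resnext101")$mean, 4), 0.9613)
  expect_equal(round(row_summary(em6, "mnasnet")$mean, 4), 0.8499)
  expect_equal(round(column_summary(em5, "svm_rbf"), 4), 0.9785)
  expect_equal(round(column_summary(em6, "svm_rbf"), 4), 0.9019)
  # constant row: mean is the value, sd zero
  cm <- evaluation_matrix(matrix(0.7, 2, 3), c("a1", "b1"),
                          c("c1", "c2", "c3"), families = c("a", "b"))
  expect_equal(row_summary(cm, "a1"), list(mean = 0.7, sd = 0))
  expect_equal(column_summary(cm, "c2"), 0.7)
  expect_error(row_summary(em5, "nope"), "unknown extractor")
  expect_error(column_summary(em5, "nope"), "unknown classifier")
})

test_that("selection recovers the three published top-3 sets", {
  expect_setequal(select_top_k(benchmark_matrix("BT-small-2c"))$selected,
                  c("densenet169", "inception_v3", "resnext50"))
  sel5 <- select_top_k(benchmark_matrix("BT-large-2c"))
  expect_setequal(sel5$selected,
                  c("densenet121", "resnext101", "mnasnet"))
  # the display-mean tie resolves to the lower-std extractor
  expect_true(nrow(sel5$tie_breaks) >= 1)
  tie <- sel5$tie_breaks[sel5$tie_breaks$winner == "mnasnet", ]
  expect_equal(nrow(tie), 1)
  expect_lt(tie$sd_a, tie$sd_b)
  expect_equal(round(c(tie$sd_a, tie$sd_b), 4), c(0.0383, 0.0459))
  sel6 <- select_top_k(benchmark_matrix("BT-large-4c"))
  expect_setequal(sel6$selected,
                  c("densenet169", "shufflenet_v2", "mnasnet"))
  # densenet121 ranks third by mean but falls to the family rule
  expect_equal(sel6$excluded$id, "densenet121")
  expect_equal(sel6$excluded$reason, "homogeneous-family")
})

test_that("greedy selection agrees with the brute-force oracle", {
  for (s in 1:60) {
    em <- random_eval_matrix(sample(4:13, 1), sample(3:9, 1), seed = s)
    k <- min(3, length(unique(em$families)))
    expect_identical(sort(select_top_k(em, k)$selected),
                     sort(brute_force_select(em, k)$selected),
                     info = paste("seed", s))
  }
})

test_that("selection handles forced ties, k = 1 and degenerate matrices", {
  # exact mean tie broken by lower std
  vals <- rbind(c(0.9, 0.8, 0.7), c(0.8, 0.8, 0.8), c(0.5, 0.5, 0.5))
  em <- evaluation_matrix(vals, c("hi_var", "lo_var", "weak"),
                          c("c1", "c2", "c3"),
                          families = c("f1", "f2", "f3"))
  sel <- select_top_k(em, 2)
  expect_equal(sel$selected, c("lo_var", "hi_var"))
  expect_true(any(sel$tie_breaks$winner == "lo_var"))
  # k = 1 is the single best mean
  expect_equal(brute_force_select(em, 1)$selected, "lo_var")
  expect_equal(select_top_k(em, 1)$selected, "lo_var")
  # all rows equal: deterministic lexicographic choice, same both ways
  eq <- evaluation_matrix(matrix(0.6, 4, 3),
                          c("delta", "alpha", "charlie", "bravo"),
                          c("c1", "c2", "c3"),
                          families = paste0("f", 1:4))
  expect_equal(select_top_k(eq, 3)$selected,
               c("alpha", "bravo", "charlie"))
  expect_equal(sort(brute_force_select(eq, 3)$selected),
               sort(select_top_k(eq, 3)$selected))
  # fewer distinct families than k is infeasible
  onefam <- evaluation_matrix(matrix(0.6, 3, 2), c("a1", "a2", "a3"),
                              c("c1", "c2"), families = rep("a", 3))
  expect_error(select_top_k(onefam, 2), "infeasible")
  expect_error(brute_force_select(onefam, 2), "infeasible")
})

test_that("selection is invariant to extractor input order", {
  em <- benchmark_matrix("BT-large-4c")
  perm <- c(7, 3, 11, 1, 13, 5, 9, 2, 12, 4, 10, 6, 8)
  emp <- evaluation_matrix(em$accuracies[perm, ],
                           em$extractor_ids[perm],
                           em$classifier_names,
                           families = em$families[perm])
  expect_setequal(select_top_k(emp)$selected, select_top_k(em)$selected)
})

test_that("evaluation matrices validate and round-trip through CSV", {
  expect_error(evaluation_matrix(matrix(1.2, 2, 2), c("a", "b"),
                                 c("x", "y"), c("a", "b")), "\\[0, 1\\]")
  em <- benchmark_matrix("BT-small-2c")
  f <- tempfile(fileext = ".csv")
  write_evaluation_matrix(em, f)
  back <- read_evaluation_matrix(f)
  expect_equal(back$accuracies, em$accuracies)
  expect_equal(back$families, em$families)
  # the written layout carries the Average row and column
  raw <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(raw), 14)
  expect_equal(ncol(raw), 11)
  expect_true("Average" %in% names(raw))
})

test_that("evaluation matrix construction scores every cell on the test rows", {
  bank <- generate_feature_bank(
    80, 2,
    extractors = list(
      list(id = "good1", family = "good", dim = 4, informative_axes = 1:2,
           class_separation = 5),
      list(id = "noise1", family = "noise", dim = 4,
           informative_axes = 1:2, class_separation = 0)),
    seed = 7)
  part <- split_dataset(bank[[1]]$sample_ids, bank[[1]]$labels, 0.8,
                        seed = 7)
  em <- build_evaluation_matrix(bank, small_bank(7), part)
  expect_equal(dim(em$accuracies), c(2, 3))
  expect_true(all(em$accuracies >= 0 & em$accuracies <= 1))
  # the informative extractor dominates the noise extractor cell-wise
  expect_true(all(em$accuracies["good1", ] >= em$accuracies["noise1", ]))
  # a duplicated extractor row is identical
  em2 <- build_evaluation_matrix(list(bank[[1]], bank[[1]]),
                                 small_bank(7), part)
  expect_equal(unname(em2$accuracies[1, ]), unname(em2$accuracies[2, ]))
  # misaligned tables are rejected
  bad <- bank
  bad[[2]]$sample_ids <- rev(bad[[2]]$sample_ids)
  expect_error(build_evaluation_matrix(bad, small_bank(7), part),
               "misaligned")
})
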