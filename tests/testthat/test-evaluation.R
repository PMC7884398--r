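test_that("leave-k-out counts are exact and symmetric", {
  expect_identical(count_leave_k_out(24, 6), 134596)
  expect_identical(count_leave_k_out(2, 1), 2)
  expect_identical(count_leave_k_out(6, 2), 15)
  expect_equal(count_leave_k_out(6, 2), ncol(combn(6, 2)))

  for (n in 2:12) for (k in seq_len(n - 1)) {
    expect_equal(count_leave_k_out(n, k), ncol(combn(n, k)))
    expect_identical(count_leave_k_out(n, k), count_leave_k_out(n, n - k))
  }
  expect_error(count_leave_k_out(6, 6), "0 < k < n")
  expect_error(count_leave_k_out(6, 0), "0 < k < n")
})

test_that("split enumeration is lexicographic with correct balance tags", {
  ids <- c("a", "b", "c", "d")
  labels <- c("sRCC", "sRCC", "nsRCC", "nsRCC")
  splits <- enumerate_leave_k_out(ids, 2, labels)
  expect_equal(length(splits), 6)
  expect_equal(splits$validation_idx, t(combn(4, 2)))

  sp1 <- get_split(splits, 1)
  expect_equal(sp1$validation_ids, c("a", "b"))
  expect_equal(sp1$training_ids, c("c", "d"))

  # brute-force balance check: a split is balanced iff each side holds
  # one subject of each class
  brute <- apply(combn(4, 2), 2, function(v)
    sum(labels[v] == "sRCC") == 1 && sum(labels[-v] == "sRCC") == 1)
  expect_equal(splits$balanced, brute)
  expect_equal(sum(splits$balanced), 4)
})

test_that("the full 24-subject leave-six-out stream has 134,596 members", {
  ids <- sprintf("s%02d", 1:24)
  labels <- rep(c("sRCC", "nsRCC"), 12)
  splits <- enumerate_leave_k_out(ids, 6, labels)
  expect_equal(length(splits), 134596)
  expect_equal(splits$n_total, 134596)
})

test_that("subsampled splits unrank combinations correctly and deterministically", {
  # unranking oracle: every rank maps to the matching combn column
  all_combos <- t(combn(8, 3))
  for (r in seq_len(nrow(all_combos)))
    expect_equal(somlvq:::nth_combination(8, 3, r), all_combos[r, ])

  ids <- sprintf("s%02d", 1:10)
  labels <- rep(c("sRCC", "nsRCC"), 5)
  s1 <- enumerate_leave_k_out(ids, 4, labels, max_splits = 20, seed = 5)
  s2 <- enumerate_leave_k_out(ids, 4, labels, max_splits = 20, seed = 5)
  expect_identical(s1$ranks, s2$ranks)
  expect_equal(length(s1), 20)
  expect_false(is.unsorted(s1$ranks))

  full <- enumerate_leave_k_out(ids, 4, labels)
  expect_equal(s1$validation_idx, full$validation_idx[s1$ranks, ])
  expect_equal(s1$balanced, full$balanced[s1$ranks])
})

test_that("metrics follow the total-cohort denominator convention", {
  # reconstructed cohort tables: test, validation, training rows
  test_row <- confusion_metrics(list(TP = 3, FP = 1, FN = 2, TN = 4))
  expect_equal(test_row$accuracy, 70)
  expect_equal(test_row$fpr, 10)
  expect_equal(test_row$fnr, 20)
  expect_equal(test_row$ppv, 75)
  expect_equal(round(test_row$npv, 2), 66.67)

  val_row <- confusion_metrics(list(TP = 3, FP = 1, FN = 0, TN = 2))
  expect_equal(round(val_row$accuracy, 2), 83.33)
  expect_equal(round(val_row$fpr, 2), 16.67)
  expect_equal(val_row$fnr, 0)
  expect_equal(val_row$ppv, 75)
  expect_equal(val_row$npv, 100)

  train_row <- confusion_metrics(list(TP = 8, FP = 1, FN = 0, TN = 7))
  expect_equal(train_row$accuracy, 93.75)
  expect_equal(train_row$fpr, 6.25)
  expect_equal(round(train_row$ppv, 2), 88.89)
  expect_equal(train_row$npv, 100)

  perfect <- confusion_metrics(list(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$ppv, 100)
  expect_equal(perfect$npv, 100)

  # identity accuracy + FPR + FNR = 100 on random matrices
  for (s in 1:20) {
    m <- withr::with_seed(s, as.list(setNames(rpois(4, 4) + c(1, 0, 0, 0),
                                              c("TP", "FP", "FN", "TN"))))
    mr <- confusion_metrics(m)
    expect_equal(mr$accuracy + mr$fpr + mr$fnr, 100)
  }

  # undefined predictive values are flagged, not thrown
  none_pos <- confusion_metrics(list(TP = 0, FP = 0, FN = 2, TN = 3))
  expect_false(none_pos$ppv_defined)
  expect_true(is.na(none_pos$ppv))
})

test_that("cross-validation is deterministic and perfect on separable maps", {
  ids <- sprintf("s%d", 1:8)
  x <- rbind(matrix(c(1, rep(0, 80)), 4, 81, byrow = TRUE),
             matrix(c(rep(0, 80), 1), 4, 81, byrow = TRUE))
  x <- x + withr::with_seed(81, matrix(rnorm(8 * 81, sd = 0.01), 8))
  rownames(x) <- ids
  labels <- setNames(rep(c("sRCC", "nsRCC"), each = 4), ids)

  splits <- enumerate_leave_k_out(ids, 2, labels)
  cfg <- lvq_config(epochs = 30, seed = 9)
  cv <- cross_validate(x, labels, cfg, splits)
  expect_equal(nrow(cv), 28)
  expect_true(all(cv$train_accuracy == 100))
  expect_true(all(cv$validation_accuracy == 100))

  # duplicated split -> identical result row
  dup <- splits
  dup$validation_idx <- dup$validation_idx[c(1, 1, 5), ]
  dup$balanced <- dup$balanced[c(1, 1, 5)]
  dup$ranks <- dup$ranks[c(1, 1, 5)]
  cv_dup <- cross_validate(x, labels, cfg, dup)
  expect_equal(cv_dup[1, ], cv_dup[2, ], ignore_attr = TRUE)

  expect_error(cross_validate(x[1:7, ], labels, cfg, splits),
               "no activation vector")
})

test_that("label-permuted cohorts cross-validate at chance level", {
  # the permutation null: with permuted labels, cross-validated accuracy
  # sits at chance. Averaging over relabelings (not only over splits of
  # one fixed labeling) gives a valid SE, and the splits are restricted
  # to class-balanced ones: unbalanced training sides predict the
  # majority class more often while validation is minority-heavy, a
  # known below-chance bias that is a property of the design, not of
  # the classifier
  n <- 12
  ids <- sprintf("s%02d", seq_len(n))
  x <- withr::with_seed(82, matrix(rnorm(n * 81), n))
  rownames(x) <- ids

  perm_means <- vapply(1:24, function(p) {
    labels <- setNames(withr::with_seed(830 + p,
      sample(rep(c("sRCC", "nsRCC"), n / 2))), ids)
    splits <- enumerate_leave_k_out(ids, 4, labels)
    keep <- withr::with_seed(84, sample(which(splits$balanced), 25))
    splits$validation_idx <- splits$validation_idx[keep, ]
    splits$balanced <- splits$balanced[keep]
    splits$ranks <- splits$ranks[keep]
    cv <- cross_validate(x, labels, lvq_config(epochs = 50,
                                               learning_rate = 0.01,
                                               seed = 85), splits)
    mean(cv$validation_accuracy)
  }, numeric(1))
  se <- sd(perm_means) / sqrt(length(perm_means))
  expect_lt(abs(mean(perm_means) - 50), 3 * se)
})

test_that("model selection applies the dual threshold, balance filter, and ordering", {
  cv <- data.frame(
    rank = 1:10,
    validation_ids = paste0("v", 1:10),
    balanced = rep(c(TRUE, FALSE), 5),
    train_accuracy = c(90, 85, 95, 80, 100, 84, 83, 83, 90, 82),
    validation_accuracy = c(85, 83, 90, 95, 100, 82, 83, 90, 83, 81))

  sel <- select_model(cv, threshold = 83)
  expect_equal(nrow(sel), 7) # rows failing either side are dropped
  expect_equal(sel$rank[1], 5)
  expect_false(is.unsorted(rev(sel$validation_accuracy)))
  # equal validation accuracy -> higher training accuracy first
  tied <- sel[sel$validation_accuracy == 90, ]
  expect_equal(tied$rank, c(3, 8))

  expect_equal(nrow(select_model(cv, threshold = 101)), 0)

  none_balanced <- cv; none_balanced$balanced <- FALSE
  expect_equal(nrow(select_model(none_balanced, 83,
                                 require_balanced = TRUE)), 0)

  sel_bal <- select_model(cv, 83, require_balanced = TRUE)
  expect_true(all(sel_bal$balanced))
})
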