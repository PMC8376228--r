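test_that("the two-edge shuffle yields one of the two valid rewirings", {
  pos <- c("a|b", "c|d")
  valid <- list(c("a|c", "b|d"), c("a|d", "b|c"))
  seen <- character(0)
  for (s in 1:20) {
    out <- shuffle_negatives(pos, seed = s)
    expect_true(any(vapply(valid, function(v) setequal(out, v), logical(1))))
    expect_length(intersect(out, pos), 0)
    expect_identical(out, shuffle_negatives(pos, seed = s))  # deterministic
    seen <- c(seen, paste(sort(out), collapse = ";"))
  }
  expect_gt(length(unique(seen)), 1)  # both rewirings occur across seeds
})

test_that("shuffling preserves degrees and avoids originals on random graphs", {
  for (s in 1:200) {
    n_e <- sample(5:40, 1)
    pos <- random_bipartite(n_e, seed = 1000 + s)
    out <- shuffle_negatives(pos, seed = s)
    expect_equal(degree_multiset(out), degree_multiset(pos))
    expect_length(intersect(out, pos), 0)
    expect_equal(length(out), length(pos))
  }
})

test_that("a homo-DDI contributes 2 to its domain's degree in the shuffle", {
  pos <- c("a|a", "b|c", "d|e", "f|g")
  out <- shuffle_negatives(pos, seed = 3)
  expect_equal(degree_multiset(out), degree_multiset(pos))
  expect_length(intersect(out, pos), 0)
})

test_that("degenerate shuffles are rejected", {
  expect_error(shuffle_negatives("a|b", seed = 1), "at least 2")
})

test_that("the learning set keeps only scored members and logs drops", {
  cons <- setNames(c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.1),
                   c("a|b", "c|d", "e|f", "g|h", "m|n", "o|p", "q|r"))
  pos <- c("a|b", "c|d", "e|f", "g|h")
  neg <- c("m|n", "o|p", "q|r", "x|y")  # x|y unscored
  ls <- suppressMessages(build_learning_set(pos, neg, cons))
  expect_length(ls$positives, 4)
  expect_length(ls$negatives, 3)
  expect_named(ls$scores)

  expect_message(
    expect_message(build_learning_set(c(pos, "z|z"), neg, cons), "unscored"),
    "learning set")
  expect_error(build_learning_set(pos, character(0), cons), "empty shuffled")
  expect_error(build_learning_set("z|z", neg, cons), "no positive")
  # a shuffled edge equal to a positive is discarded for safety
  ls2 <- suppressMessages(build_learning_set(pos, c("a|b", neg), cons))
  expect_false("a|b" %in% ls2$negatives)
})

test_that("precision/recall/F1 match hand computations", {
  expect_equal(precision_recall_f1(c(TRUE, TRUE, FALSE),
                                   c(0.9, 0.8, 0.1), 0.5),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(precision_recall_f1(c(TRUE, TRUE, FALSE, FALSE),
                                   c(0.9, 0.4, 0.6, 0.1), 0.5),
               c(precision = 0.5, recall = 0.5, f1 = 0.5))
  expect_equal(precision_recall_f1(c(TRUE, FALSE), c(0.9, 0.1), 1.0),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(c("pos", "neg"), c(0.9, 0.1), 0.5),
               c(precision = 1, recall = 1, f1 = 1))
})

test_that("the three-phase grid is an increasing union with the stated span", {
  g <- threshold_grid()
  expect_equal(min(g), 0)
  expect_equal(max(g), 1)
  expect_true(all(diff(g) > 0))
  expect_true(all(c(0.0158, 0.0159, 0.01, 0.001) %in% g))
  expect_false(0.015855 %in% g)
  expect_false(0.0001 %in% g)  # fine phase only starts at 0.01
  # phase resolutions: 0.0001 inside [0.01, 0.02], 0.001 inside [0, 0.04]
  expect_true(all(abs(g[g >= 0.01 & g <= 0.02] * 1e4 -
                        round(g[g >= 0.01 & g <= 0.02] * 1e4)) < 1e-9))
})

test_that("cross-validated selection recovers a separating threshold", {
  set.seed(41)
  ls <- make_learning_set(runif(150, 0.6, 1.0), runif(150, 0.0, 0.2))
  res <- select_threshold_cv(ls, seed = 7)
  expect_s3_class(res, "threshold_result")
  expect_gte(res$t_m, 0.2)
  expect_lt(res$t_m, 0.6)
  expect_equal(res$f1_test, 1.0)
  expect_equal(res$f1_train, 1.0)
  expect_equal(res$t_m, mean(res$fold_thresholds))

  # deterministic given the seed, and invariant to input iteration order
  res2 <- select_threshold_cv(ls, seed = 7)
  expect_identical(res, res2)
  perm <- sample(length(ls$scores))
  ls3 <- structure(list(positives = rev(ls$positives),
                        negatives = rev(ls$negatives),
                        scores = ls$scores[perm]),
                   class = "learning_set")
  expect_identical(select_threshold_cv(ls3, seed = 7), res)

  expect_error(select_threshold_cv(make_learning_set(runif(3), runif(3)),
                                   seed = 1), "5-fold")
})

test_that("a signal-free learning set yields the expected chance-level F1", {
  # with labels independent of scores and a low threshold, F1 -> 2p/(1+p)
  set.seed(42)
  n_pos <- 200; n_neg <- 200
  ls <- make_learning_set(runif(n_pos, 0.3, 1), runif(n_neg, 0.3, 1))
  res <- select_threshold_cv(ls, seed = 9)
  p <- n_pos / (n_pos + n_neg)
  expect_lt(abs(res$f1_test - 2 * p / (1 + p)), 0.12)
})

test_that("filtering is strictly greater-than", {
  cons <- c(a = 0.5, b = 0.0158)
  expect_equal(filter_matrix(cons, 0.01586), c(a = 0.5))
  expect_equal(filter_matrix(cons, 0), cons)
  expect_equal(unname(filter_matrix(c(x = 0.3), 0.3)), numeric(0))
})
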