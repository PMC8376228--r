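test_that("the consensus combination matches hand-evaluated cases", {
  # single source: weights cancel
  m <- fake_matrix("a", c("x|y", "u|v"), c(0.4, 0.9))
  cs <- combine_scores(list(a = m), c(a = 0.37))
  expect_equal(unname(cs[c("x|y", "u|v")]), c(0.4, 0.9))

  # zero scores are excluded from the denominator: 0.5*0.4 / 0.5 = 0.4
  m1 <- fake_matrix("a", "x|y", 0.4)
  m2 <- fake_matrix("b", "u|v", 0.3)
  cs2 <- combine_scores(list(a = m1, b = m2), c(a = 0.5, b = 1.0))
  expect_equal(unname(cs2["x|y"]), 0.4)
  expect_equal(unname(cs2["u|v"]), 0.3)

  # plain average with equal weights
  m3 <- fake_matrix("a", "x|y", 0.4)
  m4 <- fake_matrix("b", "x|y", 0.8)
  cs3 <- combine_scores(list(a = m3, b = m4), c(a = 1, b = 1))
  expect_equal(unname(cs3["x|y"]), 0.6)

  # weighted: (1*0.4 + 3*0.8) / 4 = 0.7
  cs4 <- combine_scores(list(a = m3, b = m4), c(a = 0.25, b = 0.75))
  expect_equal(unname(cs4["x|y"]), 0.7)
})

test_that("consensus equals the unweighted mean over nonzero sources at equal weights", {
  set.seed(51)
  keys <- sprintf("a%02d|b%02d", 1:30, 1:30)
  mats <- lapply(1:3, function(i) {
    pick <- sort(sample(30, 20))
    fake_matrix(paste0("s", i), keys[pick], runif(20))
  })
  names(mats) <- paste0("s", 1:3)
  w <- c(s1 = 0.5, s2 = 0.5, s3 = 0.5)
  cs <- combine_scores(mats, w)
  # oracle: mean over sources with a nonzero score
  for (k in names(cs)) {
    vals <- unlist(lapply(mats, function(m) m$cosine[m$key == k]))
    expect_equal(unname(cs[k]), mean(vals), tolerance = 1e-12)
  }
  # invariance to rescaling all weights
  cs2 <- combine_scores(mats, w * 7.3)
  expect_equal(as.numeric(cs2), as.numeric(cs), tolerance = 1e-12)
})

test_that("AUC matches the brute-force pairwise comparison", {
  s <- setNames(c(0.9, 0.4, 0.6, 0.1), c("p|p1", "p|p2", "n|n1", "n|n2"))
  pos <- c("p|p1", "p|p2")
  expect_equal(roc_auc(s, pos), 0.75)
  expect_equal(roc_auc(setNames(c(0.9, 0.8, 0.2, 0.1), names(s)), pos), 1.0)
  expect_equal(roc_auc(setNames(rep(0.5, 4), names(s)), pos), 0.5)
  expect_error(roc_auc(s, character(0)), "at least one")
  expect_error(roc_auc(s, names(s)), "at least one")

  set.seed(52)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    keys <- sprintf("k%03d|l%03d", 1:n, 1:n)
    sc <- setNames(round(runif(n), 2), keys)  # rounding forces ties
    pos <- sample(keys, sample(1:(n - 1), 1))
    expect_equal(roc_auc(sc, pos), bf_auc(sc, pos), tolerance = 1e-12)
  }
})

test_that("weight optimisation favors the informative source", {
  set.seed(53)
  keys <- sprintf("a%02d|b%02d", 1:20, 1:20)
  pos <- keys[1:6]
  good <- fake_matrix("good", keys, c(runif(6, 0.7, 1), runif(14, 0, 0.3)))
  bad <- fake_matrix("bad", keys, c(runif(6, 0, 0.3), runif(14, 0.7, 1)))
  mats <- list(good = good, bad = bad)

  ex <- optimize_weights(mats, pos, strategy = "exhaustive")
  ca <- optimize_weights(mats, pos, strategy = "coordinate_ascent",
                         seed = 5, restarts = 3)
  expect_equal(ca$auc, ex$auc, tolerance = 1e-12)
  expect_gt(ex$weights[["good"]] / ex$weights[["bad"]], 1)
  eq <- roc_auc(combine_scores(mats, c(good = 1, bad = 1)), pos)
  expect_gte(ex$auc, eq)

  # single source: any weight is optimal, tie-break picks 0.01
  one <- optimize_weights(list(good = good), pos, seed = 1)
  expect_equal(unname(one$weights), 0.01)
  expect_equal(one$auc, roc_auc(setNames(good$cosine, good$key), pos))
})

test_that("coordinate ascent attains the exhaustive optimum on 2-source fixtures", {
  set.seed(54)
  for (i in 1:3) {
    n <- 15
    keys <- sprintf("a%02d|b%02d", 1:n, 1:n)
    pos <- sample(keys, 5)
    mats <- list(s1 = fake_matrix("s1", keys, runif(n)),
                 s2 = fake_matrix("s2", sample(keys, 10), runif(10)))
    ex <- optimize_weights(mats, pos, strategy = "exhaustive")
    ca <- optimize_weights(mats, pos, seed = i, restarts = 3)
    expect_equal(ca$auc, ex$auc, tolerance = 1e-12)
  }
})
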