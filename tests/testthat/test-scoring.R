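test_that("cosine similarity matches hand values on incidence rows", {
  expect_equal(cosine_score(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(cosine_score(c(1, 0, 0), c(0, 1, 0)), 0.0)
  # fixture rows: d3 = (1,1,1), d2 = (1,1,0)
  expect_equal(cosine_score(c(1, 1, 1), c(1, 1, 0)), 2 / sqrt(6))
  expect_error(cosine_score(c(0, 0), c(1, 0)), "all-zero")
  expect_error(cosine_score(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("hypergeometric tail matches spot values and boundary behavior", {
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1.0)
  expect_equal(hypergeom_pvalue(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeom_pvalue(5, 3, 4, 10), "invalid")
  expect_error(hypergeom_pvalue(1, 3, 4, 2), "invalid")
})

test_that("hypergeometric tail is non-increasing in the observed count", {
  for (nz in c(5, 9, 12)) {
    for (nx in 1:nz) for (ny in 1:nz) {
      p <- hypergeom_pvalue(0:min(nx, ny), nx, ny, nz)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("fixture candidates are exactly the four expected pairs", {
  cm <- score_source(fig_graph())
  expect_setequal(cm$key, c("d1|d2", "d2|d3", "d3|d4", "d1|d4"))
  sc <- setNames(cm$cosine, cm$key)
  expect_equal(unname(sc["d1|d2"]), 1.0)
  expect_equal(unname(sc["d2|d3"]), 2 / sqrt(6), tolerance = 1e-12)
  expect_equal(unname(sc["d3|d4"]), 2 / sqrt(6), tolerance = 1e-12)
  expect_equal(unname(sc["d1|d4"]), 0.5)
  # the inferred (d2,d3) edge scores below the direct (d1,d2) edge
  expect_lt(sc["d2|d3"], sc["d1|d2"])
})

test_that("single-PPI and homo-domain candidates score 1", {
  ann <- list(A = "PF1", B = "PF2")
  g <- build_source_graph("s", data.frame(a = "A", b = "B"), ann)
  cm <- score_source(g)
  expect_equal(cm$key, "PF1|PF2")
  expect_equal(cm$cosine, 1.0)
  expect_equal(cm$k_xy, 1L)
  expect_equal(cm$n_x, 1L)
  expect_equal(cm$n_y, 1L)
  expect_equal(cm$n_z, 1L)

  ann2 <- list(A = "PF1", B = "PF1")
  cm2 <- score_source(build_source_graph("s", data.frame(a = "A", b = "B"), ann2))
  expect_equal(cm2$key, "PF1|PF1")
  expect_equal(cm2$cosine, 1.0)
})

test_that("stored counts reproduce the cosine computed from raw rows", {
  set.seed(21)
  ann <- setNames(lapply(1:25, function(i) {
    sample(sprintf("PF%02d", 1:12), sample(1:3, 1))
  }), sprintf("P%02d", 1:25))
  pairs <- data.frame(a = sample(names(ann), 60, TRUE),
                      b = sample(names(ann), 60, TRUE))
  g <- build_source_graph("s", pairs, ann)
  cm <- score_source(g)
  expect_true(all(cm$k_xy >= 1))
  expect_true(all(cm$k_xy <= pmin(cm$n_x, cm$n_y)))
  expect_true(all(cm$n_x <= cm$n_z & cm$n_y <= cm$n_z))
  for (i in sample(nrow(cm), min(25, nrow(cm)))) {
    a <- cm$domain_a[i]; b <- cm$domain_b[i]
    # recompute from raw rows in the winning orientation
    best <- -Inf
    for (o in list(c(a, b), c(b, a))) {
      if (o[1] %in% g$d_left && o[2] %in% g$d_right) {
        best <- max(best, cosine_score(as.numeric(g$m_left[o[1], ]),
                                       as.numeric(g$m_right[o[2], ])))
      }
    }
    expect_equal(cm$cosine[i], best, tolerance = 1e-12)
  }
})

test_that("Bonferroni flags use the merged family with a strict inequality", {
  m1 <- fake_matrix("a", sprintf("k%d|l%d", 1:4, 1:4), rep(0.5, 4),
                    p = rep(0.01, 4))
  flagged <- bonferroni_flags(list(a = m1), alpha = 0.05)
  expect_true(all(flagged$a$significant))  # 0.01 < 0.05/4

  m2 <- fake_matrix("a", sprintf("k%d|l%d", 1:4, 1:4), rep(0.5, 4),
                    p = rep(0.0125, 4))
  flagged2 <- bonferroni_flags(list(a = m2), alpha = 0.05)
  expect_false(any(flagged2$a$significant))  # p == alpha/n is not significant

  # the family is the union across sources
  m3 <- fake_matrix("b", sprintf("k%d|l%d", 3:6, 3:6), rep(0.5, 4),
                    p = rep(0.009, 4))
  flagged3 <- bonferroni_flags(list(a = m1, b = m3), alpha = 0.05)
  expect_equal(attr(flagged3$a, "n_tests"), 6L)
  expect_false(any(flagged3$a$significant))  # 0.01 >= 0.05/6
  expect_false(any(flagged3$b$significant))

  empty <- fake_matrix("a", character(), numeric(), p = numeric())
  expect_warning(bonferroni_flags(list(a = empty)), "no candidate")
})
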