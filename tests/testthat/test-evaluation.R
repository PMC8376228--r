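test_that("coverage follows the cross-protein domain-pair definition", {
  ann <- list(A = "PF1", B = "PF2")
  ppis <- data.frame(a = "A", b = "B")
  rep1 <- coverage(ppis, ann, "PF1|PF2")
  expect_equal(rep1$n_ppis_covered, 1)
  expect_equal(rep1$n_useful_ddis, 1)

  # a homo-DDI needs the domain on both sides of the interaction
  rep2 <- coverage(ppis, ann, "PF1|PF1")
  expect_equal(rep2$n_ppis_covered, 0)
  expect_equal(rep2$n_useful_ddis, 0)

  # fixture: (d2,d3) covers the first two PPIs only
  rep3 <- coverage(fig_pairs(), fig_annotations(), "d2|d3")
  expect_equal(rep3$n_ppis_total, 3)
  expect_equal(rep3$n_ppis_covered, 2)
  expect_equal(rep3$n_useful_ddis, 1)
  expect_equal(unname(rep3$per_ddi_cover_counts), 2L)

  # PPIs with an unannotated protein are excluded from the total
  rep4 <- coverage(data.frame(a = c("A", "A"), b = c("B", "Z9")), ann, "PF1|PF2")
  expect_equal(rep4$n_ppis_total, 1)
})

test_that("coverage agrees with the brute-force double loop", {
  set.seed(71)
  for (i in 1:10) {
    doms <- sprintf("PF%02d", 1:8)
    prots <- sprintf("P%02d", 1:15)
    ann <- setNames(lapply(prots, function(p) sample(doms, sample(1:3, 1))),
                    prots)
    ann[sample(prots, 2)] <- NULL  # some proteins unannotated
    ppis <- data.frame(a = sample(prots, 40, TRUE), b = sample(prots, 40, TRUE))
    dd <- unique(replicate(12, paste(sort(sample(doms, 2, TRUE), method = "radix"),
                                     collapse = "|")))
    got <- coverage(ppis, ann, dd)
    exp_ <- bf_coverage(ppis, ann, dd)
    expect_equal(got$n_ppis_total, exp_$n_ppis_total)
    expect_equal(got$n_ppis_covered, exp_$n_ppis_covered)
    expect_equal(got$n_useful_ddis, exp_$n_useful_ddis)
    expect_equal(got$per_ddi_cover_counts, exp_$per_ddi_cover_counts)
  }
})

test_that("three-way overlap counts every Venn region", {
  x <- c("a|b", "c|d")
  expect_equal(unname(overlap3(x, x, x)), c(0, 0, 0, 0, 0, 0, 2))
  expect_equal(unname(overlap3("a|b", "c|d", "e|f")),
               c(1, 1, 1, 0, 0, 0, 0))
  got <- overlap3(c("x|x", "y|y"), c("y|y", "z|z"), "z|z")
  expect_equal(got[["a_only"]], 1)
  expect_equal(got[["ab_only"]], 1)
  expect_equal(got[["bc_only"]], 1)
  expect_equal(sum(got), 3)  # |union|
  # region counts always sum to the union size
  set.seed(72)
  for (i in 1:10) {
    u <- sprintf("d%02d|e%02d", 1:20, 1:20)
    a <- sample(u, 8); b <- sample(u, 8); c <- sample(u, 8)
    expect_equal(sum(overlap3(a, b, c)), length(unique(c(a, b, c))))
  }
})

test_that("network statistics handle self-loops and small graphs", {
  ns <- network_stats("a|a")
  expect_equal(ns$n_nodes, 1)
  expect_equal(ns$n_edges, 1)
  expect_equal(ns$n_1node_ccs, 1)
  expect_equal(ns$degree_max, 1L)
  expect_equal(ns$n_homo_ddis, 1)

  ns2 <- network_stats(c("a|b", "b|c", "d|e"))
  expect_equal(ns2$n_nodes, 5)
  expect_equal(ns2$n_ccs, 2)
  expect_equal(ns2$giant_cc_size, 3)
  expect_equal(ns2$n_2node_ccs, 1)
  expect_equal(ns2$degree_max, 2L)
  expect_equal(ns2$argmax_node, "b")
  expect_equal(ns2$n_homo_ddis, 0)
  expect_error(network_stats(character(0)), "empty")
})

test_that("a 100-node path has 99%-degree 2 and full giant membership", {
  nodes <- sprintf("n%03d", 1:100)
  path <- paste(nodes[-100], nodes[-1], sep = "|")
  ns <- network_stats(path)
  expect_equal(ns$n_nodes, 100)
  expect_equal(ns$n_ccs, 1)
  expect_equal(ns$pct_nodes_in_giant, 100)
  expect_equal(ns$degree_sup_99, 2L)
  expect_equal(ns$degree_max, 2L)
})

test_that("component sizes agree with a brute-force flood fill", {
  set.seed(73)
  for (i in 1:8) {
    keys <- random_edges(sample(20:80, 1), sample(30:60, 1), seed = 730 + i)
    # add a couple of self-loops
    extra <- sprintf("z%02d|z%02d", 1:2, 1:2)
    keys <- c(keys, extra)
    ns <- network_stats(keys)
    sizes <- bf_components(keys)
    expect_equal(ns$n_nodes, sum(sizes))
    expect_equal(ns$n_ccs, length(sizes))
    expect_equal(ns$giant_cc_size, max(sizes))
    expect_equal(ns$n_1node_ccs, sum(sizes == 1))
    expect_equal(ns$n_2node_ccs, sum(sizes == 2))
  }
})
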