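test_that("prune merges edges, sums lengths and keeps distal supports", {
  t <- parse_newick("((A:1,B:2):3,C:4);")
  p <- prune(t, "B")
  expect_identical(write_newick(p), "(A:4,C:4);")
  expect_equal(patristic_matrix(p)["A", "C"], 8)

  # support bookkeeping: the surviving (distal) edge keeps its own support
  s <- parse_newick("(((A:1,B:1)0.8:1,C:1)0.5:1,(D:1,E:1)0.9:1);")
  ps <- prune(s, "C")
  ab <- which(!is.na(ps$support) & vapply(seq_along(ps$parent), function(v) {
    setequal(tip_labels_under_test(ps, v), c("A", "B"))
  }, logical(1)))
  expect_equal(ps$support[ab], 0.8)

  expect_error(prune(t, "Z"), "unknown tip")
  expect_identical(write_newick(prune(t, "Z", force = TRUE)), write_newick(t))
  expect_error(prune(t, c("A", "B")), "fewer than 2")
  # keep mode drops the complement
  k <- prune(s, c("A", "B", "C"), mode = "keep")
  expect_setequal(tip_labels(k), c("A", "B", "C"))
})

test_that("prune preserves patristic distances among survivors", {
  for (t in random_trees(30, sizes = c(8, 12, 20), seed = 17)) {
    tips <- tip_labels(t)
    drop <- sample(tips, length(tips) %/% 3)
    keep <- setdiff(tips, drop)
    before <- patristic_matrix(t)[keep, keep]
    after <- patristic_matrix(prune(t, drop))[keep, keep]
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("outgroup rerooting separates the outgroup and preserves splits", {
  r <- reroot_outgroup(parse_newick("((A,B),(C,D));"), c("C", "D"))
  side <- tip_labels_under_test(r, r$children[[r$root]][1])
  expect_true(setequal(side, c("C", "D")) || setequal(side, c("A", "B")))

  u <- reroot_outgroup(parse_newick("(A,B,(C,D));"), "A")
  expect_true(is_rooted(u))
  sides <- lapply(u$children[[u$root]], tip_labels_under_test, tree = u)
  expect_true(any(vapply(sides, identical, logical(1), "A")))

  expect_error(reroot_outgroup(parse_newick("((A,B),(C,D));"),
                               c("A", "B", "C", "D")), "all tips")
  expect_error(reroot_outgroup(parse_newick("((A,B),(C,D));"), "Z"), "not in tree")
  expect_warning(reroot_outgroup(parse_newick("((A,C),(B,D));"), c("A", "B")),
                 "not monophyletic")
})

test_that("rerooting preserves the split-length multiset and total length", {
  for (t in random_trees(25, sizes = c(6, 10, 18), seed = 23)) {
    og <- sample(tip_labels(t), 2)
    r1 <- suppressWarnings(reroot_outgroup(t, og))
    expect_identical(splits_with_lengths(r1), splits_with_lengths(t))
    expect_equal(sum(r1$length, na.rm = TRUE), sum(t$length, na.rm = TRUE),
                 tolerance = 1e-9)
    r2 <- reroot_midpoint(t)
    expect_identical(splits_with_lengths(r2), splits_with_lengths(t))
  }
})

test_that("midpoint rooting balances the two deepest tips", {
  m <- reroot_midpoint(parse_newick("(A:1,B:5);"))
  d <- node_depths_test(m)
  expect_equal(unname(sort(d)), c(3, 3))
  m2 <- reroot_midpoint(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(max(node_depths_test(m2)), 2)
  for (t in random_trees(10, sizes = 12, seed = 5)) {
    r <- reroot_midpoint(t)
    depths <- sort(node_depths_test(r), decreasing = TRUE)
    expect_lt(depths[1] - depths[2], 1e-9)
  }
  expect_error(reroot_midpoint(parse_newick("((A:1,B),C:2);")),
               "every branch length")
})

test_that("collapse contracts weak internal edges only, strictly below cutoff", {
  t <- parse_newick("((A,B)0.3:1,(C,D)0.9:1,E);")
  expect_identical(write_newick(collapse(t, "support", 0.7)),
                   "(A,B,(C,D)0.9:1,E);")
  # support-less edges are never collapsed under the support criterion
  t2 <- parse_newick("((A,B):1,(C,D)0.9:1,E);")
  expect_identical(write_newick(collapse(t2, "support", 0.99)),
                   "((A,B):1,C,D,E);")
  # strict comparison: cutoff 0 collapses nothing by length
  t3 <- parse_newick("((A:1,B:1):0,C:1);")
  expect_identical(write_newick(collapse(t3, "length", 0)), write_newick(t3))
  expect_identical(n_tips(collapse(t3, "length", 0.5)), 3L)
  expect_error(collapse(t, "length", -1), "non-negative")
  # tip set is invariant; retained lengths add up to total minus collapsed
  for (t in random_trees(10, sizes = 10, seed = 31)) {
    c1 <- collapse(t, "length", 0.3)
    expect_setequal(tip_labels(c1), tip_labels(t))
    internal <- which(lengths(t$children) > 0 & !is.na(t$parent))
    dropped <- sum(t$length[internal][t$length[internal] < 0.3])
    expect_equal(sum(c1$length, na.rm = TRUE),
                 sum(t$length, na.rm = TRUE) - dropped, tolerance = 1e-9)
  }
})

test_that("collapse hits the 0.9-kept case after support annotation", {
  t <- parse_newick("((A,B)0.5:1,((C,D)0.9:1,E)0.2:1);")
  ct <- collapse(t, "support", 0.7)
  expect_equal(sum(!is.na(ct$support)), 1)
  expect_equal(ct$support[!is.na(ct$support)], 0.9)
})

test_that("rename_tips renames, rejects collisions, tolerates missing", {
  t <- parse_newick("((A,B),C);")
  expect_setequal(tip_labels(rename_tips(t, c(A = "X"))), c("X", "B", "C"))
  expect_error(rename_tips(t, c(A = "B")), "duplicate")
  expect_error(rename_tips(t, c(Z = "Q")), "match no")
  expect_setequal(tip_labels(rename_tips(t, c(Z = "Q"), allow_missing = TRUE)),
                  c("A", "B", "C"))
})

test_that("resolve produces deterministic strictly binary trees", {
  t <- parse_newick("(A,B,C,D);")
  r <- resolve(t, seed = 7)
  expect_true(is_binary(r) && is_rooted(r))
  expect_setequal(tip_labels(r), tip_labels(t))
  new_edges <- sum(lengths(r$children) > 0) - 1L
  expect_true(new_edges %in% 1:2)
  expect_true(all(r$length[!is.na(r$length)] == 0))
  expect_identical(write_newick(resolve(t, seed = 7)), write_newick(r))
  bin <- parse_newick("((A:1,B:2):3,C:4);")
  expect_identical(write_newick(resolve(bin, seed = 1)), write_newick(bin))
  big <- resolve(parse_newick("(A,B,(C,D,E,F),G,H);"), seed = 3)
  expect_true(is_binary(big))
})

test_that("random_tree models have the right shapes and sizes", {
  for (model in c("yule", "uniform")) {
    t <- random_tree(8, model, seed = 2)
    expect_equal(n_tips(t), 8)
    expect_equal(sum(lengths(t$children) > 0), 7)   # rooted binary
    expect_true(is_binary(t) && is_rooted(t))
    expect_true(all(t$length[-t$root] > 0))
    expect_identical(write_newick(random_tree(8, model, seed = 2)),
                     write_newick(t))
  }
  expect_equal(colless(random_tree(5, "caterpillar")), 6)
  expect_equal(colless(random_tree(8, "balanced")), 0)
  expect_true(all(random_tree(6, "caterpillar")$length[-1] == 1))
  expect_error(random_tree(2, "yule"), "at least 3")
  expect_error(random_tree(6, "balanced"), "power of 2")
})

test_that("uniform topologies on 5 tips are equiprobable over the 105 classes", {
  keys <- vapply(1:5250, function(s) {
    paste(sort(bipartitions_rooted_key(random_tree(5, "uniform", seed = s))),
          collapse = ";")
  }, character(1))
  freq <- table(keys)
  expect_equal(length(freq), 105)
  expect_true(all(abs(as.numeric(freq) / length(keys) - 1 / 105) < 0.01))
})
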