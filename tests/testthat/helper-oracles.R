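# Independent oracles used across the suite. They deliberately avoid the
# package's own bipartition/traversal machinery: tree structure is taken
# from ape (via Newick text), so agreement is a genuine cross-check.

to_ape <- function(tree) ape::read.tree(text = write_newick(tree))

# every edge of a tree as the tip-name set of its child side (tip edges
# included), computed with ape
ape_edge_sides <- function(tree) {
  at <- to_ape(tree)
  n <- length(at$tip.label)
  lapply(seq_len(nrow(at$edge)), function(i) {
    ch <- at$edge[i, 2]
    if (ch <= n) at$tip.label[ch] else {
      ape::extract.clade(at, ch)$tip.label
    }
  })
}

# brute-force non-trivial split keys of a tree, canonicalized like the
# package (side not containing the alphabetically smallest tip)
brute_split_keys <- function(tree) {
  tips <- sort(tip_labels(tree))
  keys <- vapply(ape_edge_sides(tree), function(side) {
    if (min(length(side), length(tips) - length(side)) < 2) return(NA_character_)
    if (tips[1] %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = ",")
  }, character(1))
  unique(keys[!is.na(keys)])
}

brute_rf <- function(t1, t2) {
  k1 <- brute_split_keys(t1); k2 <- brute_split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# naive transfer distance: explicit loop over every edge and both
# orientations of the query split
naive_transfer_distance <- function(side, tree) {
  tips <- sort(tip_labels(tree))
  b <- tips %in% side
  best <- Inf
  for (es in ape_edge_sides(tree)) {
    e <- tips %in% es
    best <- min(best, sum(b != e), sum(b == e))
  }
  as.integer(best)
}

# naive TBE: per ref split, per bootstrap tree, per edge, per orientation —
# explicit O(splits * edges * n) loops; edge tip sets come from ape once
# per bootstrap tree
naive_tbe <- function(ref, boots) {
  rb <- bipartitions(ref)
  sizes <- attr(rb, "sizes")
  tips <- sort(tip_labels(ref))
  boot_sides <- lapply(boots, ape_edge_sides)
  supp <- numeric(length(rb)); mdelta <- numeric(length(rb))
  for (i in seq_along(rb)) {
    b <- tips %in% strsplit(rb[i], ",", fixed = TRUE)[[1]]
    deltas <- vapply(boot_sides, function(sides) {
      best <- Inf
      for (es in sides) {
        e <- tips %in% es
        best <- min(best, sum(b != e), sum(b == e))
      }
      best
    }, numeric(1))
    supp[i] <- mean(pmax(1 - deltas / (sizes[i] - 1), 0))
    mdelta[i] <- mean(deltas)
  }
  data.frame(split = as.character(rb), p = sizes, support = supp,
             mean_transfer_dist = mdelta, stringsAsFactors = FALSE)
}

# independent closed-form distance evaluations, re-typed from the classical
# references (shared by the distance and acceptance suites)
oracle_jc <- function(p) -0.75 * log(1 - 4 * p / 3)
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
oracle_f81 <- function(p, pi) { E <- 1 - sum(pi^2); -E * log(1 - p / E) }
oracle_f84 <- function(P, Q, pi) {
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  A <- piC * piT / piY + piA * piG / piR
  B <- piC * piT + piA * piG
  C <- piR * piY
  -2 * A * log(1 - P / (2 * A) - (A - B) * Q / (2 * A * C)) +
    2 * (A - B - C) * log(1 - Q / (2 * C))
}
oracle_tn93 <- function(P1, P2, Q, pi) {
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  k1 <- 2 * piA * piG / piR; k2 <- 2 * piC * piT / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
  -k1 * log(1 - P1 / k1 - Q / (2 * piR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * piY)) -
    k3 * log(1 - Q / (2 * piR * piY))
}
oracle_poisson20 <- function(p) -(19 / 20) * log(1 - 20 * p / 19)

# two sequences realizing exact (P1, P2, Q) proportions over n sites
pair_with_counts <- function(n, nP1, nP2, nQ) {
  base <- rep(c("A", "C", "G", "T"), length.out = n)
  other <- base
  if (nP1 > 0) { idx <- which(base == "A")[seq_len(nP1)]; other[idx] <- "G" }
  if (nP2 > 0) { idx <- which(base == "C")[seq_len(nP2)]; other[idx] <- "T" }
  if (nQ > 0) { idx <- which(base == "G")[seq_len(nQ)]; other[idx] <- "C" }
  list(s1 = paste(base, collapse = ""), s2 = paste(other, collapse = ""))
}

# unrooted (split, length) multiset; the two edges of a bifurcating root
# describe one split whose length is their sum
splits_with_lengths <- function(tree) {
  tips <- sort(tip_labels(tree))
  tu <- tips_under(tree)
  acc <- list()
  for (v in seq_along(tree$parent)) {
    if (is.na(tree$parent[v])) next
    side <- colnames(tu)[tu[v, ]]
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = ",")
    acc[[key]] <- sum(c(acc[[key]], tree$length[v]), na.rm = TRUE)
  }
  sort(vapply(names(acc), function(k) {
    paste0(k, "=", sprintf("%.9f", acc[[k]]))
  }, character(1)))
}

# brute-force tip depths by following parent pointers one tip at a time
brute_tip_depths <- function(tree) {
  vapply(tip_ids(tree), function(v) {
    d <- 0L
    while (!is.na(tree$parent[v])) { v <- tree$parent[v]; d <- d + 1L }
    d
  }, integer(1))
}

# mixed bag of random trees for property tests
random_trees <- function(n, sizes = 5:30, seed = 1) {
  lapply(seq_len(n), function(i) {
    random_tree(sizes[(i - 1L) %% length(sizes) + 1L],
                model = if (i %% 2 == 0) "yule" else "uniform",
                seed = seed * 1000 + i)
  })
}

expect_same_tree <- function(t1, t2) {
  expect_identical(sort(tip_labels(t1)), sort(tip_labels(t2)))
  expect_identical(splits_with_lengths(t1), splits_with_lengths(t2))
}

tip_labels_under_test <- function(tree, v) {
  tu <- phylokit:::tips_under(tree)
  colnames(tu)[tu[v, ]]
}

node_depths_test <- function(tree) {
  phylokit:::node_depths(tree, use_lengths = TRUE)[phylokit:::tip_ids(tree)]
}

# rooted-topology fingerprint: the set of clade tip sets
bipartitions_rooted_key <- function(tree) {
  tu <- phylokit:::tips_under(tree)
  keys <- apply(tu[lengths(tree$children) > 0, , drop = FALSE], 1, function(r) {
    paste(sort(colnames(tu)[r]), collapse = ",")
  })
  unique(keys)
}
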