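#' Tree summary statistics
#'
#' @param tree a [phytree].
#' @return A list with tip/node/edge counts, branch-length summaries
#'   (`NA` when no lengths are present), mean support over supported edges,
#'   the number of cherries, Colless and Sackin imbalance (`NA` for
#'   unrooted input, Colless also `NA` for non-binary trees), and the
#'   rooted flag.
#' @export
tree_stats <- function(tree) {
  lens <- tree$length[-tree$root]
  lens_ok <- lens[!is.na(lens)]
  sups <- tree$support[!is.na(tree$support)]
  rooted <- is_rooted(tree)
  list(
    n_tips = n_tips(tree),
    n_internal_nodes = sum(lengths(tree$children) > 0L),
    n_edges = length(tree$parent) - 1L,
    sum_length = if (length(lens_ok)) sum(lens_ok) else NA_real_,
    mean_length = if (length(lens_ok)) mean(lens_ok) else NA_real_,
    min_length = if (length(lens_ok)) min(lens_ok) else NA_real_,
    max_length = if (length(lens_ok)) max(lens_ok) else NA_real_,
    mean_support = if (length(sups)) mean(sups) else NA_real_,
    n_cherries = count_cherries(tree),
    colless = if (rooted && is_binary_rooted(tree)) colless(tree) else NA_integer_,
    sackin = if (rooted) sackin(tree) else NA_integer_,
    rooted = rooted)
}

is_binary_rooted <- function(tree) {
  is_rooted(tree) && all(lengths(tree$children) %in% c(0L, 2L))
}

#' Count cherries
#'
#' A cherry is an internal node with exactly two tip children; this counts
#' the root cherry of a two-tip rooted tree and matches the unrooted
#' reading on larger trees.
#'
#' @param tree a [phytree].
#' @return Integer cherry count.
#' @export
count_cherries <- function(tree) {
  tips <- lengths(tree$children) == 0L
  sum(vapply(which(!tips), function(v) {
    sum(tips[tree$children[[v]]]) == 2L
  }, logical(1)))
}

#' Tree imbalance indices
#'
#' `colless()` sums, over the internal nodes of a rooted binary tree, the
#' absolute difference between the tip counts of the two child subtrees.
#' `sackin()` sums the root-to-tip depths of all tips, counted in edges.
#'
#' @param tree a rooted [phytree] (binary for Colless).
#' @return Integer index value.
#' @export
colless <- function(tree) {
  if (!is_rooted(tree)) stop("Colless index requires a rooted tree")
  if (!all(lengths(tree$children) %in% c(0L, 2L))) {
    stop("Colless index requires a binary tree")
  }
  cnt <- integer(length(tree$parent))
  total <- 0L
  for (v in postorder_nodes(tree)) {
    ch <- tree$children[[v]]
    if (!length(ch)) { cnt[v] <- 1L; next }
    cnt[v] <- sum(cnt[ch])
    total <- total + abs(cnt[ch[1]] - cnt[ch[2]])
  }
  total
}

#' @rdname colless
#' @export
sackin <- function(tree) {
  if (!is_rooted(tree)) stop("Sackin index requires a rooted tree")
  d <- node_depths(tree, use_lengths = FALSE)
  as.integer(sum(d[tip_ids(tree)]))
}

#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j. Computed in one postorder sweep that combines, at every
#' internal node, the tip distances of its child subtrees.
#'
#' @param tree a [phytree] with every branch length present.
#' @return A symmetric `dist_matrix` with zero diagonal, tip labels as
#'   dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (any(is.na(tree$length[-tree$root]))) {
    stop("patristic distances require every branch length")
  }
  tips <- tip_ids(tree)
  n <- length(tips)
  tipnum <- integer(length(tree$parent)); tipnum[tips] <- seq_len(n)
  d <- matrix(0, n, n, dimnames = list(tree$label[tips], tree$label[tips]))
  # below[[v]]: tip indices under v; dist[[v]]: their distances to v
  below <- vector("list", length(tree$parent))
  dist <- vector("list", length(tree$parent))
  for (v in postorder_nodes(tree)) {
    ch <- tree$children[[v]]
    if (!length(ch)) {
      below[[v]] <- tipnum[v]; dist[[v]] <- 0
      next
    }
    bs <- lapply(ch, function(c) below[[c]])
    ds <- lapply(seq_along(ch), function(k) dist[[ch[k]]] + tree$length[ch[k]])
    if (length(ch) > 1L) {
      for (a in seq_len(length(ch) - 1L)) for (b in (a + 1L):length(ch)) {
        ia <- bs[[a]]; ib <- bs[[b]]
        d[ia, ib] <- outer(ds[[a]], ds[[b]], `+`)
        d[ib, ia] <- t(d[ia, ib, drop = FALSE])
      }
    }
    below[[v]] <- unlist(bs); dist[[v]] <- unlist(ds)
  }
  structure(d, class = c("dist_matrix", class(d)))
}

#' Tabulate statistics for a list of trees
#'
#' One row per tree, tab-separated with a header; the layout of the
#' `stats` subcommand.
#'
#' @param trees a list of [phytree] objects.
#' @return A data frame (printed as TSV by the CLI).
#' @export
trees_stats_table <- function(trees) {
  if (inherits(trees, "phytree")) trees <- list(trees)
  rows <- lapply(seq_along(trees), function(i) {
    s <- tree_stats(trees[[i]])
    data.frame(tree = i, s[c("n_tips", "n_internal_nodes", "n_edges",
                             "sum_length", "mean_length", "mean_support",
                             "n_cherries", "colless", "sackin", "rooted")],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
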