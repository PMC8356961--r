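# Bootstrap branch supports on a reference tree.
#
# FBP (Felsenstein bootstrap proportion): the fraction of bootstrap trees
# whose bipartition set contains the reference branch's split exactly.
# TBE (transfer bootstrap expectation): the mean over bootstrap trees of
# 1 - delta/(p - 1), where delta is the transfer distance from the
# reference split to the closest branch of the bootstrap tree and p is the
# reference split's light-side size. TBE degrades gracefully on deep
# branches of noisy bootstrap sets, where FBP collapses to zero.

# indicator matrix (one row per edge = non-root node, tip edges included)
# over the tip universe `universe` (character vector fixing column order)
edge_indicators <- function(tree, universe) {
  tu <- tips_under(tree)
  m <- tu[!is.na(tree$parent), , drop = FALSE]
  m[, universe, drop = FALSE]
}

#' Transfer distance from a bipartition to a tree
#'
#' The minimum number of tips that must change sides to turn the query
#' split into a split of the tree: the Hamming distance between indicator
#' vectors, minimized over the two orientations and over every edge of the
#' tree (tip edges included). Zero exactly when the split occurs in the
#' tree; never more than `p - 1` (a tip edge inside the light side realizes
#' that bound).
#'
#' @param side character vector: the tip names on one side of the split.
#' @param tree a [phytree] whose tip set is the split's universe.
#' @return Integer minimum transfer distance.
#' @export
transfer_distance <- function(side, tree) {
  universe <- sort(tip_labels(tree))
  if (length(setdiff(side, universe))) {
    stop("split contains tips absent from the tree: ",
         paste(setdiff(side, universe), collapse = ", "))
  }
  b <- universe %in% side
  E <- edge_indicators(tree, universe)
  h <- colSums(t(E) != b)
  as.integer(min(pmin(h, length(universe) - h)))
}

# all-pairs transfer distances: rows of B (ref splits) against all edges of
# one bootstrap tree, via 0/1 matrix products
min_transfer_distances <- function(B, boot, universe) {
  E <- edge_indicators(boot, universe)
  storage.mode(E) <- "double"
  n <- length(universe)
  rsB <- rowSums(B); rsE <- rowSums(E)
  # Hamming(b, e) = |b| + |e| - 2 b.e
  H <- outer(rsB, rsE, `+`) - 2 * (B %*% t(E))
  H <- pmin(H, n - H)
  apply(H, 1, min)
}

annotate_supports <- function(ref, keys, values) {
  tu <- tips_under(ref)
  n <- ncol(tu)
  smallest <- min(colnames(tu))
  for (v in which(lengths(ref$children) > 0L & !is.na(ref$parent))) {
    side <- tu[v, ]
    if (min(sum(side), n - sum(side)) < 2L) next
    if (side[[smallest]]) side <- !side
    key <- paste(sort(colnames(tu)[side]), collapse = ",")
    i <- match(key, keys)
    if (!is.na(i)) ref$support[v] <- signif(values[i], 6)
  }
  ref
}

check_boot_tips <- function(ref, boots) {
  if (!length(boots)) stop("empty bootstrap tree list")
  universe <- sort(tip_labels(ref))
  bad <- which(vapply(boots, function(b) {
    !setequal(tip_labels(b), universe)
  }, logical(1)))
  if (length(bad)) {
    stop("bootstrap tree(s) ", paste(bad, collapse = ", "),
         " do not share the reference tip set")
  }
  universe
}

support_result <- function(ref, keys, sizes, support, mean_transfer) {
  structure(list(
    tree = annotate_supports(ref, keys, support),
    table = data.frame(split = keys, p = sizes, support = support,
                       mean_transfer_dist = mean_transfer,
                       stringsAsFactors = FALSE)),
    class = "support_result")
}

#' @export
print.support_result <- function(x, ...) {
  cat(sprintf("<support_result: %d branch(es)>\n", nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Felsenstein bootstrap proportions
#'
#' @param ref reference [phytree].
#' @param boots list of bootstrap [phytree]s on the same tip set.
#' @return A `support_result`: the reference tree with supports in `[0, 1]`
#'   written on its non-trivial internal edges, plus a per-branch table.
#' @export
fbp <- function(ref, boots) {
  check_boot_tips(ref, boots)
  rb <- bipartitions(ref)
  boot_sets <- lapply(boots, bipartitions)
  supp <- vapply(rb, function(k) {
    mean(vapply(boot_sets, function(s) k %in% s, logical(1)))
  }, numeric(1))
  support_result(ref, as.character(rb), attr(rb, "sizes"), unname(supp),
                 rep(NA_real_, length(rb)))
}

#' Transfer bootstrap expectation
#'
#' @inheritParams fbp
#' @return A `support_result` as for [fbp()], with the per-branch mean
#'   transfer distance as diagnostic. Supports are clamped to `[0, 1]`.
#' @export
tbe <- function(ref, boots) {
  universe <- check_boot_tips(ref, boots)
  rb <- bipartitions(ref)
  sizes <- attr(rb, "sizes")
  if (!length(rb)) return(support_result(ref, character(0), integer(0),
                                         numeric(0), numeric(0)))
  B <- t(vapply(strsplit(rb, ",", fixed = TRUE), function(s) {
    universe %in% s
  }, logical(length(universe))))
  storage.mode(B) <- "double"
  # canonical side vs its complement is irrelevant: Hamming is minimized
  # over orientations anyway
  deltas <- vapply(boots, function(bt) {
    min_transfer_distances(B, bt, universe)
  }, numeric(length(rb)))
  deltas <- matrix(deltas, nrow = length(rb))
  contrib <- 1 - deltas / (sizes - 1L)
  contrib[contrib < 0] <- 0
  supp <- pmin(pmax(rowMeans(contrib), 0), 1)
  support_result(ref, as.character(rb), sizes, unname(supp),
                 rowMeans(deltas))
}
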