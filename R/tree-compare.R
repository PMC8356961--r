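#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted tree splits the tips into two sides.
#' The canonical form of a split is the side that does NOT contain the
#' lexicographically smallest tip name, written as the sorted names joined
#' by `","`. Trivial splits (one side smaller than 2) are excluded, and the
#' two root edges of a rooted tree contribute a single split.
#'
#' @param tree a [phytree].
#' @return Character vector of canonical split keys, with attribute
#'   `"sizes"` giving each split's light-side size
#'   `p = min(|side|, n - |side|)`.
#' @export
bipartitions <- function(tree) {
  tu <- tips_under(tree)
  n <- ncol(tu)
  smallest <- min(colnames(tu))
  internal <- which(lengths(tree$children) > 0L & !is.na(tree$parent))
  keys <- character(0); sizes <- integer(0)
  seen <- character(0)
  for (v in internal) {
    side <- tu[v, ]
    k <- sum(side)
    if (min(k, n - k) < 2L) next
    if (side[[smallest]]) side <- !side
    key <- paste(sort(colnames(tu)[side]), collapse = ",")
    if (key %in% seen) next  # the two root edges induce the same split
    seen <- c(seen, key)
    keys <- c(keys, key); sizes <- c(sizes, min(k, n - k))
  }
  structure(keys, sizes = sizes)
}

#' Compare two tree topologies via bipartitions
#'
#' Both trees are reduced to their canonical bipartition sets (rooted trees
#' are therefore compared as unrooted). The Robinson-Foulds (bipartition)
#' distance is the number of splits present in exactly one tree.
#'
#' @param ref,comp [phytree]s on identical tip sets.
#' @return List with `n_common`, `n_ref_only`, `n_comp_only` and
#'   `rf_distance`.
#' @export
compare_trees <- function(ref, comp) {
  t1 <- tip_labels(ref); t2 <- tip_labels(comp)
  if (!setequal(t1, t2)) {
    stop("tip sets differ (only in ref: ",
         paste(setdiff(t1, t2), collapse = ","), "; only in comp: ",
         paste(setdiff(t2, t1), collapse = ","), ")")
  }
  b1 <- bipartitions(ref); b2 <- bipartitions(comp)
  common <- sum(b1 %in% b2)
  list(n_common = common,
       n_ref_only = length(b1) - common,
       n_comp_only = length(b2) - common,
       rf_distance = length(b1) + length(b2) - 2L * common)
}

#' Compare tip name sets
#'
#' @param t1,t2 [phytree]s.
#' @return List with `only_in_1`, `only_in_2`, `common` (sorted). A warning
#'   is emitted when the trees share no tips.
#' @export
compare_tips <- function(t1, t2) {
  a <- tip_labels(t1); b <- tip_labels(t2)
  common <- sort(intersect(a, b))
  if (!length(common)) warning("trees share no tip names")
  list(only_in_1 = sort(setdiff(a, b)),
       only_in_2 = sort(setdiff(b, a)),
       common = common)
}
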