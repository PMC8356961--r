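#' Phylogenetic tree objects
#'
#' A `phytree` stores a rooted or unrooted edge-weighted tree as parallel
#' node vectors. Node 1..N are both tips and internal nodes; tips are the
#' nodes without children. Each non-root node carries the branch (length,
#' support) of the edge connecting it to its parent. A tree is considered
#' rooted when the root node has exactly two children, unrooted otherwise
#' (the usual Newick convention: a basal trichotomy encodes an unrooted
#' tree).
#'
#' @param parent integer vector, one entry per node; `NA` for the root.
#' @param children list of integer vectors giving each node's children in
#'   display order; empty for tips.
#' @param label character node labels; tips must be labelled, internal
#'   labels are optional.
#' @param length numeric branch lengths to the parent (`NA` when absent).
#' @param support numeric branch supports (`NA` when absent).
#' @return An object of class `phytree`.
#' @export
phytree <- function(parent, children, label, length, support) {
  t <- structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), length = as.numeric(length),
         support = as.numeric(support),
         root = which(is.na(parent))[1L]),
    class = "phytree")
  validate_phytree(t)
  t
}

validate_phytree <- function(t) {
  n <- length(t$parent)
  if (n < 1L) stop("tree has no nodes")
  roots <- which(is.na(t$parent))
  if (length(roots) != 1L) stop("tree must have exactly one root")
  tips <- which(lengths(t$children) == 0L)
  lab <- t$label[tips]
  if (anyNA(lab) || any(!nzchar(lab))) stop("every tip must have a non-empty label")
  if (anyDuplicated(lab)) {
    stop("duplicate tip labels: ", paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (any(t$length < 0, na.rm = TRUE)) stop("negative branch length")
  if (any(!is.finite(t$support) & !is.na(t$support))) stop("non-finite branch support")
  # children/parent must agree and the graph must be connected and acyclic
  for (v in seq_len(n)) {
    for (c in t$children[[v]]) {
      if (t$parent[c] != v) stop("children/parent tables disagree")
    }
  }
  if (length(postorder_nodes(t)) != n) stop("tree graph is not connected")
  invisible(t)
}

#' @export
print.phytree <- function(x, ...) {
  cat(sprintf("<phytree: %d tips, %d internal nodes, %s>\n",
              n_tips(x), sum(lengths(x$children) > 0L),
              if (is_rooted(x)) "rooted" else "unrooted"))
  nwk <- write_newick(x)
  if (nchar(nwk) > 70) nwk <- paste0(substr(nwk, 1, 67), "...")
  cat(" ", nwk, "\n")
  invisible(x)
}

#' Basic tree accessors
#'
#' @param tree a `phytree`.
#' @return `n_tips()` the number of tips; `tip_labels()` their labels in
#'   node order; `is_rooted()` whether the root is bifurcating;
#'   `is_binary()` whether every internal node (root included when rooted)
#'   resolves into exactly two children.
#' @export
n_tips <- function(tree) sum(lengths(tree$children) == 0L)

#' @rdname n_tips
#' @export
tip_labels <- function(tree) tree$label[lengths(tree$children) == 0L]

#' @rdname n_tips
#' @export
is_rooted <- function(tree) length(tree$children[[tree$root]]) == 2L

#' @rdname n_tips
#' @export
is_binary <- function(tree) {
  deg <- lengths(tree$children)
  internal <- which(deg > 0L & seq_along(deg) != tree$root)
  all(deg[internal] == 2L) && deg[tree$root] %in% c(2L, 3L)
}

tip_ids <- function(tree) which(lengths(tree$children) == 0L)

#' Node traversal orders
#'
#' Iterative traversals (no recursion limit). `postorder_nodes()` lists
#' children before parents, `preorder_nodes()` the reverse.
#'
#' @param tree a `phytree`.
#' @return integer vector of node indices.
#' @keywords internal
postorder_nodes <- function(tree) rev(preorder_nodes(tree))

preorder_nodes <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n); k <- 0L
  stack <- tree$root; top <- 1L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; out[k] <- v
    ch <- tree$children[[v]]
    for (c in rev(ch)) { top <- top + 1L; stack[top] <- c }
  }
  out[seq_len(k)]
}

# depth of every node from the root, in edge counts and in branch lengths
node_depths <- function(tree, use_lengths = FALSE) {
  d <- numeric(length(tree$parent))
  for (v in preorder_nodes(tree)) {
    p <- tree$parent[v]
    if (!is.na(p)) {
      step <- if (use_lengths) tree$length[v] else 1
      d[v] <- d[p] + step
    }
  }
  d
}

# logical matrix (nodes x tips): which tips descend from each node.
# Tip columns are ordered by tip node index.
tips_under <- function(tree) {
  tips <- tip_ids(tree)
  n <- length(tree$parent)
  m <- matrix(FALSE, n, length(tips))
  m[cbind(tips, seq_along(tips))] <- TRUE
  for (v in postorder_nodes(tree)) {
    p <- tree$parent[v]
    if (!is.na(p)) m[p, ] <- m[p, ] | m[v, ]
  }
  colnames(m) <- tree$label[tips]
  m
}

# rebuild a phytree keeping only nodes in `keep` (logical), preserving order,
# after the caller has fixed parent/children consistency on the kept subset.
compact_tree <- function(parent, children, label, length, support, keep) {
  idx <- which(keep)
  remap <- integer(length(parent)); remap[idx] <- seq_along(idx)
  phytree(parent = ifelse(is.na(parent[idx]), NA_integer_, remap[parent[idx]]),
          children = lapply(children[idx], function(ch) remap[ch]),
          label = label[idx], length = length[idx], support = support[idx])
}
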