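#' Remove tips from a tree
#'
#' Removes the selected tips (or, with `mode = "keep"`, all others), then
#' suppresses the resulting degree-2 nodes by summing branch lengths along
#' merged paths. When two edges merge, the merged edge keeps the support of
#' the edge that was farther from the root, so patristic distances among
#' surviving tips are preserved exactly.
#'
#' @param tree a [phytree].
#' @param tips character vector of tip labels.
#' @param mode `"remove"` (drop the listed tips) or `"keep"` (drop their
#'   complement).
#' @param force when `FALSE` (default), an unknown tip name is an error.
#' @return The pruned [phytree] (at least two tips must survive).
#' @export
prune <- function(tree, tips, mode = c("remove", "keep"), force = FALSE) {
  mode <- match.arg(mode)
  all_tips <- tip_labels(tree)
  unknown <- setdiff(tips, all_tips)
  if (length(unknown) && !force) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  drop <- if (mode == "remove") intersect(tips, all_tips) else {
    setdiff(all_tips, tips)
  }
  if (length(all_tips) - length(drop) < 2L) {
    stop("fewer than 2 tips would remain")
  }
  parent <- tree$parent; children <- tree$children
  label <- tree$label; len <- tree$length; sup <- tree$support
  keep <- rep(TRUE, length(parent))
  remove_node <- function(v) {
    keep[v] <<- FALSE
    p <- parent[v]
    if (!is.na(p)) children[[p]] <<- setdiff(children[[p]], v)
  }
  for (v in tip_ids(tree)) if (label[v] %in% drop) remove_node(v)
  repeat {
    changed <- FALSE
    for (v in which(keep)) {
      nch <- length(children[[v]])
      if (nch == 0L && is.na(label[v])) {        # emptied internal node
        remove_node(v); changed <- TRUE
      } else if (nch == 1L && !is.na(parent[v])) # degree-2: merge edges
      {
        c1 <- children[[v]]
        len[c1] <- sum(c(len[c1], len[v]), na.rm = FALSE)
        # support of c1 (farther from root) is kept as is
        parent[c1] <- parent[v]
        i <- match(v, children[[parent[v]]])
        children[[parent[v]]][i] <- c1
        keep[v] <- FALSE
        changed <- TRUE
      } else if (nch == 1L && is.na(parent[v])) { # root with single child
        c1 <- children[[v]]
        parent[c1] <- NA_integer_
        len[c1] <- NA_real_; sup[c1] <- NA_real_
        keep[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  compact_tree(parent, children, label, len, sup, keep)
}

# ---- rerooting ----

# Place a new root on the edge above `node`, at `position` branch-length
# units from `node`. Parent pointers along the old root path are reversed;
# both halves of the split edge inherit its support; an old root left with
# a single child is suppressed (its remaining edge merged downward).
reroot_above <- function(tree, node, position = NULL) {
  p0 <- tree$parent[node]
  if (is.na(p0)) stop("cannot reroot above the root")
  edge_len <- tree$length[node]
  if (is.null(position)) position <- if (is.na(edge_len)) NA_real_ else edge_len / 2
  parent <- tree$parent; children <- tree$children
  label <- tree$label; len <- tree$length; sup <- tree$support
  n <- length(parent)
  # path from the old parent up to the old root
  path <- integer(0); v <- p0
  while (!is.na(v)) { path <- c(path, v); v <- parent[v] }
  old_len <- len; old_sup <- sup
  newroot <- n + 1L
  parent <- c(parent, NA_integer_); label <- c(label, NA_character_)
  len <- c(len, NA_real_); sup <- c(sup, NA_real_)
  children <- c(children, list(c(node, p0)))
  children[[p0]] <- setdiff(children[[p0]], node)
  parent[node] <- newroot
  len[node] <- position
  parent[p0] <- newroot
  len[p0] <- if (is.na(edge_len)) NA_real_ else edge_len - position
  sup[p0] <- old_sup[node]  # both halves carry the split edge's support
  # reverse the remaining path edges
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      ch <- path[i]; pa <- path[i + 1L]
      children[[pa]] <- setdiff(children[[pa]], ch)
      children[[ch]] <- c(children[[ch]], pa)
      parent[pa] <- ch
      len[pa] <- old_len[ch]
      sup[pa] <- old_sup[ch]
    }
  }
  oldroot <- path[length(path)]
  len[oldroot] <- if (identical(oldroot, p0)) len[p0] else old_len[path[length(path) - 1L]]
  keep <- rep(TRUE, length(parent))
  # suppress an old root that is now degree-2 (one child + its new parent)
  if (length(children[[oldroot]]) == 1L) {
    c1 <- children[[oldroot]]
    len[c1] <- sum(c(len[c1], len[oldroot]), na.rm = FALSE)
    parent[c1] <- parent[oldroot]
    i <- match(oldroot, children[[parent[oldroot]]])
    children[[parent[oldroot]]][i] <- c1
    keep[oldroot] <- FALSE
  }
  compact_tree(parent, children, label, len, sup, keep)
}

mrca_node <- function(tree, tips) {
  ids <- match(tips, tree$label)
  anc <- function(v) { out <- v; while (!is.na(tree$parent[v])) { v <- tree$parent[v]; out <- c(out, v) }; out }
  common <- Reduce(intersect, lapply(ids, anc))
  common[1]
}

#' Reroot with an outgroup
#'
#' Places the root on the edge above the smallest clade containing all
#' outgroup tips, splitting that edge at its midpoint. If the outgroup is
#' not monophyletic in the result a warning is emitted. The unrooted
#' bipartition multiset (lengths included) is unchanged.
#'
#' @param tree a [phytree].
#' @param outgroup non-empty proper subset of the tip labels.
#' @return The rerooted (bifurcating-root) [phytree].
#' @export
reroot_outgroup <- function(tree, outgroup) {
  all_tips <- tip_labels(tree)
  if (!length(outgroup)) stop("empty outgroup")
  unknown <- setdiff(outgroup, all_tips)
  if (length(unknown)) stop("outgroup tips not in tree: ",
                            paste(unknown, collapse = ", "))
  if (setequal(outgroup, all_tips)) stop("outgroup cannot contain all tips")
  m <- mrca_node(tree, outgroup)
  if (m == tree$root) {
    # provisional rooting on the edge of a non-outgroup tip
    t0 <- setdiff(all_tips, outgroup)[1]
    tree <- reroot_above(tree, match(t0, tree$label))
    m <- mrca_node(tree, outgroup)
  }
  out <- reroot_above(tree, m)
  under <- tip_labels_under(out, out$children[[out$root]][1])
  if (!setequal(under, outgroup) &&
      !setequal(setdiff(tip_labels(out), under), outgroup)) {
    warning("outgroup is not monophyletic")
  }
  out
}

tip_labels_under <- function(tree, node) {
  tu <- tips_under(tree)
  colnames(tu)[tu[node, ]]
}

#' Midpoint rooting
#'
#' Places the root halfway along the longest tip-to-tip path, so the two
#' largest root-to-tip distances are equal. Ties among equally longest
#' paths are broken by the lexicographically smallest (sorted) tip-name
#' pair. Every branch length must be present.
#'
#' @param tree a [phytree].
#' @return The rerooted [phytree].
#' @export
reroot_midpoint <- function(tree) {
  if (any(is.na(tree$length[-tree$root]))) {
    stop("midpoint rooting requires every branch length")
  }
  pm <- patristic_matrix(tree)
  nm <- rownames(pm)
  dmax <- max(pm)
  best <- NULL
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j && pm[i, j] >= dmax - 1e-12) {
      cand <- sort(c(nm[i], nm[j]))
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && cand[2] < best[2])) best <- cand
    }
  }
  x <- match(best[1], tree$label); y <- match(best[2], tree$label)
  # node path x -> mrca -> y with cumulative distances from x
  anc <- function(v) { out <- v; while (!is.na(tree$parent[v])) { v <- tree$parent[v]; out <- c(out, v) }; out }
  ax <- anc(x); ay <- anc(y)
  m <- intersect(ax, ay)[1]
  up <- ax[seq_len(match(m, ax))]                 # x ... m
  down <- rev(ay[seq_len(match(m, ay) - 1L)])     # below m ... y
  target <- pm[best[1], best[2]] / 2
  cum <- 0
  for (v in up[-length(up)]) {                    # ascending edges v -> parent
    if (cum + tree$length[v] >= target - 1e-12) {
      return(reroot_above(tree, v, position = min(target - cum, tree$length[v])))
    }
    cum <- cum + tree$length[v]
  }
  for (v in down) {                               # descending edges parent -> v
    if (cum + tree$length[v] >= target - 1e-12) {
      pos <- tree$length[v] - (target - cum)
      return(reroot_above(tree, v, position = max(pos, 0)))
    }
    cum <- cum + tree$length[v]
  }
  stop("internal error: midpoint not found on path")
}

#' Collapse short or weakly supported branches
#'
#' Contracts every internal (non-tip, non-root) edge whose length
#' (resp. support) is strictly below the cutoff, creating polytomies.
#' Tip edges are never collapsed; with the support criterion, edges without
#' a support value are never collapsed. Children of a contracted node keep
#' their own branch lengths, so the sum of retained lengths is unchanged.
#'
#' @param tree a [phytree].
#' @param criterion `"length"` or `"support"`.
#' @param cutoff non-negative threshold.
#' @return The collapsed [phytree].
#' @export
collapse <- function(tree, criterion = c("length", "support"), cutoff) {
  criterion <- match.arg(criterion)
  if (!is.numeric(cutoff) || cutoff < 0) stop("cutoff must be non-negative")
  parent <- tree$parent; children <- tree$children
  label <- tree$label; len <- tree$length; sup <- tree$support
  keep <- rep(TRUE, length(parent))
  vals <- if (criterion == "length") len else sup
  # postorder so contracted children splice in before their parent is seen
  for (v in postorder_nodes(tree)) {
    if (is.na(parent[v]) || !length(children[[v]])) next
    val <- vals[v]
    if (!is.na(val) && val < cutoff) {
      p <- parent[v]
      i <- match(v, children[[p]])
      children[[p]] <- append(children[[p]][-i], children[[v]], after = i - 1L)
      for (c in children[[v]]) parent[c] <- p
      keep[v] <- FALSE
    }
  }
  compact_tree(parent, children, label, len, sup, keep)
}

#' Rename tips
#'
#' @param tree a [phytree].
#' @param map rename map as in [rename_seqs()].
#' @param allow_missing when `FALSE`, map entries matching no tip error out.
#' @return The renamed [phytree].
#' @export
rename_tips <- function(tree, map, allow_missing = FALSE) {
  map <- as_rename_map(map)
  tips <- tip_ids(tree)
  tree$label[tips] <- apply_rename(tree$label[tips], map, allow_missing,
                                   what = "tip")
  validate_phytree(tree)
  tree
}

#' Resolve polytomies at random
#'
#' Every node with more than two children is expanded into a random binary
#' subtree; the inserted edges have zero length and no support. The result
#' is strictly binary (an unrooted basal trichotomy is resolved too, so the
#' output is rooted).
#'
#' @param tree a [phytree].
#' @param seed integer seed; the expansion is deterministic given it.
#' @return A binary [phytree] on the same tips.
#' @export
resolve <- function(tree, seed = 1L) {
  local_seed(derive_seed(seed, 1L))
  parent <- tree$parent; children <- tree$children
  label <- tree$label; len <- tree$length; sup <- tree$support
  add <- function(p) {
    parent <<- c(parent, p); label <<- c(label, NA_character_)
    len <<- c(len, 0); sup <<- c(sup, NA_real_)
    children <<- c(children, list(integer(0)))
    length(parent)
  }
  queue <- seq_along(parent)
  for (v in queue) {
    while (length(children[[v]]) > 2L) {
      pick <- sample(seq_along(children[[v]]), 2L)
      a <- children[[v]][pick[1]]; b <- children[[v]][pick[2]]
      w <- add(v)
      children[[w]] <- c(a, b)
      parent[a] <- w; parent[b] <- w
      children[[v]] <- c(setdiff(children[[v]], c(a, b)), w)
    }
  }
  phytree(parent, children, label, len, sup)
}

#' Generate random or deterministic trees
#'
#' `"yule"` grows a tree by repeatedly splitting a uniformly chosen tip and
#' draws every branch length from Exponential(1); `"uniform"` draws the
#' topology uniformly over rooted binary labelled topologies by sequential
#' insertion of each new tip on a uniformly chosen edge (the slot above the
#' root included), with Exponential(1) lengths; `"caterpillar"` and
#' `"balanced"` are the deterministic comb and perfectly balanced shapes
#' with unit branch lengths. Tips are named `T1..Tn`.
#'
#' @param n_tips number of tips (at least 3; a power of 2 for balanced).
#' @param model `"yule"`, `"uniform"`, `"caterpillar"`, or `"balanced"`.
#' @param seed integer seed for the random models.
#' @return A rooted binary [phytree].
#' @export
random_tree <- function(n_tips, model = c("yule", "uniform", "caterpillar",
                                          "balanced"), seed = 1L) {
  model <- match.arg(model)
  if (n_tips < 3L && !(model == "balanced" && n_tips == 2L)) {
    stop("n_tips must be at least 3")
  }
  if (model == "balanced" && bitwAnd(n_tips, n_tips - 1L) != 0L) {
    stop("balanced trees require n_tips to be a power of 2")
  }
  local_seed(derive_seed(seed, 2L))
  parent <- c(NA_integer_, 1L, 1L)
  children <- list(c(2L, 3L), integer(0), integer(0))
  add_node <- function(p) {
    parent <<- c(parent, p)
    children <<- c(children, list(integer(0)))
    if (!is.na(p)) children[[p]] <<- c(children[[p]], length(parent))
    length(parent)
  }
  build_lengths <- function(tree, kind) {
    nonroot <- setdiff(seq_along(tree$parent), tree$root)
    tree$length[nonroot] <- if (kind == "unit") 1 else {
      stats::rexp(length(nonroot), rate = 1)
    }
    tree
  }
  if (model %in% c("caterpillar", "balanced")) {
    nwk <- if (model == "caterpillar") {
      s <- sprintf("(%s,%s)", "T1", "T2")
      for (k in 3:n_tips) s <- sprintf("(%s,T%d)", s, k)
      paste0(s, ";")
    } else {
      shape <- function(lo, hi) {
        if (lo == hi) return(sprintf("T%d", lo))
        mid <- (lo + hi) %/% 2L
        sprintf("(%s,%s)", shape(lo, mid), shape(mid + 1L, hi))
      }
      paste0(shape(1L, n_tips), ";")
    }
    return(build_lengths(parse_newick(nwk), "unit"))
  }
  if (model == "yule") {
    tips_now <- c(2L, 3L)
    while (length(tips_now) < n_tips) {
      v <- tips_now[sample.int(length(tips_now), 1L)]
      a <- add_node(v); b <- add_node(v)
      tips_now <- c(setdiff(tips_now, v), a, b)
    }
  } else { # uniform over rooted labelled topologies
    k <- 2L
    while (k < n_tips) {
      slots <- which(!is.na(parent))  # every edge, identified by child node
      slot <- sample.int(length(slots) + 1L, 1L)
      if (slot > length(slots)) {
        # insert above the current root
        old_root <- which(is.na(parent))
        nr <- add_node(NA_integer_)
        parent[old_root] <- nr
        children[[nr]] <- old_root
        add_node(nr)
      } else {
        v <- slots[slot]; p <- parent[v]
        w <- add_node(p)
        children[[p]] <- setdiff(children[[p]], v)
        parent[v] <- w
        children[[w]] <- c(children[[w]], v)
        add_node(w)
      }
      k <- k + 1L
    }
  }
  tips <- which(lengths(children) == 0L)
  label <- rep(NA_character_, length(parent))
  label[tips] <- paste0("T", seq_along(tips))
  t <- phytree(parent, children, label, rep(NA_real_, length(parent)),
               rep(NA_real_, length(parent)))
  build_lengths(t, "exp")
}
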