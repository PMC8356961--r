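#' Parse a Newick string into a tree
#'
#' Accepts one complete Newick statement terminated by `;`. Quoted labels
#' (single quotes, doubled to escape) are supported; square-bracket comments
#' are skipped; underscores are kept verbatim (never translated to spaces).
#' An internal-node label that parses as a finite number is stored as the
#' branch support of the edge above that node, matching the dialect written
#' by bootstrap pipelines; any other internal label is kept as a name.
#'
#' @param text a single Newick statement, e.g. `"((A:1,B:2)0.9:3,C:4);"`.
#' @return A [phytree].
#' @examples
#' t <- parse_newick("((A:1,B:2):3,C:4);")
#' sum(t$length, na.rm = TRUE)  # 10
#' @export
parse_newick <- function(text) {
  toks <- newick_tokens(text)
  res <- parse_newick_tokens(toks, 1L)
  i <- res$next_tok
  while (i <= nrow(toks) && grepl("^\\s*$", toks$tok[i])) i <- i + 1L
  if (i <= nrow(toks)) {
    stop(sprintf("newick parse error at position %d: trailing content '%s'",
                 toks$pos[i], toks$tok[i]))
  }
  res$tree
}

# Tokenizer: quoted labels, comments, structural characters, bare words,
# whitespace runs. Byte positions are kept for error messages.
newick_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "'(?:[^']|'')*'|\\[[^]]*\\]|[(),;:]|[^(),;:'\\[\\][:space:]]+|[[:space:]]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) stop("newick parse error at position 1: empty input")
  tok <- regmatches(text, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (covered != nchar(text)) {
    stop(sprintf("newick parse error: unparseable character near position %d",
                 covered + 1L))
  }
  data.frame(tok = tok, pos = as.integer(m), stringsAsFactors = FALSE)
}

unquote_label <- function(tok) {
  if (startsWith(tok, "'")) {
    gsub("''", "'", substr(tok, 2L, nchar(tok) - 1L), fixed = TRUE)
  } else tok
}

# Parse one statement starting at token `start`; returns tree + next token.
parse_newick_tokens <- function(toks, start) {
  tok <- toks$tok; pos <- toks$pos; ntok <- nrow(toks)
  cap <- 64L
  parent <- integer(cap); label <- character(cap)
  len <- numeric(cap); sup <- numeric(cap)
  children <- vector("list", cap)
  nnode <- 0L
  add_node <- function(p) {
    nnode <<- nnode + 1L
    if (nnode > cap) {
      cap <<- cap * 2L
      length(parent) <<- cap; length(label) <<- cap
      length(len) <<- cap; length(sup) <<- cap; length(children) <<- cap
    }
    parent[nnode] <<- p
    label[nnode] <<- NA_character_
    len[nnode] <<- NA_real_; sup[nnode] <<- NA_real_
    children[nnode] <<- list(integer(0))
    if (!is.na(p)) children[[p]] <<- c(children[[p]], nnode)
    nnode
  }
  cur <- NA_integer_   # node whose child list is open
  last <- NA_integer_  # node to receive label/length annotations
  closed <- FALSE      # did we just close a parenthesis?
  i <- start; done <- FALSE
  perr <- function(i, msg) {
    p <- if (i <= ntok) pos[i] else nchar(paste(tok, collapse = "")) + 1L
    stop(sprintf("newick parse error at position %d: %s", p, msg))
  }
  while (i <= ntok && !done) {
    tk <- tok[i]
    if (grepl("^[[:space:]]+$", tk) || startsWith(tk, "[")) { i <- i + 1L; next }
    if (tk == "(") {
      if (closed) perr(i, "'(' directly after ')'")
      cur <- add_node(cur)
      last <- NA_integer_
    } else if (tk == ")") {
      if (is.na(cur)) perr(i, "unbalanced ')'")
      last <- cur
      cur <- parent[cur]
      closed <- TRUE
      i <- i + 1L; next
    } else if (tk == ",") {
      if (is.na(cur)) perr(i, "',' outside parentheses")
      last <- NA_integer_
    } else if (tk == ":") {
      if (is.na(last)) perr(i, "':' without a preceding node")
      j <- i + 1L
      while (j <= ntok && grepl("^[[:space:]]+$", tok[j])) j <- j + 1L
      v <- suppressWarnings(as.numeric(tok[j]))
      if (j > ntok || is.na(v)) perr(i, "branch length expected after ':'")
      if (v < 0) perr(j, "negative branch length")
      len[last] <- v
      i <- j
    } else if (tk == ";") {
      if (!is.na(cur)) perr(i, "unbalanced '(' before ';'")
      if (nnode == 0L) perr(i, "empty statement")
      done <- TRUE
    } else { # label token
      lab <- unquote_label(tk)
      if (closed) {
        label[last] <- lab
      } else {
        if (!is.na(last)) perr(i, "two labels in a row")
        if (is.na(cur) && nnode > 0L) perr(i, "content outside the tree")
        last <- add_node(cur)
        label[last] <- lab
      }
    }
    closed <- FALSE
    i <- i + 1L
  }
  if (!done) perr(i, if (!is.na(cur)) "unbalanced '(': missing ')'" else "missing ';'")
  keep <- seq_len(nnode)
  tree <- phytree(parent[keep], children[keep], label[keep], len[keep], sup[keep])
  internal_labels_to_supports(tree, next_tok = i + 1L)
}

# numeric internal labels on non-root nodes become branch supports
internal_labels_to_supports <- function(tree, next_tok) {
  internal <- which(lengths(tree$children) > 0L)
  internal <- setdiff(internal, tree$root)
  for (v in internal) {
    lab <- tree$label[v]
    if (!is.na(lab) && nzchar(lab)) {
      val <- suppressWarnings(as.numeric(lab))
      if (!is.na(val) && is.finite(val)) {
        tree$support[v] <- val
        tree$label[v] <- NA_character_
      }
    }
  }
  list(tree = tree, next_tok = next_tok)
}

#' Serialize a tree to Newick
#'
#' Writes one Newick statement. Branch supports are emitted in the
#' internal-node label slot; labels containing whitespace or Newick
#' metacharacters are single-quoted (embedded quotes doubled). Numbers use
#' the shortest decimal representation that round-trips exactly, never
#' scientific notation, so `parse_newick(write_newick(t))` reproduces `t`.
#'
#' @param tree a [phytree].
#' @return A single string ending in `";"`.
#' @export
write_newick <- function(tree) {
  sub <- function(v) {
    ch <- tree$children[[v]]
    head <- if (length(ch)) {
      paste0("(", paste(vapply(ch, sub, character(1)), collapse = ","), ")")
    } else ""
    lab <- if (length(ch) && !is.na(tree$support[v])) {
      fmt_number(tree$support[v])
    } else if (!is.na(tree$label[v])) {
      quote_label(tree$label[v])
    } else ""
    len <- if (!is.na(tree$length[v])) paste0(":", fmt_number(tree$length[v])) else ""
    paste0(head, lab, len)
  }
  paste0(sub(tree$root), ";")
}

quote_label <- function(lab) {
  if (grepl("[^A-Za-z0-9_.|/+-]", lab) || !nzchar(lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else lab
}

# shortest plain-decimal representation that round-trips through as.numeric
fmt_number <- function(x) {
  if (x == floor(x) && abs(x) < 1e15) {
    return(format(x, scientific = FALSE))
  }
  for (d in 1:17) {
    s <- format(x, digits = d, scientific = FALSE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17, scientific = FALSE)
}
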