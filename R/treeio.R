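#' Read trees from a file
#'
#' Reads one or more trees from a Newick file (one statement per line or
#' several per file, each ending in `;`) or from the `TREES` block of a
#' Nexus file (case-insensitive keywords; a `TRANSLATE` table, when present,
#' is applied to tip labels). Gzip-compressed input is detected by its magic
#' bytes (never by file extension) and decompressed transparently.
#'
#' @param file path to the input file, or `NULL` when `text` is given.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (detected from the
#'   leading bytes: `#NEXUS` means Nexus).
#' @param text optional character scalar holding the file content directly.
#' @return A list of [phytree] objects of class `treelist`.
#' @export
read_trees <- function(file = NULL, format = c("auto", "newick", "nexus"),
                       text = NULL) {
  format <- match.arg(format)
  content <- if (is.null(text)) read_file_auto(file) else paste(text, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", content, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") parse_nexus_trees(content) else {
    parse_newick_many(content)
  }
  structure(trees, class = "treelist")
}

#' @export
print.treelist <- function(x, ...) {
  cat(sprintf("<treelist: %d tree(s)>\n", length(x)))
  invisible(x)
}

parse_newick_many <- function(content) {
  toks <- tryCatch(newick_tokens(content), error = function(e) NULL)
  if (is.null(toks)) return(list())
  trees <- list(); i <- 1L
  repeat {
    while (i <= nrow(toks) &&
           (grepl("^[[:space:]]+$", toks$tok[i]) || startsWith(toks$tok[i], "["))) {
      i <- i + 1L
    }
    if (i > nrow(toks)) break
    res <- parse_newick_tokens(toks, i)
    trees[[length(trees) + 1L]] <- res$tree
    i <- res$next_tok
  }
  trees
}

parse_nexus_trees <- function(content) {
  # strip bracket comments except rooting hints we ignore anyway
  body <- gsub("\\[[^]]*\\]", "", content)
  lines <- strsplit(body, "\r?\n")[[1]]
  joined <- paste(lines, collapse = "\n")
  block <- regmatches(joined,
    regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", joined, perl = TRUE))
  if (!length(block)) stop("nexus input has no TREES block")
  block <- block[[1]]
  statements <- strsplit(block, ";")[[1]]
  translate <- NULL
  trees <- list()
  for (st in statements) {
    st <- trimws(st)
    if (grepl("^(?i)translate\\b", st, perl = TRUE)) {
      tb <- sub("^(?i)translate\\s*", "", st, perl = TRUE)
      entries <- strsplit(tb, ",")[[1]]
      translate <- list()
      for (e in entries) {
        mm <- regexec("^\\s*(\\S+)\\s+(.+?)\\s*$", e, perl = TRUE)
        g <- regmatches(e, mm)[[1]]
        if (length(g) == 3L) translate[[g[2]]] <- unquote_label(g[3])
      }
    } else if (grepl("^(?i)tree\\s+", st, perl = TRUE)) {
      nwk <- sub("^[^=]*=\\s*", "", st)
      tr <- parse_newick(paste0(nwk, ";"))
      if (!is.null(translate)) {
        tips <- tip_ids(tr)
        lab <- tr$label[tips]
        hit <- lab %in% names(translate)
        tr$label[tips[hit]] <- unlist(translate[lab[hit]])
        validate_phytree(tr)
      }
      trees[[length(trees) + 1L]] <- tr
    } else if (grepl("^(?i)begin\\s+trees", st, perl = TRUE) ||
               grepl("^(?i)end$", st, perl = TRUE) || !nzchar(st)) {
      next
    }
  }
  trees
}

#' Write trees to a file or string
#'
#' @param trees a [phytree] or a list of them.
#' @param file output path, or `NULL` to return the text. A path ending in
#'   `.gz` is gzip-compressed.
#' @param format `"newick"` (one statement per line) or `"nexus"` (a single
#'   `TREES` block without a translate table).
#' @return The formatted text, invisibly when written to a file.
#' @export
write_trees <- function(trees, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(trees, "phytree")) trees <- list(trees)
  out <- if (format == "newick") {
    paste0(vapply(trees, write_newick, character(1)), collapse = "\n")
  } else {
    stmts <- vapply(seq_along(trees), function(i) {
      sprintf("  TREE tree%d = %s %s", i,
              if (is_rooted(trees[[i]])) "[&R]" else "[&U]",
              write_newick(trees[[i]]))
    }, character(1))
    paste(c("#NEXUS", "BEGIN TREES;", stmts, "END;"), collapse = "\n")
  }
  if (length(trees)) out <- paste0(out, "\n")
  if (is.null(file)) return(out)
  write_file_auto(out, file)
  invisible(out)
}

# ---- shared file helpers (gzip by magic bytes) ----

is_gzip_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_file_auto <- function(path) {
  if (is.null(path)) stop("either 'file' or 'text' must be given")
  if (inherits(path, "connection")) {
    return(paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
  if (identical(path, "-")) {
    return(paste(readLines(file("stdin"), warn = FALSE), collapse = "\n"))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

write_file_auto <- function(text, path) {
  if (inherits(path, "connection")) { writeLines(text, path, sep = ""); return(invisible()) }
  if (identical(path, "-")) { cat(text); return(invisible()) }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(text, con, sep = "")
  invisible()
}
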