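#' Read a multiple sequence alignment
#'
#' Supports FASTA, Phylip (relaxed names; sequential and interleaved layouts
#' both accepted), Clustal, and the Nexus `DATA`/`CHARACTERS` block. Format
#' auto-detection looks at the leading bytes: `>` means FASTA, `#NEXUS`
#' Nexus, `CLUSTAL` Clustal, and a digit the Phylip header. Gzip input is
#' detected by magic bytes and decompressed transparently.
#'
#' @param file input path (or `"-"` for standard input).
#' @param format one of `"auto"`, `"fasta"`, `"phylip"`, `"clustal"`, `"nexus"`.
#' @param text optional character scalar with the content itself.
#' @param alphabet forwarded to [alignment()].
#' @return An [alignment].
#' @export
read_alignment <- function(file = NULL,
                           format = c("auto", "fasta", "phylip", "clustal", "nexus"),
                           text = NULL, alphabet = "auto") {
  format <- match.arg(format)
  content <- if (is.null(text)) read_file_auto(file) else paste(text, collapse = "\n")
  if (!nzchar(trimws(content))) stop("empty alignment input")
  if (format == "auto") format <- sniff_aln_format(content)
  parsed <- switch(format,
    fasta   = parse_fasta(content),
    phylip  = parse_phylip(content),
    clustal = parse_clustal(content),
    nexus   = parse_nexus_aln(content))
  alignment(parsed$names, parsed$seqs, alphabet = alphabet)
}

#' Read unaligned sequences (FASTA)
#'
#' @inheritParams read_alignment
#' @return A [seqset] (sequence lengths may differ).
#' @export
read_sequences <- function(file = NULL, text = NULL, alphabet = "auto") {
  content <- if (is.null(text)) read_file_auto(file) else paste(text, collapse = "\n")
  p <- parse_fasta(content)
  seqset(p$names, p$seqs, alphabet = alphabet)
}

sniff_aln_format <- function(content) {
  head <- sub("^[[:space:]]*", "", content)
  if (startsWith(head, ">")) return("fasta")
  if (grepl("^#NEXUS", head, ignore.case = TRUE)) return("nexus")
  if (grepl("^CLUSTAL", head, ignore.case = TRUE)) return("clustal")
  if (grepl("^[0-9]", head)) return("phylip")
  stop("cannot detect alignment format from leading bytes")
}

parse_fasta <- function(content) {
  lines <- strsplit(content, "\r?\n")[[1]]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers ('>') found")
  if (any(nzchar(trimws(lines[seq_len(hdr[1] - 1)])))) {
    stop("content before first FASTA header")
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  names <- trimws(sub("^>", "", lines[hdr]))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    gsub("[[:space:]]", "", paste(body, collapse = ""))
  }, character(1))
  list(names = names, seqs = seqs)
}

parse_phylip <- function(content) {
  lines <- strsplit(content, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  m <- regexec("^\\s*(\\d+)\\s+(\\d+)\\s*$", lines[1])
  g <- regmatches(lines[1], m)[[1]]
  if (length(g) != 3L) stop("phylip header must be 'ntax nchar'")
  ntax <- as.integer(g[2]); nchar_ <- as.integer(g[3])
  body <- lines[-1]
  if (length(body) < ntax) stop("phylip body has fewer lines than declared taxa")
  split_name_line <- function(ln) {
    mm <- regmatches(ln, regexec("^\\s*(\\S+)\\s*(.*)$", ln))[[1]]
    list(name = mm[2], chunk = gsub("[[:space:]]", "", mm[3]))
  }
  # sequential: each taxon is a name line plus continuation lines until the
  # declared site count is reached exactly. Trailing lines are tolerated so
  # that the first alignment of a stacked multi-phylip stream (the classic
  # seqboot layout) can be read.
  try_sequential <- function() {
    names <- character(ntax); seqs <- character(ntax)
    li <- 1L
    for (i in seq_len(ntax)) {
      if (li > length(body)) return(NULL)
      nl <- split_name_line(body[li]); li <- li + 1L
      names[i] <- nl$name; seqs[i] <- nl$chunk
      while (nchar(seqs[i]) < nchar_) {
        if (li > length(body)) return(NULL)
        seqs[i] <- paste0(seqs[i], gsub("[[:space:]]", "", body[li]))
        li <- li + 1L
      }
      if (nchar(seqs[i]) != nchar_) return(NULL)
    }
    list(names = names, seqs = seqs)
  }
  # interleaved: one name block, then blocks of bare continuation lines
  try_interleaved <- function() {
    if (length(body) %% ntax != 0L) return(NULL)
    names <- character(ntax); seqs <- character(ntax)
    for (i in seq_len(ntax)) {
      nl <- split_name_line(body[i])
      names[i] <- nl$name; seqs[i] <- nl$chunk
    }
    rest <- body[-seq_len(ntax)]
    for (k in seq_along(rest)) {
      i <- (k - 1L) %% ntax + 1L
      seqs[i] <- paste0(seqs[i], gsub("[[:space:]]", "", rest[k]))
    }
    if (!all(nchar(seqs) == nchar_)) return(NULL)
    list(names = names, seqs = seqs)
  }
  res <- try_sequential()
  if (is.null(res)) res <- try_interleaved()
  if (is.null(res)) {
    stop(sprintf("phylip sequences do not match header (%d taxa, %d sites)",
                 ntax, nchar_))
  }
  res
}

parse_clustal <- function(content) {
  lines <- strsplit(content, "\r?\n")[[1]]
  if (!grepl("^CLUSTAL", trimws(lines[1]), ignore.case = TRUE)) {
    stop("missing CLUSTAL header line")
  }
  acc <- list(); order <- character(0)
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                      # conservation line
    mm <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(mm) < 3L) next
    nm <- mm[2]; chunk <- mm[3]
    if (grepl("^[*:. ]+$", chunk)) next
    if (!nm %in% order) order <- c(order, nm)
    acc[[nm]] <- paste0(if (is.null(acc[[nm]])) "" else acc[[nm]], chunk)
  }
  if (!length(order)) stop("no sequences found in clustal input")
  list(names = order, seqs = unlist(acc[order], use.names = FALSE))
}

parse_nexus_aln <- function(content) {
  body <- gsub("\\[[^]]*\\]", "", content)
  block <- regmatches(body,
    regexpr("(?is)begin\\s+(data|characters)\\s*;.*?\\bmatrix\\b(.*?);", body,
            perl = TRUE))
  if (!length(block)) stop("nexus input has no DATA/CHARACTERS matrix")
  mat <- sub("(?is)^.*?\\bmatrix\\b", "", block[[1]], perl = TRUE)
  mat <- sub(";\\s*$", "", mat)
  acc <- list(); order <- character(0)
  for (ln in strsplit(mat, "\r?\n")[[1]]) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    mm <- regmatches(ln, regexec("^('[^']*'|\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
    if (length(mm) != 3L) next
    nm <- unquote_label(mm[2]); chunk <- mm[3]
    if (!nm %in% order) order <- c(order, nm)
    acc[[nm]] <- paste0(if (is.null(acc[[nm]])) "" else acc[[nm]], chunk)
  }
  if (!length(order)) stop("empty nexus matrix")
  list(names = order, seqs = unlist(acc[order], use.names = FALSE))
}

#' Write an alignment
#'
#' FASTA wraps sequences at 80 columns; Phylip uses the relaxed sequential
#' dialect (full name, two-space separator); Clustal emits 60-column blocks
#' with a simple conservation line (`*` under fully identical columns);
#' Nexus writes a `DATA` block with `MATRIX`. A path ending in `.gz` is
#' gzip-compressed.
#'
#' @param aln an [alignment].
#' @param file output path or `NULL` to return the text (`"-"` = stdout).
#' @param format one of `"fasta"`, `"phylip"`, `"clustal"`, `"nexus"`.
#' @return The formatted text, invisibly when written to a file.
#' @export
write_alignment <- function(aln, file = NULL,
                            format = c("fasta", "phylip", "clustal", "nexus")) {
  format <- match.arg(format)
  out <- switch(format,
    fasta   = fmt_fasta(aln$names, aln$seqs),
    phylip  = fmt_phylip(aln),
    clustal = fmt_clustal(aln),
    nexus   = fmt_nexus_aln(aln))
  if (is.null(file)) return(out)
  write_file_auto(out, file)
  invisible(out)
}

#' @rdname write_alignment
#' @param seqs a [seqset] (FASTA only).
#' @export
write_sequences <- function(seqs, file = NULL) {
  out <- fmt_fasta(seqs$names, seqs$seqs)
  if (is.null(file)) return(out)
  write_file_auto(out, file)
  invisible(out)
}

wrap_seq <- function(s, width) {
  if (!nchar(s)) return("")
  starts <- seq(1L, nchar(s), by = width)
  paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))), collapse = "\n")
}

fmt_fasta <- function(names, seqs, width = 80L) {
  paste0(paste(vapply(seq_along(names), function(i) {
    paste0(">", names[i], "\n", wrap_seq(seqs[i], width))
  }, character(1)), collapse = "\n"), "\n")
}

fmt_phylip <- function(aln) {
  if (!n_seqs(aln)) stop("cannot write an empty alignment as phylip")
  rows <- paste0(aln$names, "  ", aln$seqs)
  paste0(sprintf(" %d %d\n", n_seqs(aln), aln_length(aln)),
         paste(rows, collapse = "\n"), "\n")
}

fmt_clustal <- function(aln, width = 60L) {
  if (!n_seqs(aln)) stop("cannot write an empty alignment as clustal")
  namew <- max(nchar(aln$names)) + 3L
  m <- aln_matrix(aln)
  cons <- apply(m, 2, function(col) {
    if (all(col == col[1]) && !is_gap(col[1])) "*" else " "
  })
  blocks <- character(0)
  for (s in seq(1L, aln_length(aln), by = width)) {
    e <- min(s + width - 1L, aln_length(aln))
    lines <- sprintf("%-*s%s", namew, aln$names, substring(aln$seqs, s, e))
    lines <- c(lines, sprintf("%-*s%s", namew, "",
                              paste(cons[s:e], collapse = "")))
    blocks <- c(blocks, paste(lines, collapse = "\n"))
  }
  paste0("CLUSTAL W multiple sequence alignment\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

fmt_nexus_aln <- function(aln) {
  if (!n_seqs(aln)) stop("cannot write an empty alignment as nexus")
  dt <- if (aln$alphabet == "nucleotide") "DNA" else "PROTEIN"
  rows <- sprintf("    %s  %s",
                  vapply(aln$names, quote_label, character(1)), aln$seqs)
  paste0("#NEXUS\nBEGIN DATA;\n",
         sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;\n", n_seqs(aln), aln_length(aln)),
         sprintf("  FORMAT DATATYPE=%s GAP=- MISSING=?;\n", dt),
         "  MATRIX\n", paste(rows, collapse = "\n"), "\n  ;\nEND;\n")
}

#' Alignment summary statistics
#'
#' @param aln an [alignment].
#' @return A list with `length`, `n_seqs`, `alphabet`, `char_freqs`
#'   (relative frequencies over non-gap characters), `gap_fraction`,
#'   `n_constant` and `n_variable`. A column is constant when all of its
#'   non-gap, unambiguous characters are identical and at least one exists;
#'   variable when it shows two or more distinct unambiguous characters.
#' @export
align_stats <- function(aln) {
  m <- aln_matrix(aln)
  chars <- as.vector(m)
  gap <- is_gap(chars)
  freqs <- if (any(!gap)) {
    tab <- table(chars[!gap])
    as.numeric(tab) / sum(tab) -> f
    stats::setNames(f, names(tab))
  } else numeric(0)
  un <- unambiguous_chars(aln$alphabet)
  col_class <- apply(m, 2, function(col) {
    core <- col[col %in% un]
    if (!length(core)) return("empty")
    if (length(unique(core)) == 1L) "constant" else "variable"
  })
  list(length = aln_length(aln), n_seqs = n_seqs(aln), alphabet = aln$alphabet,
       char_freqs = freqs,
       gap_fraction = if (length(chars)) mean(gap) else 0,
       n_constant = sum(col_class == "constant"),
       n_variable = sum(col_class == "variable"))
}
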