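#' Remove gappy columns or sequences
#'
#' `clean_sites()` drops every column whose gap fraction is strictly greater
#' than `cutoff`; `clean_seqs()` applies the same rule to rows. The strict
#' comparison means a cutoff of 0.5 keeps columns at exactly 50% gaps, and a
#' cutoff of 1 removes only all-gap columns... which are never removed
#' either, since 1 is not greater than 1. Ambiguity characters count as
#' non-gap. The number of removed items is attached as attribute
#' `"n_removed"` and reported via message.
#'
#' @param aln an [alignment].
#' @param cutoff gap fraction in `[0, 1]`.
#' @return The filtered [alignment], same row/column order.
#' @export
clean_sites <- function(aln, cutoff) {
  check_cutoff(cutoff)
  m <- aln_matrix(aln)
  gapfrac <- colMeans(matrix(is_gap(m), nrow(m), ncol(m)))
  keep <- !(gapfrac > cutoff)
  out <- matrix_aln(m[, keep, drop = FALSE], aln$alphabet)
  message(sum(!keep), " site(s) removed")
  structure(out, n_removed = sum(!keep))
}

#' @rdname clean_sites
#' @export
clean_seqs <- function(aln, cutoff) {
  check_cutoff(cutoff)
  m <- aln_matrix(aln)
  gapfrac <- rowMeans(matrix(is_gap(m), nrow(m), ncol(m)))
  keep <- !(gapfrac > cutoff)
  out <- alignment(aln$names[keep], aln$seqs[keep], alphabet = aln$alphabet)
  message(sum(!keep), " sequence(s) removed")
  structure(out, n_removed = sum(!keep))
}

check_cutoff <- function(cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single value in [0, 1]")
  }
}

#' Rename sequences or tips via an explicit map
#'
#' @param x an [alignment] or [seqset].
#' @param map a rename map: data frame / two-column matrix of (old, new), or
#'   a named character vector `c(old = "new")`.
#' @param allow_missing when `FALSE` (default), map entries matching no
#'   sequence are an error.
#' @return Same type as `x`, names replaced; unmapped names are kept.
#' @export
rename_seqs <- function(x, map, allow_missing = FALSE) {
  map <- as_rename_map(map)
  x$names <- apply_rename(x$names, map, allow_missing, what = "sequence")
  if (anyDuplicated(x$names)) {
    stop("rename would create duplicate names: ",
         paste(unique(x$names[duplicated(x$names)]), collapse = ", "))
  }
  x
}

as_rename_map <- function(map) {
  if (is.data.frame(map) || is.matrix(map)) {
    out <- stats::setNames(as.character(map[, 2]), as.character(map[, 1]))
  } else if (is.character(map) && !is.null(names(map))) {
    out <- map
  } else stop("rename map must be two columns (old, new) or a named vector")
  if (anyDuplicated(names(out))) stop("rename map: duplicate old names")
  if (anyDuplicated(out)) stop("rename map: duplicate new names")
  out
}

apply_rename <- function(names, map, allow_missing, what) {
  missing <- setdiff(names(map), names)
  if (length(missing) && !allow_missing) {
    stop("rename map entries match no ", what, ": ",
         paste(missing, collapse = ", "))
  }
  hit <- names %in% names(map)
  names[hit] <- unname(map[names[hit]])
  names
}

#' Read a two-column tab-separated rename map
#' @param file path to a TSV with columns old-name, new-name.
#' @return Named character vector usable by [rename_seqs()]/[rename_tips()].
#' @export
read_rename_map <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("rename map needs two tab-separated columns")
  as_rename_map(tab[, 1:2])
}

#' Sanitize sequence names
#'
#' Replaces every character outside `[A-Za-z0-9_.-]` with `_`, then
#' deduplicates collisions by appending `_2`, `_3`, ... in input order.
#'
#' @param x an [alignment] or [seqset].
#' @return A list with `x` (renamed object) and `map` (named vector
#'   old -> new, restricted to names that changed) for later reversal.
#' @export
sanitize_names <- function(x) {
  clean <- gsub("[^A-Za-z0-9_.-]", "_", x$names)
  seen <- character(0)
  for (i in seq_along(clean)) {
    nm <- clean[i]; k <- 1L
    while (nm %in% seen) { k <- k + 1L; nm <- paste0(clean[i], "_", k) }
    seen <- c(seen, nm); clean[i] <- nm
  }
  changed <- x$names != clean
  map <- stats::setNames(clean[changed], x$names[changed])
  x$names <- clean
  list(x = x, map = map)
}

#' Mask a window of alignment columns
#'
#' Replaces columns `[start, start + length)` (0-based) with the fill
#' character (`N` for nucleotide, `X` for protein by default); gaps inside
#' the window are preserved.
#'
#' @param aln an [alignment].
#' @param start 0-based first column of the window.
#' @param length number of columns to mask.
#' @param fill fill character, defaulting by alphabet.
#' @return The masked [alignment].
#' @export
mask <- function(aln, start, length, fill = NULL) {
  L <- aln_length(aln)
  if (start < 0 || length < 0 || start + length > L) {
    stop(sprintf("mask window [%d, %d) out of range for %d columns",
                 start, start + length, L))
  }
  if (is.null(fill)) fill <- if (aln$alphabet == "nucleotide") "N" else "X"
  if (length == 0) return(aln)
  m <- aln_matrix(aln)
  win <- (start + 1L):(start + length)
  sub <- m[, win, drop = FALSE]
  sub[!is_gap(sub)] <- fill
  m[, win] <- sub
  matrix_aln(m, aln$alphabet)
}

#' Extract column ranges
#'
#' @param aln an [alignment].
#' @param ranges list (or 2-column matrix) of 0-based half-open `[start, end)`
#'   column ranges; must be sorted, non-overlapping and within bounds.
#' @return [alignment] made of the selected blocks, concatenated in order.
#' @export
extract <- function(aln, ranges) {
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
  if (!length(ranges)) stop("at least one range is required")
  L <- aln_length(aln)
  last_end <- 0L
  cols <- integer(0)
  for (r in ranges) {
    s <- r[[1]]; e <- r[[2]]
    if (s < 0 || e > L || s >= e) stop(sprintf("invalid range [%d, %d)", s, e))
    if (s < last_end) stop("ranges must be sorted and non-overlapping")
    last_end <- e
    cols <- c(cols, (s + 1L):e)
  }
  m <- aln_matrix(aln)
  matrix_aln(m[, cols, drop = FALSE], aln$alphabet)
}

#' Concatenate alignments by sequence name
#'
#' @param alns list of [alignment]s sharing one alphabet.
#' @param fill_missing when `TRUE`, a name absent from a block contributes
#'   gaps for that block; when `FALSE` (default) any missing name is an
#'   error.
#' @return [alignment] of length equal to the sum of block lengths; its name
#'   set is the union of block names in first-appearance order.
#' @export
concat <- function(alns, fill_missing = FALSE) {
  if (!length(alns)) stop("at least one alignment is required")
  alpha <- unique(vapply(alns, function(a) a$alphabet, character(1)))
  if (length(alpha) > 1L) stop("alignments mix alphabets: ",
                               paste(alpha, collapse = ", "))
  all_names <- unique(unlist(lapply(alns, function(a) a$names)))
  if (!fill_missing) {
    for (i in seq_along(alns)) {
      miss <- setdiff(all_names, alns[[i]]$names)
      if (length(miss)) {
        stop("block ", i, " is missing sequence(s): ",
             paste(miss, collapse = ", "))
      }
    }
  }
  seqs <- vapply(all_names, function(nm) {
    paste(vapply(alns, function(a) {
      j <- match(nm, a$names)
      if (is.na(j)) strrep("-", aln_length(a)) else a$seqs[j]
    }, character(1)), collapse = "")
  }, character(1))
  alignment(all_names, unname(seqs), alphabet = alpha)
}

#' Translate nucleotide sequences to amino acids
#'
#' Drops `phase` leading characters, then translates consecutive triplets:
#' `---` becomes `-`, any other codon containing a gap or an ambiguous
#' character becomes `X`, stop codons become `*`. A trailing incomplete
#' codon is dropped with a message.
#'
#' @param x nucleotide [alignment] or [seqset].
#' @param phase 0, 1 or 2 leading characters to skip.
#' @param code a [genetic_code()] table or its name.
#' @return Amino-acid object of the same class as `x`.
#' @export
translate <- function(x, phase = 0, code = "standard") {
  if (x$alphabet != "nucleotide") stop("translate requires nucleotide input")
  if (!phase %in% 0:2) stop("phase must be 0, 1 or 2")
  if (is.character(code)) code <- genetic_code(code)
  dropped <- 0L
  prot <- vapply(x$seqs, function(s) {
    s <- substr(s, phase + 1L, nchar(s))
    n3 <- nchar(s) %/% 3L
    dropped <<- dropped + (nchar(s) - 3L * n3)
    if (!n3) return("")
    codons <- substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    paste(vapply(codons, translate_codon, character(1), code = code),
          collapse = "")
  }, character(1))
  if (dropped > 0L) message(dropped, " trailing character(s) dropped")
  if (inherits(x, "alignment")) {
    alignment(x$names, unname(prot), alphabet = "amino-acid")
  } else {
    seqset(x$names, unname(prot), alphabet = "amino-acid")
  }
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each protein alignment column into the corresponding codon of the
#' unaligned coding sequence: residue columns take the next codon, gap
#' columns become `---`. For every name, the translation of the coding
#' sequence must equal the ungapped protein sequence (a trailing stop codon
#' in the CDS is tolerated).
#'
#' @param prot_aln amino-acid [alignment].
#' @param cds [seqset] of nucleotide coding sequences, same name set.
#' @param code a [genetic_code()] table or its name.
#' @return Nucleotide [alignment] of length `3 * aln_length(prot_aln)`.
#' @export
codon_align <- function(prot_aln, cds, code = "standard") {
  if (is.character(code)) code <- genetic_code(code)
  miss1 <- setdiff(prot_aln$names, cds$names)
  miss2 <- setdiff(cds$names, prot_aln$names)
  if (length(miss1) || length(miss2)) {
    stop("name sets differ (protein-only: ", paste(miss1, collapse = ","),
         "; cds-only: ", paste(miss2, collapse = ","), ")")
  }
  out <- vapply(seq_along(prot_aln$names), function(i) {
    nm <- prot_aln$names[i]
    prot <- strsplit(prot_aln$seqs[i], "")[[1]]
    s <- cds$seqs[match(nm, cds$names)]
    n3 <- nchar(s) %/% 3L
    codons <- substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    # tolerate one trailing stop codon on the CDS
    if (length(codons) &&
        translate_codon(codons[length(codons)], code) == "*") {
      codons <- codons[-length(codons)]
    }
    res <- which(!prot %in% GAP_CHARS)
    if (length(res) != length(codons)) {
      stop(sprintf("%s: %d residues vs %d codons", nm, length(res),
                   length(codons)))
    }
    for (k in seq_along(res)) {
      aa <- translate_codon(codons[k], code)
      if (aa != prot[res[k]] && prot[res[k]] != "X" && aa != "X") {
        stop(sprintf("%s: translation mismatch at residue %d (%s vs %s)",
                     nm, k, aa, prot[res[k]]))
      }
    }
    chunks <- rep("---", length(prot))
    chunks[res] <- codons
    paste(chunks, collapse = "")
  }, character(1))
  alignment(prot_aln$names, out, alphabet = "nucleotide")
}

#' Bootstrap alignments (seqboot)
#'
#' Draws alignment columns uniformly with replacement. Replicate `r` uses a
#' private random stream derived from `(seed, r)`, so any replicate can be
#' regenerated independently of the others.
#'
#' @param aln an [alignment] with at least one column.
#' @param n_replicates number of bootstrap alignments.
#' @param seed integer seed.
#' @return List of `n_replicates` [alignment]s with identical shape.
#' @export
seqboot <- function(aln, n_replicates, seed = 1L) {
  if (!is.numeric(n_replicates) || n_replicates <= 0) {
    stop("n_replicates must be a positive integer")
  }
  L <- aln_length(aln)
  if (L < 1L) stop("alignment must have at least one column")
  m <- aln_matrix(aln)
  lapply(seq_len(n_replicates), function(r) {
    local_seed(derive_seed(seed, r))
    cols <- sample.int(L, L, replace = TRUE)
    matrix_aln(m[, cols, drop = FALSE], aln$alphabet)
  })
}

# deterministic sub-stream seed, kept within 32-bit integer range
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483647)
}

# set the RNG seed for the calling frame only, restoring any previous state
# when that frame exits (so library calls never disturb a user's RNG stream)
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}
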