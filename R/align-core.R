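#' Multiple sequence alignments and sequence sets
#'
#' An `alignment` holds equal-length named sequences over a nucleotide or
#' amino-acid alphabet; a `seqset` relaxes the equal-length constraint
#' (unaligned sequences, e.g. coding sequences destined for codon-aware
#' back-translation). Sequences are stored uppercase; `U` is normalized to
#' `T` in nucleotide data so that a single code path serves RNA and DNA.
#'
#' @param names character vector of unique, non-empty sequence names.
#' @param seqs character vector of sequences (one string each).
#' @param alphabet `"nucleotide"`, `"amino-acid"`, or `"auto"` to detect:
#'   at least 90% of non-gap characters in `A,C,G,T,U,N` means nucleotide.
#' @return An object of class `alignment` (resp. `seqset`).
#' @export
alignment <- function(names, seqs, alphabet = c("auto", "nucleotide", "amino-acid")) {
  x <- new_seqs(names, seqs, match.arg(alphabet), aligned = TRUE)
  class(x) <- "alignment"
  x
}

#' @rdname alignment
#' @export
seqset <- function(names, seqs, alphabet = c("auto", "nucleotide", "amino-acid")) {
  x <- new_seqs(names, seqs, match.arg(alphabet), aligned = FALSE)
  class(x) <- "seqset"
  x
}

new_seqs <- function(names, seqs, alphabet, aligned) {
  names <- as.character(names); seqs <- toupper(as.character(seqs))
  if (length(names) != length(seqs)) stop("names and sequences differ in number")
  if (any(is.na(names) | !nzchar(names))) stop("sequence names must be non-empty")
  if (anyDuplicated(names)) {
    stop("duplicate sequence names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (aligned && length(seqs) && length(unique(nchar(seqs))) > 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(nchar(seqs)), collapse = "-"), ")")
  }
  if (alphabet == "auto") alphabet <- detect_alphabet(seqs)
  if (alphabet == "nucleotide") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  list(names = names, seqs = seqs, alphabet = alphabet)
}

detect_alphabet <- function(seqs) {
  chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
  chars <- chars[!chars %in% c("-", "?", ".")]
  if (!length(chars)) return("nucleotide")
  nt <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (nt >= 0.9) "nucleotide" else "amino-acid"
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequence(s) x %d column(s), %s>\n",
              length(x$names), aln_length(x), x$alphabet))
  invisible(x)
}

#' @export
print.seqset <- function(x, ...) {
  cat(sprintf("<seqset: %d sequence(s), %s>\n", length(x$names), x$alphabet))
  invisible(x)
}

#' Alignment dimensions
#' @param aln an `alignment`.
#' @return number of columns / sequences.
#' @export
aln_length <- function(aln) if (length(aln$seqs)) nchar(aln$seqs[1]) else 0L

#' @rdname aln_length
#' @export
n_seqs <- function(aln) length(aln$seqs)

# character matrix view (rows = sequences)
aln_matrix <- function(aln) {
  if (!n_seqs(aln)) return(matrix(character(0), 0, 0))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$names
  m
}

matrix_aln <- function(m, alphabet) {
  alignment(rownames(m), apply(m, 1, paste, collapse = ""), alphabet = alphabet)
}

GAP_CHARS <- c("-", ".")
NT_UNAMBIG <- c("A", "C", "G", "T")
AA_UNAMBIG <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_gap <- function(ch) ch %in% GAP_CHARS

unambiguous_chars <- function(alphabet) {
  if (alphabet == "nucleotide") NT_UNAMBIG else AA_UNAMBIG
}
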