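# Genetic code tables. Codons are indexed in TCAG order, the classical
# textbook layout, and expanded below into a named 64-entry vector.

#' Genetic code tables
#'
#' @param name `"standard"` (translation table 1) or `"vertebrate-mito"`
#'   (table 2).
#' @return Named character vector mapping each of the 64 codons (over ACGT)
#'   to a one-letter amino acid, with `*` for stop.
#' @export
genetic_code <- function(name = c("standard", "vertebrate-mito")) {
  name <- match.arg(name)
  aa <- switch(name,
    "standard" =
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "vertebrate-mito" =
      "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG")
  bases <- c("T", "C", "A", "G")
  codons <- character(64); k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(strsplit(aa, "")[[1]], codons)
}

translate_codon <- function(codon, code) {
  if (codon == "---") return("-")
  if (!grepl("^[ACGT]{3}$", codon)) return("X")
  unname(code[[codon]])
}
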