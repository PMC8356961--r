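#' Pairwise site counts for nucleotide distance estimation
#'
#' Applies pairwise deletion: any site where either sequence carries a gap
#' or an ambiguity code (anything outside `A`,`C`,`G`,`T`) is excluded
#' entirely. Over the remaining sites it reports the quantities the
#' closed-form estimators consume.
#'
#' @param seq1,seq2 equal-length nucleotide strings.
#' @return A list: `n` compared sites, `p` overall mismatch proportion,
#'   `P1` A/G transition proportion, `P2` C/T transition proportion,
#'   `Q` transversion proportion, and `pair_freqs`, the 4x4 table of
#'   observed base pairs divided by `n`.
#' @export
pair_counts <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% NT_UNAMBIG & b %in% NT_UNAMBIG
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  tab <- matrix(0, 4, 4, dimnames = list(NT_UNAMBIG, NT_UNAMBIG))
  cnt <- table(factor(a, NT_UNAMBIG), factor(b, NT_UNAMBIG))
  tab[] <- as.numeric(cnt)
  P1 <- (tab["A", "G"] + tab["G", "A"]) / n
  P2 <- (tab["C", "T"] + tab["T", "C"]) / n
  p <- 1 - sum(diag(tab)) / n
  list(n = n, p = p, P1 = P1, P2 = P2, Q = p - P1 - P2, pair_freqs = tab / n)
}

#' Closed-form nucleotide evolutionary distances
#'
#' Implements the classical estimators: JC (Jukes-Cantor), K2P (Kimura
#' two-parameter), F81 (Felsenstein 1981), F84 (Felsenstein 1984, as in
#' PHYLIP's dnadist) and TN93 (Tamura-Nei 1993), plus the uncorrected
#' `pdist`/`raw` mismatch proportion. Saturated pairs (a non-positive
#' logarithm argument) yield `+Inf` with a warning rather than an error.
#'
#' @param seq1,seq2 equal-length nucleotide strings.
#' @param model one of `"JC"`, `"K2P"`, `"F81"`, `"F84"`, `"TN93"`,
#'   `"pdist"`, `"raw"` (case-insensitive).
#' @param pi base frequencies (A, C, G, T) for F81/F84/TN93; estimated from
#'   the two sequences when omitted.
#' @return The estimated distance in substitutions per site.
#' @export
nt_distance <- function(seq1, seq2, model, pi = NULL) {
  model <- toupper(model)
  if (!model %in% NT_MODELS) stop("invalid nucleotide model: ", model)
  pc <- pair_counts(seq1, seq2)
  if (is.null(pi) && model %in% c("F81", "F84", "TN93")) {
    chars <- c(strsplit(toupper(seq1), "")[[1]], strsplit(toupper(seq2), "")[[1]])
    chars <- chars[chars %in% NT_UNAMBIG]
    pi <- as.numeric(table(factor(chars, NT_UNAMBIG))) / length(chars)
  }
  nt_distance_from_counts(pc, model, pi)
}

nt_distance_from_counts <- function(pc, model, pi = NULL) {
  p <- pc$p; P1 <- pc$P1; P2 <- pc$P2; Q <- pc$Q
  safelog <- function(x) {
    if (any(x <= 0)) NA_real_ else log(x)
  }
  d <- switch(model,
    PDIST = ,
    RAW = p,
    JC = -0.75 * safelog(1 - 4 * p / 3),
    K2P = {
      l1 <- safelog(1 - 2 * (P1 + P2) - Q); l2 <- safelog(1 - 2 * Q)
      -0.5 * l1 - 0.25 * l2
    },
    F81 = {
      E <- 1 - sum(pi^2)
      -E * safelog(1 - p / E)
    },
    F84 = {
      piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
      piR <- piA + piG; piY <- piC + piT
      A <- piC * piT / piY + piA * piG / piR
      B <- piC * piT + piA * piG
      C <- piR * piY
      P <- P1 + P2
      l1 <- safelog(1 - P / (2 * A) - (A - B) * Q / (2 * A * C))
      l2 <- safelog(1 - Q / (2 * C))
      -2 * A * l1 + 2 * (A - B - C) * l2
    },
    TN93 = {
      piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
      piR <- piA + piG; piY <- piC + piT
      k1 <- 2 * piA * piG / piR
      k2 <- 2 * piC * piT / piY
      k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
      l1 <- safelog(1 - P1 / k1 - Q / (2 * piR))
      l2 <- safelog(1 - P2 / k2 - Q / (2 * piY))
      l3 <- safelog(1 - Q / (2 * piR * piY))
      k1 * l1 * -1 + k2 * l2 * -1 + k3 * l3 * -1
    })
  d <- as.numeric(d)
  if (is.na(d)) {
    warning("saturated pair (log of a non-positive value); returning Inf")
    return(Inf)
  }
  max(d, 0)
}

#' Nucleotide distance matrix
#'
#' All unordered pairs through [nt_distance()]; base frequencies (for
#' F81/F84/TN93) are estimated once from the whole alignment's unambiguous
#' characters, which stabilizes the estimators on short pairs.
#'
#' @param aln a nucleotide [alignment] with at least two sequences.
#' @param model passed to [nt_distance()].
#' @return A symmetric `dist_matrix` (matrix with a class attribute for the
#'   Phylip writer), zero diagonal, `+Inf` marking saturated pairs.
#' @export
nt_distance_matrix <- function(aln, model) {
  if (aln$alphabet != "nucleotide") stop("nucleotide alignment required")
  if (n_seqs(aln) < 2L) stop("at least two sequences required")
  chars <- unlist(strsplit(aln$seqs, ""), use.names = FALSE)
  chars <- chars[chars %in% NT_UNAMBIG]
  pi <- as.numeric(table(factor(chars, NT_UNAMBIG))) / length(chars)
  pairwise_matrix(aln, function(i, j) {
    nt_distance_from_counts(pair_counts(aln$seqs[i], aln$seqs[j]),
                            toupper(model), pi)
  })
}

pairwise_matrix <- function(aln, fun) {
  n <- n_seqs(aln)
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- fun(i, j)
    }
  }
  structure(d, class = c("dist_matrix", class(d)))
}

#' Maximum-likelihood protein distances under empirical models
#'
#' For each sequence pair the distance maximizes the likelihood
#' `prod(pi[a] * P[a, b](d))` over the compared sites, where `P(d) =
#' exp(Q d)` and `Q` is the model's reversible rate matrix normalized to
#' one expected substitution per unit distance. The 1-D likelihood is
#' maximized by Brent search on `[1e-9, 20]` with absolute tolerance 1e-8.
#' Sites where either member carries a gap or a character outside the 20
#' standard amino acids are excluded (pairwise deletion).
#'
#' @param aln an amino-acid [alignment].
#' @param model `"DAYHOFF"`, `"JTT"`, `"MTREV"`, `"LG"`, `"WAG"`, or
#'   `"uniform"` (Poisson).
#' @return A symmetric `dist_matrix` of ML distances.
#' @export
prot_distance_matrix <- function(aln, model) {
  if (aln$alphabet != "amino-acid") stop("amino-acid alignment required")
  if (n_seqs(aln) < 2L) stop("at least two sequences required")
  mod <- prot_model(model)
  codes <- lapply(strsplit(aln$seqs, ""), function(ch) match(ch, AA_ORDER))
  pairwise_matrix(aln, function(i, j) {
    a <- codes[[i]]; b <- codes[[j]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) stop("no comparable sites between ", aln$names[i], " and ",
                       aln$names[j])
    ml_prot_distance(tabulate((a[ok] - 1L) * 20L + b[ok], 400L), mod)
  })
}

ml_prot_distance <- function(pattern_counts, mod) {
  N <- matrix(pattern_counts, 20, 20, byrow = TRUE)
  if (sum(N) == sum(diag(N))) return(0)  # identical over compared sites
  negll <- function(d) {
    P <- transition_probs(mod, d)
    lik <- mod$frequencies * P
    lik[lik <= 0] <- .Machine$double.xmin
    -sum(N * log(lik))
  }
  opt <- stats::optimize(negll, c(1e-9, 20), tol = 1e-8)
  opt$minimum
}

#' Write a distance matrix in Phylip square format
#'
#' Infinite entries (saturated pairs) are written as the sentinel `20.0`
#' and flagged with a message.
#'
#' @param dm a matrix with row/column names, e.g. from
#'   [nt_distance_matrix()].
#' @param file output path, `"-"` for stdout, or `NULL` to return the text.
#' @return The formatted text, invisibly when written to a file.
#' @export
write_phylip_matrix <- function(dm, file = NULL) {
  m <- unclass(dm)
  n_inf <- sum(!is.finite(m))
  if (n_inf > 0) {
    message(n_inf, " saturated entrie(s) written as sentinel 20.0")
    m[!is.finite(m)] <- 20.0
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(rownames(m)[i], "  ",
           paste(sprintf("%.8f", m[i, ]), collapse = " "))
  }, character(1))
  out <- paste0(sprintf(" %d\n", nrow(m)), paste(rows, collapse = "\n"), "\n")
  if (is.null(file)) return(out)
  write_file_auto(out, file)
  invisible(out)
}

#' Read a Phylip square distance matrix
#' @param file path, or `text` the content.
#' @param text optional character scalar.
#' @return Symmetric numeric matrix with names.
#' @export
read_phylip_matrix <- function(file = NULL, text = NULL) {
  content <- if (is.null(text)) read_file_auto(file) else text
  lines <- strsplit(content, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  nm <- vapply(parts, `[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(m) <- list(nm, nm)
  m
}
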