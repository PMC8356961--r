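# Deterministic synthetic data for tests and examples: sequence-pair
# simulation under the implemented substitution models, random alignments,
# and the catalog of hand-derived worked examples.

#' Simulate a homologous sequence pair at a known distance
#'
#' Site-independent simulation: the ancestral state is drawn from the
#' model's equilibrium frequencies and the descendant state from the
#' transition probabilities `P(d) = exp(Q d)` of the normalized rate
#' matrix, so `d` is the expected number of substitutions per site
#' separating the two sequences. Byte-for-byte reproducible under a seed.
#'
#' @param model `"JC"`, `"K2P"`, `"F81"`, `"F84"`, `"TN93"` or a protein
#'   model name accepted by [prot_model()].
#' @param d true distance (substitutions per site), `>= 0`.
#' @param length number of sites.
#' @param seed integer seed.
#' @param pi,kappa optional nucleotide model parameters (frequencies in
#'   A, C, G, T order; transition/transversion rate ratio).
#' @return An [alignment] of two sequences, `s1` (ancestor) and `s2`.
#' @export
simulate_pair <- function(model, d, length, seed = 1L,
                          pi = rep(0.25, 4), kappa = 2) {
  stopifnot(d >= 0, length >= 1)
  model <- toupper(model)
  mod <- if (model %in% c(PROT_MODELS, "UNIFORM")) prot_model(model) else {
    nt_model(model, pi = pi, kappa = kappa)
  }
  states <- names(mod$frequencies)
  k <- length(states)
  local_seed(derive_seed(seed, 3L))
  anc <- sample.int(k, length, replace = TRUE, prob = mod$frequencies)
  P <- transition_probs(mod, d)
  des <- vapply(seq_len(length), function(i) {
    sample.int(k, 1L, prob = P[anc[i], ])
  }, integer(1))
  alignment(c("s1", "s2"),
            c(paste(states[anc], collapse = ""),
              paste(states[des], collapse = "")),
            alphabet = if (k == 4L) "nucleotide" else "amino-acid")
}

#' Random alignment (for round-trip and property tests)
#'
#' Uniform characters with a configurable gap fraction; purely a fixture
#' generator, no evolutionary structure.
#'
#' @param n_seqs,length dimensions.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param gap_frac expected fraction of gap characters.
#' @param seed integer seed.
#' @return An [alignment] with names `s1..sn`.
#' @export
random_alignment <- function(n_seqs, length, alphabet = "nucleotide",
                             gap_frac = 0.05, seed = 1L) {
  local_seed(derive_seed(seed, 4L))
  chars <- unambiguous_chars(alphabet)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    s <- sample(chars, length, replace = TRUE)
    g <- stats::runif(length) < gap_frac
    s[g] <- "-"
    paste(s, collapse = "")
  }, character(1))
  alignment(paste0("s", seq_len(n_seqs)), seqs, alphabet = alphabet)
}

#' Catalog of hand-derived worked examples
#'
#' Small, fully worked cases exercised across the test suite: each entry
#' names the operation, carries its literal inputs, the expected output and
#' the oracle by which the expectation can be re-derived (hand count, path
#' sum, exhaustive enumeration, closed form). The catalog is static and
#' identical across runs.
#'
#' @return A named list of cases, each a list with at least `input`,
#'   `expected` and `oracle` fields.
#' @export
worked_examples <- function() {
  list(
    newick_roundtrip = list(
      input = "((A:1,B:2):3,C:4);", expected = "((A:1,B:2):3,C:4);",
      oracle = "parse then write is the identity on canonical input"),
    newick_branch_sum = list(
      input = "((A:1,B:2):3,C:4);", expected = 10,
      oracle = "sum of the four printed branch lengths"),
    prune_path_merge = list(
      input = list(tree = "((A:1,B:2):3,C:4);", remove = "B"),
      expected = "(A:4,C:4);",
      oracle = "suppressing the degree-2 node sums lengths 1+3"),
    patristic_triple = list(
      input = "((A:1,B:2):3,C:4);",
      expected = c(AB = 3, AC = 8, BC = 9),
      oracle = "path sums over the printed lengths"),
    rf_quartet = list(
      input = list(ref = "((A,B),(C,D));", comp = "((A,C),(B,D));"),
      expected = list(n_common = 0L, rf = 2L),
      oracle = "each quartet has one split; the two differ"),
    rf_binary_vs_star = list(
      input = list(ref = "((A,B),(C,D));", comp = "(A,B,C,D);"),
      expected = list(rf = 1L),
      oracle = "1 split vs 0 splits"),
    star_bipartitions = list(
      input = "(A,B,C,D);", expected = 0L,
      oracle = "a star has no internal edge"),
    collapse_support = list(
      input = list(tree = "((A,B)0.3:1,(C,D)0.9:1,E);", cutoff = 0.7),
      expected = "(A,B,(C,D)0.9:1,E);",
      oracle = "0.3 < 0.7 contracts; 0.9 survives"),
    midpoint_two_tips = list(
      input = "(A:1,B:5);", expected = 3,
      oracle = "half of the 6-unit path"),
    clean_sites_half = list(
      input = list(seqs = c(s1 = "A-A", s2 = "AA-", s3 = "A-A"),
                   cutoff = 0.5),
      expected = 2L,
      oracle = "gap fractions 0, 2/3, 1/3: only column 2 exceeds 1/2"),
    mask_gap_preserved = list(
      input = list(seq = "A-GT", start = 1L, length = 2L),
      expected = "A-NT",
      oracle = "window [1,3) filled with N, gaps preserved"),
    translate_gap_codon = list(
      input = "ATG---AAA", expected = "M-K",
      oracle = "standard code: ATG=M, AAA=K, --- stays a gap"),
    codon_align_map = list(
      input = list(prot = c(s1 = "M-K", s2 = "MLK"),
                   cds = c(s1 = "ATGAAA", s2 = "ATGCTGAAA")),
      expected = c(s1 = "ATG---AAA", s2 = "ATGCTGAAA"),
      oracle = "protein gaps expand to --- codons"),
    jc_p03 = list(
      input = 0.3, expected = -0.75 * log(1 - 4 * 0.3 / 3),
      oracle = "Jukes-Cantor closed form at p = 0.3"),
    k2p_example = list(
      input = c(P = 0.1, Q = 0.05),
      expected = -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
      oracle = "Kimura two-parameter closed form"),
    tbe_cherry = list(
      input = list(ref = "((A,B),(C,D),E);", boot = "((A,C),(B,D),E);"),
      expected = list(delta_AB = 1L, contribution = 0),
      oracle = "cherry p=2: per-tree contribution is 1 - delta/1, delta=1"),
    colless_caterpillar = list(
      input = 3:12, expected = (3:12 - 1) * (3:12 - 2) / 2,
      oracle = "comb imbalance formula (n-1)(n-2)/2")
  )
}
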