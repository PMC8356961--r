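---
title: "Models, algorithms and design choices in phylokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, algorithms and design choices in phylokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylokit)
```

`phylokit` is a toolkit for the repetitive manipulations that surround tree
inference — format conversion, cleaning, rerooting, comparison, branch
supports, distance estimation — exposed both as R functions and as two
chainable command-line tools. This vignette documents the models it
implements, the numerical choices behind them, and the places where a
design decision was genuinely open.

## Tree model and Newick dialect

A tree is a node table: each non-root node carries the branch length and
support of its parent edge. A tree is *rooted* exactly when the root is
bifurcating; a basal trichotomy encodes an unrooted tree, the common Newick
convention. Three dialect decisions matter in practice:

* **Numeric internal labels are supports.** A finite number in the
  internal-label slot is stored as the support of the edge above that node;
  anything else is kept as a clade name. This matches what bootstrap
  pipelines write. A node stores one or the other, never both.
* **Underscores are never translated to spaces.** Labels that need
  protection (whitespace, metacharacters) are single-quoted on output, with
  embedded quotes doubled. This sidesteps the classic underscore ambiguity
  between Newick dialects.
* **Numbers are written as the shortest plain decimal that round-trips**
  through double precision, never scientific notation, so
  `parse_newick(write_newick(t))` reproduces `t` byte-for-byte on its own
  output. Square-bracket comments are skipped, not preserved.

Gzip input is recognized by its two magic bytes, never by file extension;
output is compressed when the target path ends in `.gz`.

## Alignment handling

Sequences are stored uppercase; `U` is normalized to `T` so one code path
serves DNA and RNA. The alphabet is auto-detected: at least 90% of non-gap
characters in `A,C,G,T,U,N` means nucleotide. Phylip is read in both
sequential and interleaved layouts (sequential is attempted first and must
account for every site of every taxon exactly; otherwise the interleaved
interpretation is tried) and written sequentially with relaxed,
full-length names. Trailing content after a complete sequential alignment
is tolerated so the first replicate of a stacked seqboot stream can be
read. Duplicate names are an error everywhere, never silently renamed:
silent renames corrupt downstream joins.

Gap-fraction cleaning (`clean_sites`, `clean_seqs`) uses a *strict*
comparison: a column is removed when its gap fraction exceeds the cutoff,
so a cutoff of 0.5 keeps columns at exactly half gaps and a cutoff of 1
removes nothing. Ambiguity codes count as non-gap for this purpose. The
API is 0-based half-open throughout; the command line accepts the 1-based
inclusive coordinates users expect and converts.

## Distance estimation

Nucleotide distances use the classical closed forms (JC, K2P, F81, F84,
TN93, plus the uncorrected proportion), computed from pairwise-deleted
sites: any position where either sequence carries a gap or any character
outside `A,C,G,T` is excluded entirely — no fractional matching of
ambiguity codes. Base frequencies for F81/F84/TN93 are estimated once from
the whole alignment rather than per pair; per-pair frequencies are noisy on
short sequences and make the matrix asymmetric in the constants it uses.
A saturated pair (a non-positive logarithm argument) yields `+Inf` with a
warning rather than an error, and the Phylip matrix writer substitutes the
sentinel `20.0` (flagged on the diagnostics stream) so downstream tools
still receive a usable matrix.

Protein distances are maximum-likelihood under an empirical model
(Dayhoff, JTT, mtREV24, LG, WAG; the published exchangeabilities and
frequencies ship with the package as plain text). The rate matrix is built
as Q_ij = s_ij π_j with the diagonal set to minus the row sum, then scaled
so the equilibrium substitution rate is one — distances are therefore in
expected substitutions per site. Transition probabilities use the
symmetric eigendecomposition of D^{1/2} Q D^{-1/2} (D = diag(π)), which is
exact for reversible models and numerically stable. The likelihood is
unimodal in d; it is maximized by Brent search on [10⁻⁹, 20] with absolute
tolerance 10⁻⁸. The `uniform` model (equal exchangeabilities, uniform
frequencies) is included because its ML distance has the closed form
−(19/20)·ln(1 − 20p/19), giving the test suite an exact external check of
the whole eigendecomposition-plus-optimization path. No rate heterogeneity
across sites is modelled.

## Branch supports

FBP is exact split membership: the fraction of bootstrap trees whose
bipartition set contains the reference split. TBE replaces membership by
graded proximity: per bootstrap tree, 1 − δ/(p−1), where the transfer
distance δ is minimized over every edge of the bootstrap tree (tip edges
included) and both orientations of the split. A tip edge inside the light
side always realizes δ ≤ p−1, so contributions are non-negative before
clamping. The implementation computes all Hamming distances per bootstrap
tree with 0/1 matrix products; the test suite verifies exact agreement
with a naive per-edge, per-orientation loop, which is the defining
specification. Bootstrap trees must carry exactly the reference taxon set
— partial overlap is rejected rather than renormalized, keeping the
contract simple. Supports are written as internal labels with six
significant digits.

## Tree editing

* **Pruning** removes tips and suppresses the resulting degree-2 nodes,
  summing lengths along merged paths, so patristic distances among
  survivors are preserved exactly. When two edges merge, the merged edge
  keeps the support of the edge *farther from the root*: of the two, it is
  the one whose bipartition survives the merge.
* **Outgroup rerooting** places the root on the edge above the smallest
  clade containing the outgroup, splitting it at its midpoint (the
  reference point is arbitrary; the midpoint keeps both halves
  informative). The unrooted split-length multiset is unchanged; a
  non-monophyletic outgroup triggers a warning, not an error.
* **Midpoint rooting** roots halfway along the longest tip-to-tip path.
  Ties among equally longest paths are broken by the lexicographically
  smallest sorted tip-name pair, making the result deterministic.
* **Collapsing** contracts internal edges strictly below the cutoff
  (length or support criterion); tip edges and support-less edges are
  never touched.
* **Random trees**: Yule (uniform tip splitting), uniform over rooted
  labelled topologies (sequential insertion on a uniformly chosen edge,
  the slot above the root included — on five tips this provably yields all
  105 topologies equally often), caterpillar and balanced. Random models
  draw branch lengths from Exponential(1), a conventional scale that puts
  typical depths near one substitution per site; the deterministic shapes
  use unit lengths.

## Statistics conventions

A *cherry* is an internal node with exactly two tip children; this counts
the root cherry of a two-tip tree and matches the unrooted reading on
larger trees (a three-taxon tree reports one cherry under any rooting of
the same topology). *Sackin* counts edges from root to tip, so a two-tip
tree scores 2; *Colless* requires a rooted binary tree and both are
reported as absent for unrooted input rather than silently rooting.
Bipartitions are canonicalized as the side *not* containing the
lexicographically smallest tip name — a deterministic, order-independent
equality key that needs no double hashing.

## Synthetic data and what the tests show

The package ships its own generators (`simulate_pair`,
`random_alignment`, `random_tree`) because every test input is built in
code. `simulate_pair` draws sites independently: ancestor from π,
descendant from P(d) of the chosen model, so the true distance is known by
construction and estimators can be checked for parameter recovery (JC at
d ∈ {0.1, 0.5, 1.0} with 10⁴ sites, WAG at d = 0.2 with 5·10⁴ sites —
sizes at which the sampling error is a few times smaller than the
tolerances being verified). These simulations have no indels, no rate
variation across sites and no correlation along the sequence; passing
tests therefore validate the estimators and the algebra, not robustness to
alignment error or model misspecification on real data. All generators
take a seed and derive independent sub-streams per replicate, so any
single replicate is reproducible without regenerating the ones before it;
no generator call disturbs the caller's RNG state.

## Command-line contract

One atomic task per subcommand; data on stdin/stdout, diagnostics
(removed-site counts, saturation warnings, monophyly warnings) strictly on
stderr; exit 0 on success, 1 on data errors, 2 on usage errors. Every
randomized subcommand takes `--seed` and is byte-deterministic given it.
These rules are what make the tools safe to chain inside workflow
managers.

## Known limitations

PhyloXML, NHX annotations and Newick comment preservation are out of
scope; bootstrap trees with partially overlapping taxa are rejected;
protein ML distances assume rate homogeneity across sites; nucleotide
distances are closed-form only. The Nexus reader targets the common
TREES/DATA dialects (case-insensitive keywords, optional TRANSLATE), not
the full grammar.
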