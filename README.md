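# phylokit

Phylogenetic analysis pipelines are mostly glue: reformatting alignments
between FASTA/Phylip/Clustal/Nexus, renaming and cleaning sequences,
pruning and rerooting trees, comparing topologies, and attaching bootstrap
supports. These steps are individually small but numerous, and doing them
with ad-hoc scripts makes workflows fragile and hard to reproduce.
`phylokit` packages them as a library of atomic, composable operations with
two shell entry points (`phylokit-tree`, `phylokit-alignment`) that read
standard input and write standard output, so commands chain in Unix
pipelines exactly as they would inside a Nextflow or Snakemake workflow.

## What it computes

**Evolutionary distances.** For nucleotide alignments, the closed-form
estimators with pairwise deletion of gap/ambiguous sites — with *p* the
mismatch proportion, *P₁*, *P₂* the A↔G and C↔T transition proportions,
*Q* the transversion proportion and *π* the base frequencies:

- JC: d = −(3/4)·ln(1 − 4p/3)
- K2P: d = −(1/2)·ln(1 − 2P − Q) − (1/4)·ln(1 − 2Q)
- F81: d = −E·ln(1 − p/E), E = 1 − Σπᵢ²
- F84 and TN93: the Felsenstein-1984 and Tamura–Nei-1993 forms in
  (P₁, P₂, Q, π)

plus `pdist`/`raw`. For protein alignments, the distance d̂ maximizes the
likelihood L(d) = ∏ πₐ·P_ab(d) over compared sites, with P(d) = exp(Qd) and
Q the reversible rate matrix of an empirical model (Dayhoff, JTT, mtREV,
LG, WAG) normalized to one expected substitution per unit distance;
the one-dimensional likelihood is maximized by Brent search on [10⁻⁹, 20].

**Branch supports.** Given a reference tree and bootstrap trees on the same
taxa: Felsenstein bootstrap proportions (FBP), the fraction of bootstrap
trees containing each reference bipartition exactly, and the transfer
bootstrap expectation (TBE), the mean over bootstrap trees T of
1 − δ(b,T)/(p−1), where δ is the transfer distance (minimum number of taxa
that must switch sides to turn the reference split b into a split of T) and
p is the light-side size of b. TBE ≥ FBP edge-wise, with equality on
cherries (p = 2).

**Everything around them.** Newick/Nexus tree I/O (gzip detected by magic
bytes), bipartition-based Robinson–Foulds comparison, pruning with exact
preservation of patristic distances, outgroup and midpoint rerooting,
collapsing branches by length or support, polytomy resolution, random tree
generation (Yule, uniform-topology, caterpillar, balanced), tree statistics
(cherries, Colless and Sackin imbalance, patristic matrices); alignment
cleaning, renaming, masking, extraction, concatenation, translation,
codon-aware back-translation, and bootstrap column resampling (seqboot).

## Worked example

Transfer and classical supports for a reference tree against ten bootstrap
trees, eight of which reproduce it:

```r
library(phylokit)
ref   <- parse_newick("(((A,B),C),((D,E),F));")
boots <- c(replicate(8, parse_newick("(((A,B),C),((D,E),F));"), simplify = FALSE),
           replicate(2, parse_newick("(((A,C),B),((D,F),E));"), simplify = FALSE))
res <- tbe(ref, boots)
res$table
#>    split p support mean_transfer_dist
#>    D,E,F 3     1.0                0.0
#>  C,D,E,F 2     0.8                0.2
#>      D,E 2     0.8                0.2
write_newick(res$tree)
#> (((A,B)0.8,C)1,((D,E)0.8,F)1);
```

The split separating {A,B,C} from {D,E,F} (printed as its canonical side
`D,E,F`) survives in every bootstrap tree, support 1.0; the two cherries
are destroyed in the two conflicting trees, so eight exact matches plus two
transfer distances of 1 with p = 2 give 0.8. Supports are written into the
Newick internal-label slot, ready for any viewer.

Distance recovery from a simulated pair (Tamura–Nei model, true distance
0.3, 5000 sites):

```r
a <- simulate_pair("TN93", 0.3, 5000, seed = 1, pi = c(.35, .15, .2, .3), kappa = 3)
nt_distance(a$seqs[1], a$seqs[2], "TN93")
#> [1] 0.3091345
```

The same operations from a shell:

```sh
phylokit-tree generate yule -n 8 --seed 3 \
  | phylokit-tree reroot midpoint \
  | phylokit-tree stats
phylokit-alignment build seqboot -n 100 --seed 7 -i aln.fasta \
  | phylokit-alignment compute distance -m tn93
```

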