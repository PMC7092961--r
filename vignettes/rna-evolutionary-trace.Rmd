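---
title: "Evolutionary Trace analysis of RNA: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary Trace analysis of RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaet)
```

## The problem

Structured functional RNAs — ribozymes, riboswitches, rRNA — carry their
functional determinants in a minority of nucleotides: catalytic cores,
ligand pockets, tertiary contacts.  Plain column conservation finds some
of them, but misses positions that are free to vary *between* lineages
while being strictly maintained *within* each lineage (a hallmark of
subfunctionalized or clade-specific elements).  The Evolutionary Trace
(ET) framework ranks every alignment column by how well its variation
tracks the branching of the phylogeny, so both kinds of constraint are
detected.

`rnaet` implements the full pipeline for RNA: trace ranking, structural
evaluation of the ranking (clustering, overlap with functional sites,
smoothness), and ensemble optimization of the input alignment, together
with a synthetic fixture generator that makes every stage testable
without downloading any family data.

## Trace ranking

The alignment (over the alphabet `A C G U N -`; gaps are a first-class
fifth symbol everywhere) is first clustered into a rooted binary UPGMA
tree.  Cutting the tree below the `n` internal nodes closest to the root
partitions the leaves into `n` groups; the partitions are nested, with
sizes running from 1 (the whole alignment) to N − 1.

*Integer ET* assigns column `i` the rank

    r_i = 1 + sum_{n=1}^{N-1} delta(n)

where `delta(n)` is 0 when the column is invariant inside **every** group
of the level-`n` partition and 1 otherwise.  A fully conserved column
earns rank 1; a column that differs in every sequence earns rank N.

*Real-value ET* (`rvet()`, the default throughout) replaces the binary
penalty with the mean Shannon entropy (natural logarithm) of the column
within the groups, weighting level `n` by `1/n`:

    r_i = 1 + sum_{n=1}^{N-1} (1/n) * sum_{g=1}^{n} H_ng(i)

Entropy degrades gracefully under sequence noise, which is the practical
reason to prefer it: a column fixed within each clade but different
between clades contributes `ln 2` at the root level and nothing below it,
keeping its rank near the top even when a few sequences are corrupted.

Ranks are normalized to percentile **coverage** (ties share the largest
position, so coverage lies in (0, 100]).  Positions with coverage at or
below 35% are called *ET nucleotides*; the 35% window is a convention
carried over from protein traces and is a parameter (`max_cov`), not a
constant.

`shannon_conservation()` provides the tree-free conservation baseline on
the same coverage scale.

### Numerical and tie-breaking choices

* **UPGMA distance.** Normalized Hamming distance over all columns,
  gap counted as a symbol.  It is the simplest distance consistent with
  gap-as-nucleotide, and it is what the tests' independent `hclust`
  cross-check uses.
* **Merge ties.** Equal minimum distances resolve to the lexicographically
  lowest pair of current cluster indices, so trees are bit-reproducible.
* **Equidistant internal nodes.** Nodes are consumed one per level in
  deterministic (reverse-creation) order, so every level has exactly one
  more group than the previous one.
* **Alphabet.** `N` contributes to entropies as a symbol of its own;
  only observed symbols matter, so the nominal alphabet size never enters
  the computation.

## Structural evaluation

Contact graphs come in three contexts: tertiary (`contact_graph_3d()`:
minimum heavy-atom distance at most 4 Å, immediate backbone neighbors
excluded by default because they contact trivially — both the cutoff and
the exclusion are parameters), secondary (base pairs plus backbone), and
primary (backbone only).  "Distance between nucleotides" is made concrete
as the minimum over heavy-atom pairs; a C1′-only mode is available.

The **Selection Clustering Weight** `w` of a position set S is the number
of graph edges internal to S.  Its null mean and variance under uniform
selection of k of L positions are closed forms in the edge count E and
the number of 2-paths T:

    <w>  = E p2
    Var  = E p2 + 2 T p3 + (E(E-1) - 2T) p4 - (E p2)^2

with `p_m` the probability that m named positions are all selected.  The
tests verify these against exhaustive enumeration of every selection on
small graphs, and a permutation mode provides a Monte-Carlo alternative.

The **clustering z-score** is `(w - <w>)/sigma`.  Positions are binned
cumulatively by rank; bin b (coverage 100·b/L) is *attained* when the
selection at that threshold has exactly b members.  Bins inside a tied
plateau, and bins with zero null variance and a non-zero deviation, are
invalid and inherit the z of the closest valid bin (ties toward lower
coverage); a zero-variance bin whose observed weight equals its
expectation exactly (the full selection, for instance) is scored 0 and
kept.  `zc35%` is the mean of the filled bins with coverage ≤ 35%.

The **overlap z-score** compares the number of functional-site members in
a selection with the hypergeometric expectation `n M / N` and standard
deviation `sqrt(n (M/N)(1-M/N)(N-n)/(N-1))`.  (The divisor N − 1 is the
standard finite-population correction; the tests pin the formula to the
enumeration oracle.)  Site-specific evaluation removes *other* known
sites from the universe entirely — they count neither as positives nor
negatives, both in z and in the ROC AUC, which is computed by pair
counting with ties credited ½.

**Smoothness** (`smoothness()`) is the sum of squared rank differences
over adjacent positions; by default the coverage percentile is used as
the rank variable so values are comparable across molecules of different
alignment depth.

## Alignment optimization

Trace quality is limited by the input sequence set.  `optimize_alignment()`
draws an ensemble of sub-alignments, removing a uniform-random number of
sequences (never the query row; at least `min_keep` sequences remain),
traces each member, and keeps the best under one of:

* `zc35` — maximize the mean clustering z-score, the recommended
  criterion;
* `re_smt` — maximize min–max-normalized Rank Entropy times
  (1 − normalized smoothness).  Rank Entropy, `RE = -sum f_r ln f_r`
  over the frequencies of distinct rank values, is zero for an entirely
  conserved trace and maximal when all ranks are distinct; it guards the
  smoothness term against collapsing onto a few invariant sequences;
* `smt` — pure smoothness, exposed deliberately because it exhibits that
  failure mode (the tests assert it selects lower rank diversity than
  `re_smt`).

Orientation and normalization choices: smoothness is a cost, so the
combined score uses `1 − normalized SMT`; min–max normalization is taken
over the current ensemble, which makes the product well-defined without
any external scale.  All stochastic steps derive their RNG streams
deterministically from (seed, member id).

`degradation_study()` implements the complementary experiment: corrupt a
fraction of non-gap characters with uniform random bases (resampling, so
the expected identity at rate 1 is exactly 0.25; a within-column
permutation mode is available behind a flag), re-trace, and track how
overlap, clustering, and smoothness co-degrade across rates.

## The synthetic fixture

`make_fixture()` generates the study system used throughout the tests:

* a balanced binary tree of `n_leaves = 16` sequences (two top-level
  clades), `L = 80` columns;
* 20% conserved columns, 20% clade-specific columns (fixed within each
  clade, distinct between clades — the signal that distinguishes ET from
  conservation), 60% iid uniform columns;
* a toy helix structure, one pseudo-atom per residue (radius 3 Å, twist
  30°, rise 1 Å), chosen so that residues i and i±2 fall 3.6 Å apart —
  inside the 4 Å cutoff — while backbone neighbors are excluded; the
  conserved plus clade-specific columns form one contiguous block, so the
  planted functional site is spatially clustered;
* an optional `noise` rate that corrupts characters of the important
  columns, the regime in which real-value ET visibly outperforms plain
  conservation.

These defaults were chosen once as a realistic small instance (alignment
depth and length of a compact RNA family, two major clades, a
catalytic-core-sized site) and all calibration, positive-control,
degradation, and recovery experiments run against them.  What the fixture
does **not** emulate: realistic substitution processes, indel evolution,
rate heterogeneity, or alignment error; passing tests demonstrate the
statistics and the machinery, not performance on real families.

Scaled problem sizes used by the test suite: null calibration over 200
fixture seeds; positive controls over 25 seeds; degradation over 6 rates
× 3 replicates; decontamination recovery over 25 seeds with ensembles of
400 members and `min_keep = 10` (the default `min_keep = 20` reflects
full-scale alignments of hundreds of sequences; the fixture alignment has
21 after contamination, so the floor is scaled with it).

## Degenerate inputs and edge cases

* A trace in which every column ties produces a single attained bin at
  100% coverage; the summary window inherits its z-score (0) rather than
  erroring.
* `clustering_z()`/`overlap_z()` flag zero-variance selections
  (`valid = FALSE`, `z = NA`); profiles exclude such bins from the fill
  sources, and a profile with no valid bin at all is an error.
* A functional site covering the whole universe, or emptied by
  exclusions, is an error.
* Mapping between alignment columns and structure residues tries an
  exact substring match before falling back to global pairwise alignment,
  and rejects mappings with more than 10% base mismatches (configurable).

## Known limitations

* UPGMA is the only tree built in-package (Newick import/export via
  `ape` is provided); likelihood trees are out of scope.
* Structures are reduced to one RNA chain, first model; modified
  nucleotides are read as their parent base or `N`.
* The overlap machinery reports raw z-scores; no multiple-testing
  correction is applied across sites.
* Optimization only removes sequences; it never proposes additions.
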