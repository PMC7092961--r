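# rnaet — Evolutionary Trace ranking and structural cluster analysis for RNA

`rnaet` ranks every column of an RNA multiple sequence alignment by
phylogenetic importance and evaluates that ranking against structure and
function.  It is aimed at people studying structured functional RNAs
(ribozymes, riboswitches, rRNA) who want to locate catalytic cores,
binding surfaces, and other functional sites from sequence variation
alone, and to quantify how trustworthy the resulting map is.

## The method

1. **Trace.**  A UPGMA tree is built from the alignment (normalized
   Hamming distance; gaps count as a fifth symbol).  Integer ET scores a
   column by the number of tree levels at which it still varies inside
   some branch:

       r_i = 1 + Σ_{n=1}^{N−1} δ(n),   δ(n) = 0 iff column i is invariant
                                        within every group at level n

   Real-value ET (the default) weights each level by the mean in-group
   Shannon entropy, `r_i = 1 + Σ_n (1/n) Σ_g (−Σ_a f_iag ln f_iag)`,
   giving noise-robust real-valued ranks.  Ranks are normalized to
   percentile *coverage*; positions at coverage ≤ 35% are the "ET
   nucleotides".

2. **Clustering.**  On a contact graph (tertiary: min heavy-atom distance
   ≤ 4 Å; secondary: base pairs + backbone; primary: backbone), the
   Selection Clustering Weight `w = Σ_{i>j} S(i)S(j)A(i,j)` of each
   cumulative rank bin is standardized with analytic null moments to a
   z-score; `zc35%` is the mean over the 0–35% coverage bins.

3. **Overlap.**  Recovery of annotated functional sites is standardized
   under the hypergeometric null (`zo35%`), with other known sites
   removable from the universe, plus ROC AUC by pair counting.

4. **Optimization.**  `ET smoothness` (Σ A(i,j)(x_i−x_j)², lower =
   smoother), Rank Entropy (−Σ f_r ln f_r), and `zc35%` score random
   sub-alignment ensembles to pick a better input alignment.

A synthetic-fixture generator (`make_fixture()`) produces balanced-tree
alignments with conserved / clade-specific / random columns and a toy
helix structure with a planted, spatially contiguous site, so the whole
pipeline is testable and calibratable offline.

## Worked example

```r
library(rnaet)

fx   <- make_fixture(fixture_spec(seed = 42))   # 16 sequences, 80 columns
tree <- build_upgma(fx$alignment)
tr   <- rvet(fx$alignment, tree)
g    <- contact_graph_3d(fx$structure)          # 4 A heavy-atom contacts

z_profile(tr, g)
#> z_profile (clustering): 80 bins, mean z over 0-35% coverage = 7.935

ov <- overlap_profile(tr, fx$site$members)
sprintf("zo35 = %.3f  AUC = %.3f", ov$mean_0_35, ov$auc)
#> [1] "zo35 = 5.935  AUC = 1.000"

head(as.data.frame(tr), 3)
#>   column rank coverage
#> 1      1    1       20
#> 2      2    1       20
#> 3      3    1       20
```

The planted site (the conserved + clade-specific block) clusters far
above chance (`zc35% = 7.9`; values ≥ 2 are significant) and is fully
recovered by the top-ranked positions (`zo35% = 5.9`, AUC = 1).  The
three columns shown are conserved, hence rank exactly 1 and shared
coverage 20% (the conserved block is the top fifth of the ranking).

A command-line front-end with the same functionality is installed as
`exec/rna-et` (subcommands `trace`, `cluster`, `overlap`, `simulate`,
`degrade`, `optimize`), e.g.

```sh
rna-et simulate --out fix --seed 3
rna-et trace   --aln fix/alignment.sto --method rvet --out ranks.tsv
rna-et cluster --ranks ranks.tsv --structure fix/structure.pdb \
               --out zprofile.tsv --summary cluster.json
```

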