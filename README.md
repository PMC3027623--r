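# parsikit

Maximum-parsimony phylogenetics for discrete morphological character
matrices, in R.  parsikit implements the complete analysis pipeline used
in systematic paleontology to place a new taxon: heuristic tree search on
a NEXUS/TNT matrix, consensus and branch-support evaluation, constrained
topology hypothesis tests, and parsimony mapping of discrete and
continuous traits (the motivating application: sacral-vertebra
configuration and femoral shaft width as a body-size proxy across the
'prosauropod'–sauropod transition).

## The method in brief

A character matrix scores 50 or so taxa across a few hundred discrete
characters, with abundant missing data.  A tree's length is

> L(T) = Σ_c w_c · min over ancestral state assignments of the number of
> state changes of character c on T,

with unit weights, 0/1 change costs for unordered characters and |i−j|
for ordered (additive) ones.  The most parsimonious trees (MPTs) minimize
L.  parsikit computes lengths with a generalized Sankoff dynamic program
(exact on binary and multifurcating trees, with missing cells as free
choices), and searches tree space with the classic strategy: random
addition sequence Wagner trees, TBR branch swapping holding a buffer of
equally parsimonious trees per replicate, then a final unbounded TBR
round, rule-1 collapsing of unsupported branches, and deduplication by
bipartition set.  On top of the MPT set it provides:

* strict and reduced strict consensus; greedy rogue-taxon identification
  with a missing-data vs character-conflict classification;
* Bremer supports by reverse-constraint search; bootstrap and jackknife
  group frequencies, absolute and GC;
* Templeton (Wilcoxon signed-rank) tests of constrained alternative
  placements, exact for N ≤ 25 nonzero per-character differences;
* MPR ancestral states with typed change lists (unambiguous
  synapomorphies, ambiguous changes, autapomorphies) and linear-parsimony
  interval reconstruction of continuous traits;
* a synthetic-data generator (known tree, Poisson change counts,
  controlled missingness) so the whole pipeline is testable offline.

Ensemble indices follow the standard definitions: CI = M/L and
RI = (G−L)/(G−M), where M and G are the summed per-character minima and
star-tree maxima.

## Worked example

```r
library(parsikit)

set.seed(1)
tree   <- simulate_tree(12, seed = 7)                     # known topology
matrix <- simulate_matrix(tree, synthetic_spec(n_chars = 150, rate = 1.2,
                                               missing_frac = 0.2), seed = 8)

cfg <- analysis_config(
  matrix,
  search     = search_config(n_replicates = 10, hold = 10),
  hypotheses = list(alt = constraint(c("t01", "t12"))),
  resampling = list(n_reps = 100, schemes = "bootstrap"),
  seed = 42)
rep <- run_full_analysis(cfg)
rep
#> parsimony analysis: 12 taxa x 150 characters
#>   best length 137 (CI 0.708, RI 0.714), 1 MPTs; best found in 10/10 replicates
#>   hypothesis 'alt': +19 steps, Templeton p = 3.815e-06
```

Read: the search found a single most parsimonious tree of 137 steps in
every replicate (length and the ensemble consistency/retention indices
are the standard summary of fit); forcing the two named taxa to be
sisters costs 19 extra steps, and the Templeton test firmly rejects that
placement.  `rep$bremer`, `rep$resampling`, `rep$consensus`
and `rep$mpts` hold the per-clade support tables and trees; with
`output_dir` set, the same results are written as JSON, TSV and Newick
files.  Real matrices enter through `read_matrix("file.nex")` (NEXUS or
TNT `xread`, including polymorphic cells and ordered-character blocks).

A study-scale synthetic data set shaped like a basal-sauropodomorph
analysis (50 taxa × 277 characters, two fragmentary rogue taxa, nested
sacral-state gains, a body-size trait) is available via
`basal_sauropodomorph_fixture()`.

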