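---
title: "Parsimony analysis of morphological matrices with parsikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony analysis of morphological matrices with parsikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsikit)
```

## The problem and the model

parsikit implements the standard workflow for analysing a discrete
morphological character matrix under equally weighted maximum parsimony,
the framework in which most studies of basal dinosaur (and generally
fossil-taxon) relationships are conducted.  The data are a taxa-by-characters
grid of state sets: singleton cells for ordinary observations, `?` for
missing data, `-` for inapplicable (gap) cells, and multi-state sets for
polymorphic or uncertain scorings.  A candidate phylogeny is an unrooted,
leaf-labelled tree; its score is the minimum number of state changes
(steps) needed to explain every character on that tree, summed over
characters.  The preferred hypotheses are the most parsimonious trees
(MPTs), and everything downstream — consensus, branch support, hypothesis
tests, ancestral-state reconstruction — is computed over that optimal set.

Two character kinds are supported.  *Unordered* (non-additive) characters
cost one step for any state change; *ordered* (additive) characters cost
the interval distance `|i - j|`, appropriate when states form a
morphocline (e.g. counts of sacral vertebrae).  Both are scored exactly by
one generalized Sankoff dynamic program: each node carries a vector of
conditional subtree costs per state, combined across edges by a min-plus
transform that costs O(k) per edge for both cost regimes.  This single
engine subsumes the classical Fitch (unordered) and Farris/Wagner interval
(ordered) passes and — unlike textbook Fitch — remains exact on
multifurcating trees, which matters because consensus trees and rule-1
collapsed trees are routinely polytomous.  Missing and gap cells enter the
leaf cost vectors as "every state free", the standard treatment; gap is
retained as a distinct tag for reporting but never scored as a fifth
state, since matrices of this school do not use it that way.  Polymorphic
`(01)` and uncertain `{01}` tokens are both scored as free choice within
the set (the cheapest member is taken during optimization); the exact
polymorphism costing some programs apply is deliberately out of scope.

## Heuristic search

Exact optimization is hopeless beyond ~12 taxa, so the package reproduces
the classic two-stage heuristic:

1. **Random-addition Wagner trees.** Taxa are added in a seeded random
   order, each at the currently cheapest insertion edge, ties broken
   uniformly from the same stream.  Each replicate therefore starts the
   climb from a different region of tree space.
2. **TBR branch swapping.** Every branch is bisected and the two fragments
   reconnected across every pair of their edges.  The climb accepts strict
   improvements and explores equal-length plateaus, holding up to a
   configurable number of trees per replicate (default 10).
3. **Final round.** The best trees pooled over all replicates are swapped
   again with an unbounded buffer, expanding the complete set of optimal
   trees reachable on the plateau, which is then collapsed (rule 1) and
   deduplicated by bipartition set.

Rule-1 collapsing contracts an internal branch iff its minimum optimized
length over all most-parsimonious reconstructions is zero — i.e. no
character forces a change there.  The quoted rule admits two readings; we
use the standard software meaning ("minimum length zero"), computed
exactly from the same Sankoff arrays via an outside (rest-of-tree) pass.
Collapsing happens after the search, before deduplication; counts of MPTs
are sensitive to this timing, which is why downstream logic relies on the
consensus rather than the raw MPT count.

Every source of randomness derives from one master seed through derived
per-replicate seeds, so a whole analysis is bit-reproducible.  The
per-replicate diagnostic `replicate_hits` records how many replicates
reached the final best length — the usual sanity check that search effort
was adequate.

## Consensus, rogue taxa, and support

The strict consensus contains exactly the bipartitions present in every
MPT (tested as an exact set identity).  Fragmentary taxa that float among
positions can dissolve real structure; `identify_unstable_taxa()`
implements a greedy variant of iterative positional-congruence pruning:
repeatedly remove the leaf whose solitary deletion most increases
consensus resolution, stop at zero gain.  For each pruned taxon the
distinct attachment positions across the MPTs are collected, and the cause
is classified as `missing_data` when the taxon's scored characters have
identical summed optimized length in every alternative position (nothing
in the data favours one spot), else `character_conflict`.  The published
procedure this emulates is cited, not restated, in the sources we follow,
so the gain criterion and classifier here are documented stand-ins, not a
reimplementation.  The reduced strict consensus is then the strict
consensus of the MPTs with those taxa pruned a posteriori — never a
re-search.

Branch support comes in two families:

* **Bremer (decay) support**: for each consensus clade, the extra steps
  needed before trees lacking the clade appear.  The default method runs a
  reverse-constraint search per clade (forbid monophyly, search, subtract);
  it is exact up to search effort and is validated against exhaustive
  enumeration on small fixtures.  A sweep method that harvests one
  suboptimal search instead is available for speed and yields lower
  bounds.
* **Resampling frequencies**: bootstrap (characters resampled with
  replacement, implemented as weight vectors) and jackknife (independent
  deletion, default probability 0.36, the conventional removal rate close
  to `1 - exp(-1)`).  Each pseudoreplicate is searched at reduced effort
  (default 2-5 addition replicates — full production effort per
  pseudoreplicate buys nothing at these matrix sizes) and the bipartitions
  of its strict consensus tallied.  `absolute` is the recovery percentage;
  `GC` subtracts the frequency of the most frequent contradicting group,
  so it is negative for groups that the resampled data actively dispute.

## Topology hypothesis tests

Alternative placements of a taxon are tested by constrained search
(enforce a monophyly constraint, re-search, count extra steps) followed by
the Templeton test: the per-character length differences between the
constrained best tree and an MPT are ranked (midranks for ties, zeros
dropped) and the smaller signed rank sum is referred to the signed-rank
null.  For `N <= 25` nonzero differences the p-value is exact, computed by
dynamic programming over the doubled midranks (equivalent to enumerating
all `2^N` sign assignments, and verified against that enumeration); for
larger `N` a normal approximation with tie and continuity corrections is
used, matching the generic signed-rank routine to within `1e-9`.  The
switch point and the corrections follow common practice in phylogenetic
software; both branches are exposed because published p-values may
reflect either.  Reporting is two-tailed and symmetric in the two trees.

## Trait mapping

Discrete traits (the motivating case: sacral configuration, with states
such as `S1+S2`, `DS+S1+S2`, `DS+S1+S2+CS`) are mapped by the same MPR
machinery: per-node optimal state sets plus a typed change list.  A change
on a terminal edge is an `autapomorphy`; an internal change present in
every MPR is a `synapomorphy_unambiguous`; anything present only in some
MPRs is `ambiguous`.  `diagnose_clade()` applies this across the whole MPT
set and demotes to `ambiguous` any character whose stem-edge change fails
in even one MPT — mirroring how published diagnoses flag synapomorphies
that hold "only in some of the MPTs".

Continuous traits (femoral lateromedial shaft width, FML, as a body-size
proxy) are reconstructed under linear parsimony: minimize the summed
absolute change along edges.  Optima of this Manhattan cost always occur
at observed leaf values, so the implementation runs the ordered-character
dynamic program on the grid of distinct observed values, which is exact;
per-node closed intervals are the unions of optimal assignments (Farris
intervals), matching the "range of ancestral body size" presentation such
studies use.  A squared-change variant (each ancestor the mean of its
neighbours, solved as a small linear system) is offered for comparison.
Conversion of FML to body mass via a published regression is left to the
user as an affine map on logs — the regression coefficients are citations,
not data we ship — so the pipeline reports FML itself.

## The synthetic-data generator

Because the package must be testable end to end without external data,
`simulate_tree()` / `simulate_matrix()` generate matrices with the
statistical structure the analysis assumes: uniform random unrooted
topologies (sequential uniform edge addition), and characters evolved by a
Poisson number of changes dropped on random edges — symmetric jumps for
unordered characters, reflecting ±1 steps for ordered ones — followed by
cell-wise degradation to missing or polymorphic states.  Change counts
rather than continuous-time rates are simulated deliberately: parsimony
never consumes branch lengths, and the change count directly controls
homoplasy (ensemble CI falls monotonically as the rate rises, which is
tested).  A "fragmentary taxon" mode concentrates missingness in chosen
rows to reproduce rogue-taxon behaviour.

`basal_sauropodomorph_fixture()` assembles a deterministic study-scale
data set — 50 taxa by 277 characters, roughly 40% missing cells, two
fragmentary rogues, a sacral trait with nested gains plus one
autapomorphic deviant, and an FML trait rising toward the derived clade
with one small-bodied exception nested inside it.  It mimics the *shape*
of such studies, not any real matrix: characters are independent and
missingness (outside the rogues) is uniform, so passing tests demonstrate
algorithmic correctness, not that real morphological data behave this
benignly.

## Numerical and design choices

* State alphabets are capped at 31 states so a cell's state set fits an
  integer bitmask; symbols `0-9` then `A-U` are accepted.
* All lengths are integers (weighted sums of integer steps); no tolerances
  enter scoring.  Ties in Wagner addition are broken by the seeded stream;
  ties among equally parsimonious trees are kept, not broken.
* Trees are stored unrooted; any outgroup provides display rooting only,
  since parsimony length is rooting-invariant.  A constraint group is
  monophyletic iff its bipartition is an edge of the unrooted tree.
* Character indices are 0-based in TNT `ccode` blocks (that format's
  convention) and 1-based everywhere the package reports to the user.
* CI and RI are reported both over all active characters (headline values,
  the common software default) and over parsimony-informative characters
  only, since published values do not always state the variant.
* Degenerate inputs are defined, not crashed on: constant matrices score
  length 0 with CI/RI reported as `NaN` plus a warning; star trees have
  empty bipartition sets; pruning below 3 leaves is refused.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on generated data at
sizes chosen to keep exhaustive oracles feasible: brute-force labeling
checks on trees of up to 6 leaves, exhaustive topology enumeration up to 8
taxa (10,395 trees), recovery simulations at 8 taxa by 500 characters, and
a 12-taxon by 150-character end-to-end study with 100 bootstrap and
jackknife pseudoreplicates.  The full pipeline scales to the 50-by-277
fixture; a production-scale run of that size is simply a matter of more
replicates and wall time.

## Known limitations

* No implied or successive weighting, no step-matrix (Sankoff-matrix)
  custom costs, no continuous characters in the matrix model itself.
* The TBR scan rescoring is exact but not incremental; very large matrices
  would benefit from the usual incremental shortcuts.
* The unstable-taxon cause classifier is a stated approximation (see
  above), and resampling pseudoreplicates use reduced search effort, which
  can depress support values slightly for barely supported groups.
* MPT counts depend on collapsing conventions; cross-program comparisons
  should be made at the level of best length and consensus structure.
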