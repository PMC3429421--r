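---
title: "Dollo parsimony for SINE presence/absence markers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dollo parsimony for SINE presence/absence markers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinephylo)
```

## The character model

A SINE insertion locus scored across a taxon panel is a binary character with
a known polarity: absence is ancestral, presence derived. Because an element
inserts once at a given site and is practically never excised precisely, the
natural evolutionary model is Dollo's: **at most one gain** of the derived
state anywhere on the tree, **any number of losses** below it, and the state
ancestral to the root fixed at absent. `sinephylo` scores a character on a
rooted tree as gains plus losses of the minimal reconstruction under these
constraints, computed by a three-state dynamic programme over the nodes (cost
of: absent with no gain below; absent with the single gain below; present).
The gain lands on the edge above the most recent common ancestor of the
present leaves; each maximal all-absent subtree inside the gain clade costs
one loss.

Three conventions deserve spelling out:

* **Characters present on both sides of the root.** The single gain is placed
  on the root's stem and still costs one step, so a character present in every
  taxon scores 1, not 2. This matches the behaviour of the classic parsimony
  programs with ancestral state fixed at absent. With outgroups in the panel
  (which lack every ingroup marker by construction) the case does not arise in
  practice.
* **Unknown cells (`?`).** A failed amplification carries no information
  either way, so unknown leaves take whichever state does not increase the
  step count. Ties resolve to absent: we never infer an insertion that the
  data do not force. Concretely, an unknown leaf strictly inside a gain clade
  whose resolution as absent would cost a loss resolves present; an unknown
  leaf that could join a pendant gain at no cost resolves absent (and the
  smaller gain clade is reported).
* **Multifurcations.** Polytomies are scored directly by the same programme —
  each all-absent child subtree inside the gain clade is one loss — so
  consensus trees and collapsed trees can be scored and annotated without
  arbitrary resolution.

The per-character scorer exists twice: a small C++ routine used by the tree
search and bootstrap (where it is called hundreds of thousands of times) and
an R implementation with a traceback that also reports the gain edge, the loss
edges and the resolved states. The test suite holds the two equal, and holds
both equal to an independent brute-force oracle that enumerates every legal
internal-state assignment on every rooted topology with up to six leaves.

## Ensemble indices

With per-character observed steps `obs`, minimum `min` (1 for any character
with a present taxon) and maximum `max`, the ensemble indices are
`CI = Σmin/Σobs`, `HI = 1 − CI`, and `RI = (Σmax − Σobs)/(Σmax − Σmin)`.
`RI` is reported as undefined when `Σmax = Σmin` (e.g. a matrix of
autapomorphies, where no character can show homoplasy on any tree).

The per-character maximum under Dollo needed a decision. We use

```
max = 0 (no present taxon), 1 (one present taxon), 1 + n_absent (otherwise)
```

The worst case is attained by a caterpillar interleaving the absent leaves
along the paths between present leaves, which makes every absent leaf its own
maximal absent subtree inside the gain clade; no tree can do worse because
losses are bounded by the number of absent leaves. `max_dollo_steps()` also
offers exhaustive enumeration over all rooted binary trees, and
`ensemble_indices()` uses the enumeration on panels of up to 8 taxa; the
closed form is validated against the enumerator in the tests across the full
range it can reach. Note the simpler guess `1 + min(n_present − 1, n_absent)`
is wrong whenever absent leaves outnumber interleaving opportunities — the
enumerator refutes it already at two present and two absent taxa (maximum 3,
not 2) — which is why the validated form above is the package's convention.
On a homoplasy-free matrix the choice is immaterial (`obs = min` makes
`RI = 1` under any convention that keeps `Σmax > Σmin`).

## Tree search

Panels of up to 7 taxa (configurable) are searched **exactly**: all
`(2n−3)!!` rooted binary topologies are scored (10,395 at n = 7, a fraction of
a second with the C++ scorer). This keeps the small-panel behaviour honest —
branch swapping can stall in local optima even with SPR at six taxa, as the
test suite demonstrates on random matrices.

Above the cutoff the search is the classic heuristic: greedy stepwise
addition (taxa in panel order or seeded random order; ties broken by the
first attachment point in a deterministic node ordering), then hill climbing
by NNI or SPR accepting the **first** improving neighbour in a deterministic
edge order — reproducibility over aggressiveness — until no neighbour is
shorter. Independent random-addition restarts (`n_starts`) are available as
the standard insurance against local optima; the lemur fixture needs none
(its characters are perfectly clade-consistent, so the greedy start already
lands on an optimum). Equally-best topologies are then collected
breadth-first from the optimum plateau up to `max_equal_trees` and
deduplicated by a canonical topology key.

Duplicate column patterns are collapsed into weights before scoring: a
bootstrap replicate is then just a reweighting, and the fixture's 95 loci
reduce to 14 distinct patterns.

**Rooting.** The search operates on rooted trees (Dollo scoring requires a
root); the returned trees are rerooted on the edge separating the outgroups
from the ingroup. If the outgroups are not monophyletic on the unrooted
topology, the tree is rooted above the largest pure-ingroup clade and flagged
— with insertion markers the outgroups carry no derived states, so a
non-monophyletic outgroup arrangement is itself evidence-free and harmless.

**Reported trees.** Internal edges to which no character gain maps are
collapsed in reported trees (`collapse_unsupported = TRUE` in the pipeline):
an edge with no insertion evidence and zero length is an artefact of binary
resolution, and reporting polytomies there is more faithful than picking one
of the many equally-best resolutions. This is why the pipeline reports a
single collapsed tree alongside the strict consensus of the equally-best set.

## Bootstrap

Characters are resampled with replacement (same locus count), the search is
rerun per replicate, and the rooted clades of the first best tree are
tallied. The consensus is majority-rule (> 0.5), built directly from the
tallied clades (clades above one half are pairwise compatible). Replicates
whose resample is degenerate (all constant) are recorded and skipped. The
whole procedure consumes randomness only through the resampling stream, so a
fixed seed reproduces the result byte for byte; the per-replicate search is
pinned to the deterministic addition order. The default is 1,000 replicates —
at that depth the binomial standard error of a 95% clade is 0.7 points, ample
for a desk-scale analysis; the published scale of 10,000 is one argument
away.

## The insertion likelihood test

Around an internal branch, three resolutions of the local trichotomy compete.
Under the null that each informative marker supports any of the three with
probability 1/3, the clean-support counts `(k, m, n)` are trinomial with
`N = k + m + n`. The test is exact: enumerate the trinomial sample space,
order outcomes by the one-sided likelihood-ratio statistic for the
**prespecified** focal resolution (alternatives pooled), and sum the
probability of outcomes at least as favourable. For unopposed support this
reduces to `p = (1/3)^k`, so a single unopposed marker gives `p = 1/3` (never
significant) and six give `p ≈ 0.0014` (significant at the 1% level) — which
is exactly the significance pattern of the lemur fixture: only the two
single-locus family pairings fail `p < 0.05`.

An **agnostic** variant (no prespecified resolution; unrestricted
likelihood-ratio ordering) is available behind the `variant` argument; it is
roughly three times more conservative when one resolution dominates, and the
two variants agree on every decision the fixture poses. We default to the
prespecified form because the branch being tested is always named in advance
by the reconstruction.

**What counts as a conflict.** A locus conflicts with a branch only when its
present-taxon set is *exactly* one of the two alternative unions of the local
trichotomy — such a locus would be loss-free under its own resolution. Any
other loss-requiring pattern is ambiguous and counts for nobody: with real
insertion data those patterns are, on sequencing, near-parallel independent
insertions or other indels rather than genuine homoplasy, and the screening
module's classifier plus `recode_near_parallel()` implement precisely that
resolution path.

## Screening stage

The in-silico screen mirrors the computational stage of a marker study:
parse RepeatMasker annotations (1-based inclusive coordinates, `C` mapped to
strand `−`), keep hits in the target subfamily set (default: families named
`AluL*`) that are **strictly longer than 280 bp** — near-full-length elements
make reliable PCR markers, truncated copies do not — and extract flanks for
primer design (default 50 bp, truncated at contig ends with a flag).
Filled/empty calling from product sizes uses a ±20 bp window by default and
refuses configurations where the two windows overlap. For confounding events
the positional tolerance for "nearly the same location" is 50 bp; the paper
trail behind a verdict (subfamily identity, insertion-point offset, TSD
compatibility) is returned with the call. These defaults are configuration
values, not biology: the thresholds a given study uses should be set
explicitly.

## Synthetic data and the fixture

`simulate_insertions()` draws insertions per branch from a Poisson law (mean
= rate × branch length) and inherits each by every descendant leaf — the
identity-by-descent model that makes these markers valuable. Confounders are
layered on top with per-column probabilities: excision (a descendant subtree
reverts), parallel insertion (a duplicate column on an independent branch),
incomplete lineage sorting (the column follows a discordant local
resolution), and missing data (cells become `?`). What the simulator does
*not* emulate: insertion-rate variation across lineages, subfamily structure,
correlated missingness by DNA quality, or locus ascertainment bias from
designing primers in one genome. Passing tests on simulated data therefore
certify the inference machinery, not the field protocol.

The lemur fixture is a reconstruction of a published 24-taxon matrix from the
per-clade locus counts printed in its running text: ten clades carrying
10/6/1/1/10/6/8/6/19/6 loci and four taxa carrying 3/2/16/1 private
insertions — 95 columns, 73 informative and 22 autapomorphic. Deliberate
choices: only counts printed in text are included, so nodes whose counts
appear only in a figure carry no fixture loci and the fixture tree has
polytomies there; the six loci excluding the aye-aye are modelled as present
in all 21 remaining lemurs (the text supports the placement, not the
per-taxon pattern); of the eight Indriidae-clade loci, the one whose position
the text leaves ambiguous is omitted and the six placeable ones are used. The
full published matrix had 138 loci (111 informative, 27 autapomorphic); those
totals are not reproducible from printed information, which is why the test
suite substitutes property-based checks (oracle equivalence, simulation
recovery, exact-test enumeration, bootstrap saturation) for them.

## Numerical choices and degenerate inputs

Integer step counts throughout; the C++ scorer uses a large-double infinity
with saturating sums, safe because any feasible column has a finite
gain-at-root reconstruction. Ties are never random: first-minimum child in
the reconstruction traceback, first attachment point in stepwise addition,
first improving neighbour in hill climbing, lexicographic clade keys in
tables. Degenerate inputs fail loudly: fewer than 4 taxa, all-constant
matrices ("no signal"), entirely-unknown columns (classified constant with a
warning), overlapping presence/absence windows, off-contig coordinates.
Seeds: every stochastic entry point takes one; derived seeds stay within
32-bit range.

## Problem sizes

The shipped analysis and tests run at desk scale by choice: the 24-taxon ×
95-locus fixture (search well under a second; 1,000 bootstrap replicates
about a minute), exact-search panels of 4–7 taxa, oracle sweeps over all 945
six-leaf topologies, a 9-taxon simulation study with 24 seeds per condition,
and trinomial enumeration to N = 8. All are chosen so the full suite runs
comfortably on one core.

## Known limitations

* Dollo only: no Fitch/Wagner characters, no likelihood models of sequence
  evolution, no branch lengths — topology and character mapping are the
  product, as is appropriate for insertion markers.
* The heuristic search offers NNI/SPR with restarts but no TBR and no
  simulated annealing; pathological matrices can in principle defeat it above
  the exact-search cutoff.
* The bootstrap consensus reports rooted clades; it assumes the outgroup
  rooting is itself stable, which holds when outgroups lack all markers.
* The screening stage consumes existing annotations; it does not reimplement
  RepeatMasker, BLAT or primer design, and orthology assessment expects
  precomputed alignment evidence.
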