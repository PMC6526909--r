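---
title: "Parsimony, stratigraphic congruence and paleodiversity with morphostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony, stratigraphic congruence and paleodiversity with morphostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphostrat)
```

morphostrat implements the classic paleobiological cladistics workflow for
discrete morphological matrices: maximum-parsimony tree estimation with
ensemble fit indices and resampling supports, ancestral-state
reconstruction under parsimony and the Mk model, stratigraphic-congruence
assessment with ghost-lineage time-scaling, and clade
diversity-through-time curves with radiation-pulse detection. This
vignette explains the models and conventions behind each stage, the
parameters that matter, and what the synthetic-data generator does and
does not emulate.

## The character matrix

A matrix holds, per taxon and character, a *state-set*: a single state, a
polymorphic/ambiguous set, or a missing entry. Missing (`?`) and
inapplicable (`-`) observations are both scored as the full state-set of
the character — the data say nothing, so no assignment may be penalized.
This equates the two codings deliberately: parsimony on unordered
characters cannot distinguish them without a model of applicability.
Alphabets are per character: the reader validates symbols against a
declared NEXUS `SYMBOLS` list when present, but each column's state count
is the set of symbols it actually uses (as Mesquite does). A consequence
worth knowing: a state that is declared but never observed does not
survive a round trip through a file, so missing-cell masks are defined
relative to the observed alphabet. Weights are per-character non-negative
numbers, default 1; the NEXUS writer records non-unit weights in an
`ASSUMPTIONS`/`WTSET` block that the reader understands.

## Parsimony scoring

`fitch_length()` computes unordered (Fitch) parsimony. Binary nodes use
the textbook intersection/union pass; polytomies are scored as *hard*
polytomies with Hartigan's generalization (per state, count the children
whose sets contain it; a node costs `children - max count`). Exactness,
including set-valued leaves from polymorphism and missing data, is tested
against a brute-force oracle that enumerates every internal-node
assignment on all trees with up to six tips.

Per-character bounds are `char_min_steps()` — the size of the smallest
set of states hitting every non-missing cell's state-set, minus one — and
`char_max_steps()` — the star-tree score: non-missing cells minus the
largest achievable single-state count. From observed steps `s`, minima
`m` and maxima `g`, `ensemble_indices()` reports

- CI = &Sigma;wm / &Sigma;ws (consistency),
- RI = (&Sigma;wg − &Sigma;ws) / (&Sigma;wg − &Sigma;wm) (retention),
- HI = 1 − CI, RC = CI × RI,

with parsimony-uninformative characters (g = m) dropped from the RI sums
to avoid 0/0; an all-constant matrix reports the indices as undefined
(`NA`) rather than 0/0. Printed values are rounded to three decimals
except RC, which is *truncated* — TNT's display convention, and the only
way the usual published triple (CI, RI, RC) is internally consistent.
`index_report()` builds the same object from published statistics, so the
remaining indices of a reported cladogram can be derived and checked
without the matrix.

`mpr_states()` returns most-parsimonious-reconstruction state-sets per
node via a two-pass 0/1-cost dynamic programme (minimum changes inside
and outside each subtree; a state is in the MPR set when the two sum to
the character's length). It requires a fully resolved tree; MPR sets on
polytomies are not well-defined in this framework and are rejected.

## Tree search

`search_mpt()` is a multi-start heuristic: seeded random-addition
starting trees (each taxon inserted where it adds the fewest steps),
hill-climbing with NNI, SPR or TBR neighbourhoods, and optionally the
parsimony ratchet (a seeded random fraction of characters — default 25% —
has its weight doubled, the tree is re-swapped, then re-swapped again
under the original weights, keeping improvements). Searches operate on
trees rooted at a fixed outgroup (default: the first matrix taxon);
unordered parsimony is rooting-invariant, so this is presentation only.
All distinct topologies found at the best length are kept, up to
`max_saved_trees`; topology identity is the set of clades. `ratchet()`
with zero iterations is exactly the hill-climbed start, and the search
log records each start's initial and final length, which must be
monotone within a climb.

The scorer behind the searches packs four characters per machine word
(7-bit fields, grouped by weight) so one Fitch pass scores four
characters at once, with branch-and-bound early abort against the current
best length; SPR hill-climbing runs in compiled code with a
first-improvement sweep. Scoring correctness of the packed path is
checked against the plain per-character scorer and against an independent
implementation (phangorn). Tree Fusing, Tree Drifting and Sectorial
Search — TNT's proprietary-grade heuristics — are not reimplemented; the
multi-start TBR/SPR + ratchet combination targets the same optima, which
is what the reported statistics depend on. On matrices of roughly the
study scale used in the demonstration pipeline (82 × 350), one SPR climb
takes seconds; exhaustive enumeration is used only as a test oracle (all
105 six-tip and 945 seven-tip topologies).

## Resampling support

`bootstrap_support()` resamples characters with replacement (implemented
as multinomial weights), reruns a reduced search per replicate (default:
5 random-addition starts, SPR, no ratchet), takes the replicate's strict
consensus, and reports for each reference clade the percentage of
replicate consensuses containing it. `symmetric_resampling()` perturbs
every character independently — weight to 0 with probability p/2, doubled
with probability p/2, unchanged otherwise (p defaults to 0.33) — and
additionally reports GC, the frequency difference between the group and
its best-supported contradictory group, in [−100, 100]. Two conventions
had to be fixed where the method's common descriptions are silent: each
replicate is summarized by the strict consensus of the trees it finds
(not the full tree set), and support attaches to the non-trivial groups
(2 to n−2 tips) of the reference tree, with other recovered groups
reported in a side table. At p = 0 every replicate reproduces the
original analysis, so GC is exactly 100 for every reference clade of a
conflict-free matrix — a boundary case the tests pin down.

## Mk ancestral states

The Mk(k) model is the equal-rates k-state Markov process with uniform
stationary and root distributions. With `rate` r substitutions per unit
branch length and per-pair rate r/(k−1), the transition probabilities
have the closed form P<sub>ii</sub>(t) = 1/k + (k−1)/k·e<sup>−k·r·t/(k−1)</sup>
(off-diagonals equal by symmetry); these match a matrix-exponential
oracle to 10<sup>−10</sup> in the tests. `mk_loglik()` is Felsenstein
pruning with per-node rescaling, vectorized across characters that share
a state count; by default each character uses its own alphabet size as k.
Missing tips carry a vector of ones and leave the likelihood of the rest
of the data untouched. `mk_marginal()` gives marginal posterior state
probabilities per node from the standard up/down pass. `mk_fit_rate()`
maximizes the summed log-likelihood over the rate by a coarse log-spaced
grid followed by golden-section refinement — the grid is needed because
the likelihood flattens at saturating rates, where golden-section search
alone can drift to the boundary. Only the product rate × branch length is
identifiable: doubling all branch lengths exactly halves the fitted rate.

Because a parsimony cladogram carries no branch lengths, ancestral-state
reconstruction on real data should use the branch durations from
`timescale()` (in Myr), or explicitly chosen equal lengths; the package
leaves this to the caller rather than guessing.

## Stratigraphic congruence and time-scaling

The Stratigraphic Consistency Index is the fraction of stratigraphically
consistent nodes among the non-root internal nodes; for a fully resolved
rooted tree of T tips the denominator is T − 2. A node is consistent when
the clade it subtends first appears no earlier than its sister lineage:
`clade_fad(node) <= clade_fad(sister)`, where a clade's FAD is the oldest
first appearance among its tips. Ties count as consistent under the
default; a strict variant is available (`strict = TRUE`), and matters in
practice when range truncation drives several FADs to a common bound. At
polytomies the oldest sister lineage is used and the denominator counts
the actual non-root internal nodes (with a warning, since the T − 2
convention presumes full resolution). A partition SCI (e.g. one family
within a larger analysis) is the SCI of the subtree rooted at the named
tips' most recent common ancestor.

`timescale()` performs minimum-age scaling: every internal node is as old
as its oldest descendant first appearance, computed bottom-up, with an
optional `min_branch` duration pushing parents older. Each branch then
carries a *ghost* duration — the gap between the lineage's origin (its
parent's age) and its first evidence: the tip's FAD on terminal branches,
the child's age on internal ones. Under minimum-age scaling an internal
branch is therefore entirely inferred (ghost) duration; only terminal
branches can have zero ghost, which they do exactly when preservation is
perfect. Exact recovery of true node ages is only guaranteed on trees in
which every internal node has a terminal child originating at it
(pectinate trees); on balanced topologies minimum-age scaling is, as
always, a lower bound on node ages.

## Diversity through time

Every branch of a time-scaled tree is a lineage segment from the parent's
age to the tip's last appearance (terminal branches; first appearance
optionally, for FAD-only counting) or the child's age (internal
branches). `lineage_count()` counts segments crossing a time point;
`diversity_curve()` counts, per half-open bin [t<sub>old</sub>,
t<sub>young</sub>), the distinct segments intersecting it, once each
regardless of overlap. Zero-length internal segments (simultaneous node
ages from minimum-age scaling) are cladogenesis points, not lineages, and
are dropped; zero-length terminal segments (point occurrences) are kept.
Clade subsets are tip sets: a branch belongs to the subset when all its
descendant tips do, and `exclude` removes the branches lying fully inside
the excluded clade (stem included). With this rule a clade and its
complement partition the branches exactly, so their curves add up to the
whole — a conservation law the tests enforce on random trees. The default
bin width is 1 Myr; analyses of the demonstration pipeline span the last
40 Myr.

`detect_pulses()` formalizes what is usually read off the plot: scanning
oldest-first, maximal non-decreasing runs of counts are cut into windows
of span at most `max_span` (default 3 Myr), and windows with total rise
at least `min_rise` (default 3 lineages) become events, reported oldest
first. Published radiation events are typically identified visually, so
these thresholds are exposed configuration, not biology.

## Synthetic data and what passing tests mean

`simulate_yule_tree()` grows a pure-birth tree forward from two lineages
(waiting time Exp(n·&lambda;) at n lineages, plus a final Exp(n·&lambda;)
hold), so the expected root age is &Sigma;<sub>k=2..n</sub> 1/(k&lambda;)
— the closed form the generator is tested against. A `ladder` option
always splits the youngest lineage, producing the pectinate shape on
which minimum-age scaling is exact. `simulate_mk_matrix()` evolves each
character down the tree with the closed-form transition probabilities and
masks a configurable fraction of tip cells; `simulate_fossil_ranges()`
either records each tip lineage from its true origin (perfect
preservation) or delays first appearances by exponential gaps with mean
1/q Myr. A single seed fans out deterministically into per-stage
sub-streams, so every stage is independently reproducible.

The study-scale defaults in `simulate_dataset()` — 82 taxa, 350 mostly
binary characters (state counts 2–6 with probabilities 0.6, 0.2, 0.1,
0.05, 0.05), 30% missing data, speciation rate 0.11/lineage/Myr (root age
around 35–40 Ma), substitution rate 0.02/Myr (a heavily homoplastic
regime, ensemble CI near 0.3), and mean first-appearance gaps of 3 Myr —
were chosen once to emulate a large fossil-mysticete-type analysis and
are not tuned per experiment. The generator emulates tree shape, state
frequencies, missingness and preservation gaps; it does **not** emulate
correlated characters, ordered or weighted character regimes,
heterogeneous rates across characters or time, anatomical-module
structure, or non-random missingness (fossils missing whole body
regions). Passing tests therefore show the algorithms are correct and
the pipeline is deterministic — not that real matrices of this size are
free of search difficulties or that their supports behave like the
simulated ones.

Two saturation effects in the simulation are worth knowing. First, when
preservation gaps grow so large that most ranges truncate at the present,
FADs tie at 0 and the (&le;) consistency criterion counts the ties as
consistent, so the SCI rebounds; monotone degradation of mean SCI with
thinning holds in the regime where gaps stay below the typical branch
spacing, and the tests probe exactly that regime (gap means 0.05–1 Myr
against roughly 0.4–5 Myr branches). Second, recovering a generating
topology from simulated characters requires every internal branch to have
acquired at least one change — at low rates short branches often have
none, which is a property of the data, not the search.

## Numerical and reproducibility choices

Lengths and weights are compared with a 10<sup>−9</sup> tolerance
(weights may be non-integer after resampling). Tie-breaking is
deterministic everywhere: stepwise addition keeps the first best
insertion point in node order, hill-climbing accepts the first improving
move in a fixed sweep order, and equally parsimonious topologies are
deduplicated by sorted clade keys. Likelihood pruning rescales partial
likelihoods at every node and accumulates the log factors, so hundreds of
taxa do not underflow. The pipeline driver (`run_pipeline()`) writes
every stage's outputs before the next stage starts, derives each
stochastic stage's seed from the master seed by a documented hash, and
ends with a manifest of MD5 checksums; a rerun with the same
configuration is byte-identical, which the acceptance checks verify on
the study-scale preset. The preset's demonstration settings (2
random-addition starts, SPR with 3 ratchet cycles, 8 symmetric-resampling
replicates) keep the worked example interactive; production analyses
should scale the search and the replicate counts (the original-scale
choice would be 1,000 bootstrap and 100 symmetric replicates) through the
same configuration.

## Known limitations

Ordered, irreversible and step-matrix characters are out of scope (all
characters are unordered), as are implied weighting, Bremer supports,
other stratigraphic-fit metrics (RCI, GER, MSM*), gamma rate
heterogeneity and asymmetric Mk variants, and birth–death rate
estimation from the diversity curves. The NEXUS reader covers
DATA/CHARACTERS blocks with the usual FORMAT options and a WTSET command;
exotic ASSUMPTIONS content is ignored. Alphabets are capped at 31 states
(bitmask representation), and the packed search scorer at 6 states per
character — beyond that, scoring still works through the per-character
path but searches refuse the matrix.
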