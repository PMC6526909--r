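# morphostrat

Parsimony phylogenetics, stratigraphic congruence and paleodiversity for
discrete morphological character data.

Paleobiological studies of fossil-rich clades routinely run one workflow:
score a taxa × characters morphological matrix, search for the most
parsimonious cladograms, report ensemble fit indices and resampling
supports, reconstruct ancestral states, confront the tree with the
stratigraphic record, and count lineages through time to find radiation
pulses. The individual pieces live in different programs (TNT, Mesquite,
spreadsheets); morphostrat implements the whole chain as one tested,
scriptable R package, for systematists and paleobiologists who want the
published numbers to be reproducible from a single seed.

## What it computes

* **Fitch parsimony** on unordered multistate characters (missing `?` and
  inapplicable `-` scored as full state-sets, polymorphisms as sets),
  with Hartigan's generalization on polytomies; per-character minimum
  (m) and maximum (g) steps; ensemble indices
  CI = Σwm/Σws, RI = (Σwg−Σws)/(Σwg−Σwm), HI = 1−CI, RC = CI·RI
  (uninformative characters excluded from RI; RC truncated for display,
  following TNT).
* **Heuristic tree search**: seeded random-addition starts, NNI/SPR/TBR
  hill-climbing (SPR in compiled code with bit-packed scoring and
  branch-and-bound), the parsimony ratchet, and strict consensus of all
  equally parsimonious topologies found.
* **Clade support**: nonparametric bootstrap and Goloboff-style symmetric
  resampling (weight → 0 or 2w, each with probability p/2; default
  p = 0.33) with frequency-difference (GC) output.
* **Ancestral states**: most-parsimonious-reconstruction state-sets (MPR)
  and marginal posteriors under the Mk(k) equal-rates model, including
  maximum-likelihood rate fitting.
* **Stratigraphic congruence**: the Stratigraphic Consistency Index
  SCI = (consistent nodes)/(total nodes), where a node is consistent when
  its clade's oldest first appearance is no older than its sister's and
  the denominator is tips − 2 on a resolved tree; minimum-age
  time-scaling with per-branch ghost-lineage durations.
* **Paleodiversity**: lineage-through-time curves per clade subset
  (observed ranges plus inferred ghost segments, binned per Myr) and
  threshold-based detection of diversity pulses.
* **Synthetic data with ground truth**: Yule trees (random or pectinate),
  Mk-evolved matrices, and fossil ranges under perfect or exponentially
  thinned preservation, all reproducible from one seed.
* **Pipeline driver**: `run_pipeline()` executes
  data → search → consensus → support → SCI/time-scaling → diversity from
  one config (R list or YAML) and writes a manifest with MD5 checksums;
  reruns are byte-identical. A thin command-line wrapper lives at
  `inst/cli/morphostrat.R`.

## Worked example

```r
library(morphostrat)

## a study-scale simulation, scaled down: 20 taxa, 80 characters,
## 30% missing, fossil ranges with exponential preservation gaps
sim <- simulate_dataset(seed = 42, n_tips = 20, n_chars = 80)
sim$matrix
#> Morphological character matrix: 20 taxa x 80 characters
#>   states per character: 2 - 6 ; missing cells: 30.4%

res <- search_mpt(sim$matrix, search_config(n_starts = 3, swap = "spr",
                                            ratchet_iterations = 3,
                                            seed = 42))
res
#> Maximum-parsimony search
#>   best length found: 175 steps
#>   equally parsimonious distinct topologies kept: 2
#>   starts: 3 (spr swapping, 3 ratchet cycles)

ensemble_indices(res$trees[[1]], sim$matrix)
#> Parsimony index report
#>   tree length: 175 steps
#>   CI = 0.577  RI = 0.639  HI = 0.423  RC = 0.368
#>   per-character table available ($per_char)

sci(res$trees[[1]], sim$ages)
#> Stratigraphic Consistency Index: 7/18 = 0.39

ts <- timescale(res$trees[[1]], sim$ages)
ts
#> Time-scaled tree: 20 tips, root at 8.54 Ma
#>   total ghost-lineage duration: 72.67 Myr

curve <- diversity_curve(ts, bin_width = 1)
detect_pulses(curve, min_rise = 2, max_span = 3)
#>   start end rise   label
#> 1     7   6    3 event_1
#> 2     5   3    6 event_2
#> 3     1   0    4 event_3
```

Reading: the best trees found need 175 steps; a consistency index of
0.577 says the average character changes 1/0.577 ≈ 1.7 times more often
than its theoretical minimum (homoplasy). Only 7 of the 18 non-root
internal nodes appear in the stratigraphically expected order — the 72.7
Myr of ghost lineage implied by minimum-age time-scaling quantifies the
same mismatch. The diversity curve counts both observed ranges and those
ghost segments per 1-Myr bin; three windows show a rise of at least 2
lineages within 3 Myr and are flagged as candidate radiation pulses.

Real data enter through `read_char_matrix()` (NEXUS or TNT `xread`),
`read_trees()` (Newick/NEXUS) and `read_ages()` (CSV `taxon,fad,lad`, in
Ma), and the whole chain can be driven from one file:
`run_pipeline("run.yaml")`.

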