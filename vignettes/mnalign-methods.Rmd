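---
title: "Aligning multiple PPI networks with mnalign: model and methods"
author: "mnalign maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning multiple PPI networks with mnalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnalign)
```

## The problem

Protein–protein interaction (PPI) networks for different species describe
partially conserved machinery: groups of proteins that descend from a
common ancestor often retain both their sequences and their interactions.
A *global multiple network alignment* summarizes this conservation as a
set of mutually disjoint **match-sets** — groups of proteins, possibly
several per species, asserted to be functional orthologs. Two competing
quantities measure the quality of an alignment Ŝ:

* the **weighted average similarity**
  `Σ_i |S_i|·sim(S_i) / Σ_i |S_i|`, where `sim(S_i)` averages the raw
  cross-network similarity over all unordered pairs in `S_i` (within-network
  pairs score 0 by construction, so multi-network match-sets are favoured);
* the **number of conserved edges**: an interaction `(x, y)` of network i
  is conserved when another network contains an interaction `(x', y')`
  with `S(x') = S(x)` and `S(y') = S(y)`, or when `x` and `y` are in the
  same match-set. A *strictly* conserved edge additionally has
  `sim(x, x') > 0` and `sim(y, y') > 0` for some witness.

Joint optimization of both is NP-hard already for two networks (it is a
binary quadratic program), so `mnalign` treats the two goals in sequence:
similarity drives clustering and seed selection, topology drives the
expansion that actually forms the match-sets.

## The pipeline

### Preprocessing (topology into similarity)

For every stored pair `(a, b)` an *extra score* is computed by greedily
matching neighbours: repeatedly pick the unused neighbour pair
`(a', b')`, `a' ∈ N(a)`, `b' ∈ N(b)`, with maximal similarity, add
`sim(a', b')`, and retire both proteins, until either neighbourhood is
exhausted. The extra score is capped at the original score before being
added, so preprocessed scores lie in `[sim, 2·sim]` and the support of the
matrix never grows — a pair without sequence evidence can never be
promoted by topology alone. The greedy matching is used exactly as
stated rather than an optimal assignment: it is the documented rule, it is
cheap (`O(d² log d)` per pair), and on sparse PPI-like graphs the two
rarely differ. Ties between equal-similarity neighbour pairs are broken by
the lexicographically smallest pair, which keeps the extra score symmetric
in its arguments.

All *decisions* downstream (clustering, the seed threshold τ, queue
priorities, the merging criterion) use the preprocessed matrix; all
*reported metrics* use the raw matrix. This split is forced by the worked
example in the package documentation: the expansion order follows
preprocessed scores, yet the final average similarity of the result is
85/3 on raw scores.

### Clustering

Proteins with at least one nonzero similarity entry are partitioned into
`m = max(1, ⌊n_sim / k⌋)` clusters (overridable). Two criterion functions
are supported, over unordered distinct pairs:

* `I1 = Σ_i (1/n_i) Σ_{u,v ∈ C_i} sim(u, v)` (default — it mirrors the
  per-match-set average similarity that the evaluation rewards),
* `I2 = Σ_i Σ_{u,v ∈ C_i} sim(u, v)`.

The optimizer is greedy agglomerative: start from singletons and repeatedly
perform the merge with the greatest criterion gain (gains may be negative
once good merges are exhausted) until `m` clusters remain. Merges are
restricted to cluster pairs connected by at least one similarity entry
whenever any such pair exists; gain ties fall back to the
lexicographically smallest pair of cluster labels. The implementation
keeps cross-cluster similarity sums incrementally and is tested against a
from-scratch oracle that re-evaluates the criterion of every candidate
partition at every step. The reference clustering tool the procedure is
modelled on is an external native program; re-implementing the greedy
optimization of the same criteria removes that dependency, at the cost
that merge schedules on data other than the packaged examples need not
coincide with that tool's.

The unordered-pairs reading of the criterion sums, and clustering on the
preprocessed matrix, are the two readings that reproduce the worked
example's clustering `{{A1, B1}, {A2, B2, B3}, {A3, B4}}`; both are
validated in the test suite (on this instance raw scores happen to give
the same partition).

### Seeds, expansion, and the merging criterion

Within each cluster, every cross-network pair scoring at least τ becomes a
seed. Seeds enter a max-priority queue; two phases follow:

1. all seeds are popped in descending score order and offered to the
   merging criterion (multi-network seed unions form here);
2. for every ≥2-member match-set, all cross-network pairs of unaligned
   neighbours of its cross-network member pairs are pushed; popping a pair
   that the criterion merges pushes the unaligned-neighbour pairs of the
   merged pair in turn. Queue entries whose proteins already share a
   match-set are skipped at pop time.

The criterion for merging `S(v_i)` and `S(v_j)`, with parameters
`(β, ρ, ω)`:

* **size gate** — reject if `|S(v_i)| + |S(v_j)| > ω·|Net(union)|`:
  a match-set should not carry many more proteins than species it spans;
* `maxSim` — the maximal decision score among all pairs in the union;
* `count` — the number of cross-set pairs scoring above `maxSim·β`;
* `expandRatio` — `|Net(union)| / max(|Net(S(v_i))|, |Net(S(v_j))|)`,
  favouring merges that reach new species;
* merge iff `maxSim > 0` and `count·expandRatio ≥ |S(v_i)|·|S(v_j)|·ρ`.

Finally, pairs of proteins that are both still unaligned and have positive
decision score are processed in descending score order under the same
criterion (stage 4). Match-sets that remain singletons are dropped;
uncovered proteins are reported in the `.unaligned` sidecar written next
to alignment files, since downstream users usually want that list and the
alignment format itself has no place for it.

### Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| τ (`tau`) | 0.1 | decision-score units | seed admission threshold; higher τ → fewer seeds, more topology-driven alignment, lower average similarity. 0.1–0.5 suits normalized BLAST scores in [0, 1]; tens–hundreds suit raw bit scores. |
| β (`beta`) | 0.1 | (0, 1] | a cross-set pair "counts" when it scores above β·maxSim; larger β demands more uniformly similar sets. |
| ρ (`rho`) | 0.5 | (0, 1] | minimal counted-pair density; ρ > 0.5 with k = 2 provably caps match-sets at two proteins (pairwise mode). |
| ω (`omega`) | 2.5 | proteins per network | size gate; suggested range 1.5–2.5. |
| criterion | I1 | — | clustering criterion; I1 tracks average-similarity quality. |

`(β, ρ, ω) = (0.1, 0.5, 2.5)` are the method's suggested defaults and are
used everywhere unless noted.

## Numerical and design choices

* **Tie-breaks.** Queue priorities tie only among equal scores (in
  practice, zero-score neighbour pairs). Ties pop most-recently-pushed
  first (LIFO) over a deterministic lexicographic push order; stage-4 and
  seed orderings break score ties lexicographically. All orderings are
  documented so runs are reproducible and invariant to input row order.
* **Zero-similarity singleton merges.** During expansion the criterion
  always merges two singleton match-sets that pass the size gate, even at
  similarity zero — the expansion stage's stated behaviour, and the only
  reading under which the no-preprocessing worked example (which aligns a
  zero-similarity pair) comes out. The `maxSim > 0` gate still governs all
  non-singleton merges, and stage 4 never considers zero-score pairs. The
  flag `mergeZeroSimSingletons` disables the exception.
* **Duplicate similarity rows** keep the maximum (BLAST tables typically
  contain both query/subject directions); self pairs, zero scores and
  within-network pairs are dropped on ingest.
* **Namespacing.** If any raw protein id occurs in two input networks, all
  ids are namespaced `network::id` so vertex sets stay disjoint; raw ids
  are restored on output when unambiguous.
* **Hypergeometric enrichment** uses the upper cumulative tail with the
  background `N` equal to the total protein count of all networks
  (unannotated proteins count towards `N − M`), no multiple-testing
  correction, and a fixed `p < 10⁻⁴` enrichment cut. `stats::phyper`
  supplies a numerically stable implementation; the suite cross-checks it
  against direct combinatorial summation for every tuple with `N ≤ 25`.
* **Pairwise baseline.** The maximum-weight bipartite matching between two
  vertex sets (via `igraph`) gives the similarity-optimal one-to-one
  alignment; zero-score matches are dropped. Note that it maximizes
  *total* similarity — a partial alignment that keeps only its best pair
  can exceed its *average* — so the dominance property tested is on
  totals.
* **Degenerate inputs.** Empty similarity matrices raise
  ("no alignable proteins"); `m` larger than the protein count returns
  singletons with a warning; empty alignments are valid objects that read
  and write as empty files.

## The synthetic generator

`generatePlanted()` emulates what the aligner assumes, not real
interactomes: an Erdős–Rényi ancestor `G(n0, pEdge)` is copied into k
networks with independent per-copy edge deletion (rate `pDel`); copies of
one ancestor protein form a ground-truth ortholog group; group pairs score
`simSignal` ± uniform jitter and spurious cross-network pairs appear at
rate `noiseRate` with scores in `(0, noiseMax]`. Defaults
(`k = 2, n0 = 50, pEdge = 0.1, pDel = 0.1, simSignal = 1,
simJitter = 0.1, noiseRate = 0.01, noiseMax = 0.3`) describe an "easy"
regime: signal and noise scores are separated, and every ortholog pair
carries signal. Passing recovery tests on such instances demonstrates that
the machinery is implemented correctly — *not* that the method attains any
particular accuracy on real PPI data, whose degree distributions are
heavy-tailed, whose similarity matrices mix paralog families, and whose
interaction coverage is biased in ways this model does not attempt.
`plantedRecovery()` scores pair-level precision/recall/F1 against the
planted groups.

## Problem sizes

The packaged examples and tests run on deliberately small instances: the
seven-protein worked example; random oracle instances of 10–18 proteins
(where `O(|E|²)` brute-force conservation checks, exhaustive assignment
enumeration up to 7×7 and full-recomputation clustering oracles are
feasible); and planted instances of 50–80 ancestor proteins per network.
These sizes exercise every code path while keeping the whole suite around
ten seconds. The algorithm itself is designed for networks of thousands of
proteins (its dominant cost is the `O(n² log n)` clustering stage, run
once per dataset even when sweeping τ via `alignSweep()`); the dense
cross-cluster bookkeeping in the clustering step is the first thing to
revisit for inputs beyond ~10⁴ similarity-bearing proteins.

## Known limitations

* Edge weights (interaction confidences) are ignored; networks are
  unweighted and undirected.
* The agglomerative optimizer is greedy; it matches a step-wise optimal
  oracle but carries no global optimality guarantee.
* The pairwise baseline is defined for exactly two networks.
* GO terms are opaque strings: no ontology traversal, ancestor
  propagation, or FDR control.
* BLAST/Pfam scoring itself is out of scope; similarity tables are
  consumed as given.
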