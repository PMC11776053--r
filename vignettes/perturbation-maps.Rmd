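---
title: "Planning perturbation maps with intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning perturbation maps with intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemap)
```

## The planning problem

Relative binding FEP estimates the binding free-energy difference between
two ligands by alchemically transforming one into the other inside the
binding site. The transformation converges only when it is chemically
small; a pair differing by entire rings must be routed through intermediate
compounds, each consecutive pair differing by a few atoms. Beyond making
each step small, a useful plan keeps the route between the two ligands of
interest *short* (errors accumulate along the route) and keeps every
critical edge on a *thermodynamic cycle* (the free energies around a closed
loop must sum to zero, so cycles expose simulation errors; an edge on no
cycle — a bridge — cannot be checked at all). `alchemap` automates this
planning: it never runs simulations, it decides which ones are worth
running.

## Molecular model and its assumptions

Molecules are hydrogen-suppressed, kekulized graphs with formal charges;
every heavy-atom count in the scoring formula excludes hydrogens.
Parsing, canonicalization and format I/O are delegated to Open Babel
(`ChemmineOB`); every parsed molecule is rebuilt from its canonical SMILES,
which gives two properties the algorithms rely on:

* the canonical SMILES is a structure key — equal keys mean the same
  constitution, which drives all deduplication;
* atom indices are canonical, so index-wise lexicographic tie-breaking in
  the MCS search is reproducible regardless of input atom order.

Open Babel is deliberately permissive about valence, so chemical sanity of
edited structures is enforced in-package with a valence-cap table
(e.g. C ≤ 4 − |q|, N ≤ 3 + q, O ≤ 2 + q). 3D geometry, conformers,
tautomers and binding poses are out of scope: planning is purely
topological.

Protonation is handled by a small deterministic rule table meant to mimic
the dominant microstates at pH 7.4: carboxylic/sulfonic acid hydroxyls are
deprotonated and aliphatic non-conjugated amines are protonated, while
explicit input charges are preserved. A commercial preparation tool may
assign different absolute states; what matters for planning is that both
inputs and all intermediates share one net charge (charge-changing
intermediates are discarded during generation, as charge perturbations need
special simulation treatment).

## The maximum common substructure

The MCS drives both scoring and generation. The implementation is a
connected, *induced* common-subgraph search (McGregor-style backtracking
with a size bound):

* atom compatibility ignores element identity when mismatch tolerance is on
  (the default); mismatched pairs are recorded and later repaired in place
  by the mutation edit rather than by deletion/insertion;
* bonds match irrespective of order — alchemical transformations routinely
  change bond order — but a ring bond may only map to a ring bond, so the
  common core never tears a ring open;
* among maximum mappings the search keeps the one with the fewest element
  mismatches, then the lexicographically smallest pair list.

The search is exact for the molecule sizes this package targets (tens of
heavy atoms); a node cap and a wall-clock budget (default 10 s per pair)
return the best mapping found so far with a `timed_out` flag in
pathological cases. Note one consequence of the ring-bond rule worth
knowing when checking scores by hand: naphthalene and biphenyl share only a
6-atom core, because biphenyl's inter-ring bond is acyclic and may not map
onto a ring bond.

## Intermediate generation

Generation edits the start compound toward the core it shares with the
target. An atom is *settled* when it is mapped and already agrees with its
target partner in element and charge. One edit is any of:

* **a** — mutate a mapped, unsettled atom to its target element/charge;
* **b** — delete one unsettled acyclic atom (connectivity preserved);
* **c/d** — delete a fully unsettled ring system attached by a single
  bond, capping with hydrogen (c) or a methyl carbon (d);
* **e** — peel one chordless ring off a fused system by deleting its
  exclusive unmapped atoms, then restore an alternating double-bond pattern
  over the remaining formerly-aromatic atoms (edits whose remainder cannot
  be kekulized are discarded).

Treating *mismatched* core atoms as deletable (not only strictly non-core
atoms) matters: with mismatch-tolerant MCS the biphenyl/phenol core
includes a carbon↔oxygen pair, and only the unsettled reading generates
both benzene and toluene as intermediates. Peeling fused rings one at a
time (rather than deleting the whole non-core portion at once) is what
creates mid-sized stepping stones for multi-ring differences — a tricyclic
outlier sheds one ring per step.

A LIFO compound pool with a global canonical-key visited set closes the
edit relation; termination is guaranteed because every edit strictly
reduces the count of unsettled atoms (the methyl cap of d adds one atom
that procedure b later removes, still a net decrease per ring). Safety caps
(50 000 pops, 10 000 candidates per direction) guard against combinatorial
inputs. Generation runs in both directions (A toward B's core, B toward
A's) and the union is deduplicated.

## Scores, the optimal path, and the map

* Link score: `S_e = exp(-beta * (N_A + N_B - 2 N_MCS))`, `beta = 0.1`.
  Only inserted/deleted atoms are penalized; in-place mutations are free at
  the scoring level, which is exactly why the MCS tolerates mismatches.
* Path score: `S_P = 1 / sum(1 / S_e^2)`, the harmonic mean of squared link
  scores divided by path length. The implementation uses the reduced form;
  the test suite asserts the algebraic identity against the expanded one.

The optimal path maximizes `S_P` over all simple paths with every
`S_e >= min_score` and at most `max_dist` edges, found by exhaustive
depth-bounded enumeration (candidate graphs have tens of nodes and
`max_dist <= 4`, so enumeration is cheap and certifiably optimal). Ties are
broken by shorter length, then higher worst link, then lexicographic node
ids. When no qualifying path exists the search raises a typed error
carrying the best-effort path that maximizes the worst link instead,
explicitly flagged `fallback` — an infeasible request is never silently
downgraded.

Map construction prunes candidate edges below `prune_threshold`, then
attempts removals worst-first (ties: lexicographic endpoint pair). A
removal survives when every optimal link is still present and still lies on
a cycle of at most `max_cycle` edges; links for which the *pruned* graph
never offered such a cycle are exempt from the cycle test but flagged in
the constraint report and in the map's warnings. Because removals never
create cycles, a single pass is already a fixpoint (each rejected removal
stays rejected), and the result is locally minimal. The corridor
restriction — keep only nodes on simple A–B paths within
`max_subgraph_dist` — is applied once at finalization by default; applying
it after every kept removal is available as `subgraph_mode = "during"`
(which reading of "after removal" is intended is genuinely ambiguous; both
finish through the same finalization pass, and the extraction is reverted
whenever it would break a constraint).

## Congeneric-series mode

The base map over series members is Lomap-style worst-first removal under
three constraints: the member graph stays connected, every member stays
within `base_dmax = 6` links of every other, and each retained edge keeps a
cycle of at most `max_cycle` edges whenever the full graph offered one.
These base settings are this package's own defaults for a "usual" Lomap
build. Member–member edges scoring below `series_threshold` then receive
optimal intermediate paths (pair machinery, deduplicated injection), the
map is rebuilt incrementally — only edges incident to new intermediates are
added, existing member–member decisions stand — with connectivity, distance
and cyclicity *not* checked for intermediates, and intermediates that end
up disconnected or as cycle-free leaves are pruned to a fixpoint. The loop
repeats until no member–member edge is below threshold, a pair is marked
unfixable (its direct link is kept and flagged), or the iteration cap
(default 5) is reached; remaining bad edges are reported in the map's
warnings, never dropped silently.

## Parameters

| parameter           | default | role |
|---------------------|--------:|------|
| `beta`              | 0.1     | link-score scaling per inserted/deleted heavy atom (dimensionless) |
| `min_score`         | 0.5     | lowest admissible link on the optimal path |
| `prune_threshold`   | 0.2     | lowest link kept in the map's candidate graph |
| `max_dist`          | 3       | optimal-path length cap (edges) |
| `max_cycle`         | 4       | largest admissible protecting cycle (edges) |
| `max_subgraph_dist` | 4       | A–B corridor path-length cap (edges) |
| `series_threshold`  | 0.6     | member link score below which intermediates are injected |
| `base_dmax`         | 6       | member–member distance cap in the base map |
| `mcs_timeout`       | 10 s    | per-pair MCS search budget |

The first six mirror the reference workflow this planner implements;
raising `max_dist` buys better worst links at the price of longer routes
(more error accumulation), and `max_cycle`/`max_subgraph_dist` bound the
extra simulation cost spent on redundancy.

## The toy fixtures, and what the tests do and do not show

`make_congeneric_series()` builds the deterministic series used throughout
the tests: benzene-scaffold analogues (H, methyl, hydroxyl, chloro — all
pairwise link scores ≥ 0.8 since single-atom substituents either map or
cost ≤ 1 atom) plus one distant member, a hydroxymethyl-anthracene
(16 heavy atoms) whose two extra fused rings put it 10 inserted/deleted
atoms from benzene: link score exp(−1) ≈ 0.37, the regime where injection
is mandatory. `make_scored_graph()` produces seeded abstract scored graphs
that bypass chemistry entirely, so the path and map algorithms are tested
against brute-force oracles on hundreds of topologies.

These fixtures exercise every code path but are not drug-like: real series
have larger, decorated, heteroatom-rich molecules, stereochemistry, and
charge diversity. Passing tests demonstrate algorithmic correctness
(oracle equivalence, invariants, determinism), not that the planner's
scores predict actual FEP convergence — link scores are a topological
proxy and deliberately ignore simulation physics. Problem sizes in the
suite were chosen to keep oracles exact: molecules of ≤ 16 heavy atoms,
50 path-search graphs of ≤ 12 nodes, 30 map-construction graphs of
≤ 8 nodes.

## Numerical and degenerate-input choices

* Scores are exact doubles; no rounding anywhere in the pipeline, and
  score ties are always broken lexicographically on node ids, so repeated
  runs are byte-identical.
* Identical inputs collapse to a single node (a zero-length "path" request
  between one compound and itself is rejected).
* A pair with different net charges is a hard error before any generation.
* Disconnected input molecules are rejected at parse time; edits that
  would disconnect a molecule, break a valence cap, or fail
  canonicalization are discarded (the generator logs nothing for them —
  they are not chemistry).
* A bare-path map with no possible cycle returns with every optimal link
  flagged infeasible and a warning, never a silent pass.

## Known limitations

* No charge-changing intermediates: pairs must share a net charge.
* The MCS is connected-only and ring-strict; disconnected common cores
  (two matched fragments joined differently) are not found.
* Re-kekulization after ring peeling handles benzenoid and simple
  heteroaromatic remainders; exotic aromatic systems may cause an edit to
  be discarded rather than repaired.
* Protonation rules cover the two dominant ionizable groups only.
* Link scores do not model simulation difficulty beyond atom counts
  (no softcore/topology considerations, no per-target calibration).
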