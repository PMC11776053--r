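# alchemap

Planning tool for relative binding free-energy (RBFE / FEP) campaigns.

When two ligands in a lead-optimization series differ by whole rings or
scaffold pieces, the direct alchemical transformation between them is too
large for an FEP simulation to converge. `alchemap` plans such calculations
for computational chemists: it invents the *intermediate* compounds that
break a large transformation into small steps, picks the best sequence of
steps, and assembles a *perturbation map* — a graph of planned FEP
calculations — in which every critical transformation sits on a small
thermodynamic cycle so that cycle-closure errors stay detectable.

## Method

For a compound pair the pipeline is:

1. **Exhaustive intermediate generation.** Compute the maximum common
   substructure (MCS) of ligands A and B, tolerating atom-type mismatches.
   Edit A toward the common core one chemical step at a time — mutate a
   mismatched core atom (a), delete an acyclic side atom (b), delete a
   pendant ring capping with H (c) or methyl (d), or peel one ring off a
   fused system (e) — collecting every distinct product in a compound pool
   until it is exhausted, then repeat from B. Intermediates whose net charge
   differs from the inputs are discarded.
2. **Link scores.** Each candidate transformation (edge) *e* between
   compounds with N_A and N_B heavy atoms and an MCS of N_MCS atoms gets

       S_e = exp(-beta * (N_A + N_B - 2 * N_MCS)),    beta = 0.1

   the exponential of the number of atoms inserted or deleted; S_e is 1
   exactly for identical compounds.
3. **Optimal intermediate path.** A path P from A to B is scored by

       S_P = 1 / sum_e (1 / S_e^2)

   (the harmonic mean of the squared link scores divided by the path
   length). Among all simple paths with every S_e >= MIN_SCORE and at most
   MAX_DIST edges, the path with the highest S_P wins.
4. **Perturbation map.** Starting from the pruned candidate graph, edges are
   removed worst-first; a removal is kept only while every optimal link is
   retained and stays on a cycle of at most MAX_CYCLE edges. The map is
   finally restricted to the corridor of A–B paths within
   MAX_SUBGRAPH_DIST, discarding unused intermediates.

For a congeneric series, a Lomap-style map over the members is built first;
every member–member link scoring below a threshold (default 0.6) then gets
an optimal intermediate path injected, the map is rebuilt with constraints
relaxed for intermediates, and pendant or disconnected intermediates are
pruned — repeating until no planned member–member transformation is below
threshold.

## Worked example

Biphenyl to phenol — a ring deletion plus an atom mutation:

```r
library(alchemap)

link_score("c1ccc(-c2ccccc2)cc1", "Oc1ccccc1")
#> <link_score> 0.6065  (N_A=12, N_B=7, N_MCS=7, beta=0.1)

gen <- exhaustive_generate("c1ccc(-c2ccccc2)cc1", "Oc1ccccc1")
gen
#> <generation_result> 4 compounds (2 intermediates) between A and B
#>   per procedure: a=0 b=0 c=1 d=1 e=0
```

The generator finds benzene (ring deleted, procedure c) and toluene (ring
replaced by methyl, procedure d) as intermediates. Five atoms separate the
inputs from their 7-atom common core, so the direct link scores
exp(-0.1·5) = 0.6065; it clears MIN_SCORE = 0.5, so the optimal path is the
direct edge, and the map builder closes a cycle over it with one
intermediate:

```r
cg   <- candidate_graph(gen)
path <- find_optimal_path(cg, "A", "B", min_score = 0.5, max_dist = 3)
path
#> <xform_path> A - B  (score 0.3679, worst link 0.6065, length 1)

map <- build_pair_map(cg, path, run_config())
map_statistics(map)
#> $worst_link_score        0.6065
#> $ab_distance             1
#> $n_intermediates         1
#> $n_links                 3
#> $optimal_path_has_bridge FALSE
```

Three planned FEP links (A–B, A–X, X–B) instead of one: the extra two close
the thermodynamic cycle that lets the A–B estimate be error-checked.

Series mode on the built-in toy series (four benzene analogues plus one
tricyclic outlier whose best link to the others scores 0.41):

```r
series <- make_congeneric_series(fixture_spec())
smap   <- build_series_map(series, params = run_config())
series_summary(smap)
#>   n_nodes n_links links_le_0.6 links_le_0.4
#> 1       6       6            0            0
```

One intermediate (2-naphthalenylmethanol) was injected and every remaining
member–member link now scores at least 0.6.

A command-line front end wrapping the same functions is installed at
`inst/cli/alchemap` (subcommands `pair`, `series`, `score`, `stats`).

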