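# hyperfix

Fixation dynamics of birth-death processes on hypergraphs.

## The problem

Evolutionary graph theory asks how population structure changes the fate of
a mutant: on a network, a mutant type with constant relative fitness *r*
competes with a resident type of fitness 1 under birth-death updating, and
the structure is an **amplifier of selection** if a rare mutant fixates more
easily than in the well-mixed (Moran) population whenever *r* > 1 — or a
**suppressor** if structure damps selection instead. On conventional
networks, most structures amplify. This package implements the analogous
dynamics on **hypergraphs**, where reproduction acts through group
interactions: the parent, chosen with probability proportional to fitness,
picks one of its hyperedges uniformly and converts *all* co-members
(model 1), or converts them only when its type holds a strict majority in
the hyperedge (model 2). Under these group-level dynamics the picture
reverses — symmetric model families and randomized fixtures alike come out
as suppressors of selection.

The Moran baseline is
x_i = (1 − r^(−i)) / (1 − r^(−N)), with x_i = i/N at r = 1,
for *i* initial mutants among *N* individuals; a structure is compared to it
point by point over a fitness grid after an exactness check of the neutral
anchor x_i(1) = i/N.

It is intended for researchers in evolutionary dynamics and higher-order
networks who need exact small-system answers, validated closed forms, and a
fast simulator for arbitrary hypergraph data.

## What is inside

* `hypergraph()`, `make_model_hypergraph()` — the container plus generators
  for the complete, cyclic and star 3-uniform families and the complete
  graph; `read_hyperedge_list()` / `write_hyperedge_list()` for plain-text
  hyperedge lists; `one_mode_projection()` (weighted or not);
  `randomize_hypergraph()` (degree- and size-preserving double-edge swaps);
  `random_hypergraph()` for synthetic fixtures.
* `build_reduced_chain()` + `solve_absorption()` — symmetry-reduced Markov
  chains (pentadiagonal, tridiagonal, or sparse 2N x 2N for the star
  family) with sparse, dense and pentadiagonal (PTRANS-family) solvers;
  `closed_form_fixation()` for the printed rational functions;
  `brute_force_fixation()`, an exact 2^N-state oracle for any connected
  hypergraph with N ≤ 14 that also detects model-2 configurations that never
  fixate.
* `sim_step()`, `run_to_fixation()`, `estimate_fixation()` — a compiled
  stochastic simulator with the per-node uniform-initialization protocol,
  deterministic seeding and Wilson 95% intervals.
* `fixation_curve()`, `classify_selection()`, `run_experiment()` — fitness
  sweeps returning tibbles, amplifier/suppressor verdicts, and a one-call
  pipeline (curve + verdict + optional projection and randomization sweeps,
  CSV/JSON output). `autoplot()`, `tidy()` and `glance()` methods cover the
  result types, and `exec/hyperfix` is a thin command-line front end.

## Worked example

The star 3-uniform hypergraph on N = 5 nodes (hub node 1 plus every pair of
the four leaves as a hyperedge), swept exactly under model 1 and compared to
the Moran process:

```r
library(hyperfix)

H <- make_model_hypergraph("star3", 5)
cv <- fixation_curve("star3", 1, i = 1, N = 5,
                     r_values = c(0.25, 0.5, 0.8, 1, 1.25, 2, 4))
as.data.frame(cv)
#>      r       x      method
#> 1 0.25 0.01265 closed_form
#> 2 0.50 0.05966 closed_form
#> 3 0.80 0.14212 closed_form
#> 4 1.00 0.20000 closed_form
#> 5 1.25 0.26810 closed_form
#> 6 2.00 0.42802 closed_form
#> 7 4.00 0.64348 closed_form

classify_selection(cv)
#> <selection_verdict> suppressor
#>   baseline: Moran process, N = 5, i = 1
```

The curve passes the neutral anchor exactly (x_1(1) = 1/5 = 0.2), sits above
the Moran value at every r < 1 and below it at every r > 1 — a suppressor.
At r = 2 the exact value 0.42802 is well below the Moran 0.51613. The
stochastic simulator reproduces the same number with its per-node protocol
(3000 runs from each of the 5 start nodes):

```r
estimate_fixation(H, 1, 2, i = 1, runs_per_start = 3000, seed = 1)
#>   r i estimate ci_low ci_high  runs fixations timeouts mean_steps
#> 1 2 1   0.4227 0.4148  0.4306 15000      6340        0      4.154
```

Under model 2 the comparison itself can break down: at N = 5 the exact
two-mutant fixation probability at neutrality is

```r
sol <- solve_absorption(build_reduced_chain("star3", 2, 5, 1))
star_uniform_mix(sol, 2)
#> [1] 0.2571429   # = 9/35, not the Moran 2/5
```

so the star family at this size is neither amplifier nor suppressor under
the majority rule (`classify_selection()` reports `not_comparable`).

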