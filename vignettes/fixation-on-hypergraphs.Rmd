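---
title: "Fixation dynamics on hypergraphs: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation dynamics on hypergraphs: models, solvers, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperfix)
```

## The two models

`hyperfix` studies constant-selection evolutionary dynamics on a connected
hypergraph with `N` nodes. Each node carries one of two types: the mutant
(fitness `r`) or the resident (fitness 1). One update step does three things:

1. a **parent** is drawn from all nodes with probability proportional to its
   fitness;
2. the parent draws one of its incident hyperedges **uniformly**, regardless
   of hyperedge size (duplicated hyperedges in the multiset count once per
   copy, which is how integer edge weights are represented);
3. the parent **converts** the other members of that hyperedge to its own
   type — unconditionally in **model 1**, and in **model 2** only when the
   parent's type is held by *strictly more than half* of the hyperedge's
   members (parent included). Ties on even-sized hyperedges and minority
   parents change nothing.

The quantity of interest is the fixation probability `x_i`: the probability
that the mutant type takes over the whole population when `i` mutants are
placed uniformly at random ("uniform initialization"). The baseline is the
Moran process — the same birth-death rule on a complete graph — with

$$x_i = \frac{1 - r^{-i}}{1 - r^{-N}}, \qquad x_i = i/N \text{ at } r = 1.$$

A structure is a **suppressor of selection** when its curve lies below the
Moran curve for every `r > 1` and above it for every `r < 1`, and an
**amplifier** in the reverse case. The comparison only makes sense when the
curve passes the neutral anchor `x_i(1) = i/N`; model 1 always does
(neutral-drift theorem, tested exactly in the suite), while model 2
generally does not, because whether a parent propagates depends on the types
of its hyperedge co-members, which breaks the relabeling argument behind the
theorem. Model-2 curves failing the anchor are labelled `not_comparable`
(the conventional phrase is "neither amplifier nor suppressor").

Model 2 has a second pathology: fixation need not happen at all. On the
6-node hypergraph with hyperedges {1,2,3}, {3,4,5}, {4,5,6}, {6,1,2} and
mutants starting on nodes 1 and 2, nodes 4 and 5 remain residents forever
while 3 and 6 toggle indefinitely. The brute-force solver confirms absorption
probability 0 at both unanimous configurations, and simulations from that
start always hit the step cap.

## Exact machinery

**Reduced chains.** For the three symmetric families the `2^N`-state chain
collapses: the complete 3-uniform family (every 3-subset a hyperedge) and the
cyclic 3-uniform family (consecutive triples around a cycle) reduce to the
mutant count `i` in `0..N` — pentadiagonal under model 1 (up to two nodes can
flip per step), tridiagonal for the complete family under model 2 (at most
one flip under the majority rule). The star 3-uniform family (hub plus every
pair of the `N − 1` leaves) reduces to the pair (hub type, mutant leaf
count), a sparse `2N x 2N` chain. Note a counting subtlety in the star
construction: the hub belongs to all `choose(N-1, 2)` hyperedges while each
*leaf* belongs to `N − 2` of them (it pairs with each other leaf once); the
package derives all star transition rules from the model definition with
these degrees, and the derivation was checked symbolically against the
printed small-`N` rational forms before being frozen.

For the cyclic family under model 1 the count reduction is valid only when
the mutants form one consecutive block — which holds for all time if it holds
initially, in particular for a single initial mutant. The cyclic family under
model 2 is served by its closed form instead of an exposed reduced chain.

**Absorption solves.** Fixation probabilities per reduced state solve
`M x = b` with `M` the transition matrix minus the identity on non-absorbing
rows, identity rows at the two unanimous states, and `b` the indicator of the
all-mutant state. The default solver is a sparse LU (`Matrix`); a dense
LAPACK solve and a hand-written pentadiagonal elimination in the PTRANS
family are available as `method = "dense"` / `"ptrans"` and are required by
the test suite to agree to 1e-10 at `N = 200`. The banded route exists for
fidelity to standard practice for pentadiagonal systems; at the sizes treated
here all three are effectively instantaneous, so the choice is about
cross-checking, not speed. Residuals above 1e-10 and probabilities outside
`[0, 1]` by more than 1e-12 raise errors instead of being clipped silently.

**Closed forms.** Printed rational functions cover model 1 with `i = 1` at
`N = 4, 5` for all three families, and model 2 with `i = 2`: the complete
family at any `N` via the telescoping product over the odds ratios
`gamma_k = p_{k,k-1}/p_{k,k+1}` (giving `x_2 = (1 + 1/r)^{3-N}`, hence
`2^{3-N}` at neutrality), the cyclic family at any `N`, and the star family
at `N = 4, 5` (`x_2 = 9/35` at neutrality for `N = 5`). Two transcription
hazards were resolved by re-derivation: the star model-2 `N = 4` form was
reconstructed symbolically from the 8-state chain (it equals
`r(15r+17)/[(3r+5)(5r+3)]`, consistent with the neutral value 1/2), and the
general-`N` branch of the cyclic model-2 formula is gated in the tests by
brute-force equality at `N = 5, 6, 7` before being trusted at larger sizes.
The cumulative products in the telescoping form are built iteratively so no
large intermediate factorial appears.

**Brute force.** For arbitrary connected hypergraphs with `N <= 14` the full
`2^N`-state kernel is assembled directly from the model definition, with
states as bitmasks and transitions vectorized over states. Model 2 requires
care: the chain can have closed recurrent classes besides the two unanimity
states. These are found by strongly-connected-component analysis of the
positive-transition graph (igraph); each closed class other than the target
gets absorption probability 0 there, which makes the linear system
well-posed and exposes `P(never fixates)` as `1 - x_mutant - x_resident`.
The brute-force solver is the package's internal oracle: the suite requires
it to agree with every reduced chain and closed form to 1e-10 for
`N = 4..8`, both models.

## Stochastic simulation

The inner loop (parent choice by fitness, uniform incident hyperedge,
conversion rule, absorption check) is compiled C++ driven by R's RNG stream,
so a root seed fixes every run. `estimate_fixation()` follows the per-node
protocol: for `i = 1` each node serves as the initial mutant with
`runs_per_start` independent runs (default 3000, the convention for
`r >= 1`; use 40000 for small `r < 1` where fixations are rare); for
`i >= 2` mutant sets are sampled uniformly per run, with exhaustive
enumeration available for small `N`. Per-start seeds are derived
deterministically from the root seed by integer hashing. This is a simpler
reproducibility scheme than counter-based per-run substreams; it gives up
order-independent parallel execution, which is out of scope here.

Step caps default to `1e4 * N` for model 1 (fixation is almost sure; the cap
is a safety net several orders above typical fixation times at the sizes we
treat) and `1e3 * N^2` for model 2, where non-fixation is real. Timeouts are
a distinct outcome: under model 2 they are reported and excluded from the
estimate's denominator; under model 1 they would indicate a budget artifact
and are counted as non-fixation and flagged. Uncertainty is summarized by a
95% Wilson score interval, which behaves sensibly for estimates at or near
0 and 1 — the regime small `r` produces.

## Classification

`classify_selection()` operationalizes the amplifier/suppressor definitions,
which are stated over *all* `r`, on a finite grid: the default is 25
log-spaced points on `[1/4, 4]` plus `r = 1` exactly, symmetric in `log r`.
After the neutral anchor check, each grid point contributes a sign of
`x(r) - x_Moran(r)` only when the deviation is *resolvable* — larger than
`tol` (default 1e-9) for exact curves, or Moran outside the 95% CI for
simulated ones. A suppressor verdict requires every signed point to follow
the suppressor pattern with at least one signed point on each side of
`r = 1`; `equivalent` means no resolvable deviation anywhere; any
contradictory pattern is `neither`.

The resolvability rule is a deliberate design choice. Both fixation
probabilities decay like `r^{-N}` below `r = 1`, so at `N = 200` a grid
point at `r = 0.8` compares two numbers of order `1e-14` — below any
trustworthy solver resolution — and must not decide a verdict. For large `N`
one should therefore include grid points close to 1 (the package's own
acceptance checks add `0.95, 0.98, 1.02, 1.05`), exactly as one magnifies
the neighborhood of `r = 1` when reading such curves. On the default grid
the verdicts for the three families are invariant to grid refinement, which
the suite checks.

## Structural utilities

One-mode projections replace each hyperedge by its pairwise cliques; the
weighted variant keeps one size-2 hyperedge per shared hyperedge, so the
core dynamics on the projection automatically selects edges proportionally
to weight. The projections of the complete and cyclic families are regular,
hence isothermal — their model-1 dynamics reproduces the Moran curve to
1e-10 in the tests — while the weighted projection of the star family is a
weak amplifier. Both facts matter because they show the suppression observed
on the hypergraphs is not an artifact recoverable from their projections.

Randomization preserves each node's degree and each hyperedge's size by
bipartite double-edge swaps on the incidence structure; proposals that would
duplicate a node within a hyperedge are rejected and do not count toward the
swap budget (default `10 x` total incidences, a standard mixing heuristic).
Connectivity of the output is *not* enforced — the randomized ensemble is
reported with a connectivity flag, and consumers that need connectivity
(brute force) check it. The test fixtures walk seeds until connected
replicas are found rather than biasing the swap chain.

`random_hypergraph()` generates the synthetic fixtures used throughout the
tests: uniform hyperedge sizes from a user set, uniform member sets,
rejection of disconnected draws. These fixtures share two features with
empirical group-interaction data (hyperedges of mixed sizes, no special
symmetry) but none of its heterogeneity — no heavy-tailed degrees, no
community structure, no nestedness of groups. Green tests on them demonstrate
the correctness of the machinery and the robustness of the suppression
pattern on small unstructured hypergraphs; they do not by themselves
establish behavior on large empirical datasets, which must be loaded through
`read_hyperedge_list()` and simulated.

## Numerical choices and limitations

* `r = 1` is handled by explicit limit expressions wherever a formula has a
  0/0 form (the Moran formula and the cyclic model-2 closed form); elsewhere
  the neutral case is just another parameter value.
* Linear-solve residual tolerance 1e-10, probability clipping slack 1e-12;
  violations raise.
* The brute-force cap `N <= 14` keeps the kernel below `2^14` states; beyond
  that the simulator is the only general tool.
* Exact comparisons between closed forms and solves are asserted as absolute
  differences: at probabilities of order `1e-16` relative agreement is
  meaningless in double precision.
* Problem sizes used by the tests and the acceptance script — `N` up to 200
  exactly, `N = 4..8` for oracle cross-checks, roughly `10^4` simulation
  runs per calibration cell — were chosen so the full suite completes in a
  few minutes while leaving every comparison with comfortable statistical
  and numerical margin.
* Fixation *times*, death-birth updating, dynamic hypergraphs and
  metapopulation variants are out of scope.
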