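---
title: "Genome halving and median problems as polygon gluings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome halving and median problems as polygon gluings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjtopo)
```

## The problems

`dcjtopo` works with circular genomes written as signed gene orders. Under
the double-cut-and-join (DCJ) model an operation removes two adjacencies and
re-pairs the four freed extremities, which captures reversals, fusions,
fissions and (for multichromosomal genomes) translocations in one move. Three
classical reconstruction problems drive the package:

* **Genome halving (GHP).** Given an all-duplicated genome `A` (every gene
  in two copies, the typical state some time after a whole-genome
  duplication), find an ordinary genome `R` minimizing `d_DCJ(A, 2R)` where
  `2R` is the doubled genome.
* **Restricted guided halving (RGGHP).** Among the (typically very many)
  halving solutions for `A`, find one closest to a guide genome `B`.
* **Intermediate genome median (IGMP).** Given ordinary `P`, `Q` and an
  outgroup `T`, find a genome on a shortest scenario between `P` and `Q`
  that is closest to `T`.

The package's central idea is that the last two problems become a single
*surgery* problem on surfaces.

## From breakpoint graphs to surfaces

For ordinary genomes the breakpoint graph decomposes into alternating
PQ-cycles and `d_DCJ(P,Q) = n − c(P,Q)` (`dcj_distance()`, with
`brute_force_distance()` as the independent BFS oracle). For an
all-duplicated `A` the two copies of each gene are glued, giving the
contracted breakpoint graph (`contracted_breakpoint_graph()`): every
extremity has degree two in the A-edges, which therefore split uniquely into
A-cycles; `k` denotes the number of even ones. The halving optimum is
`d = n − k`, attained exactly when the doubled graph admits `n + k`
alternating AR-cycles.

Fixing an orientation of each A-cycle turns it into an oriented polygon with
one labelled side per cycle vertex (`polygons_from_cycles()`), and any
candidate `R` becomes a matching on the sides. The orientable head-to-tail
gluing (`glue()`) identifies, for matched sides `s` and `t`, the corner
following `s` with the corner preceding `t` and vice versa. Vertices of the
glued complex are corner orbits, edges are matched pairs, faces are
polygons, and per component the Euler relation determines the genus
(`genus_from_euler()`). Two structural facts make this useful:

* the glued vertices correspond one-to-one to the AR-cycles of the
  *ht-decomposition* for that orientation (`ht_decomposition()`), and
* a gluing of `k` even-gons and `2l` odd-gons on `2n` sides has at most
  `n + k` vertices, with equality exactly for all-sphere configurations with
  one even-gon or two odd-gons per component.

So halving solutions are exactly the matchings that (for some orientation)
glue to the maximal number of spheres, and a DCJ on `R` is a *DCJ-surgery*
on the embedded graph: cut two edges, re-glue the four freed sides
(`apply_surgery()`, with `dcj_from_surgery()`/`surgery_from_dcj()`
translating between the two pictures).

```{r fig4}
A <- parse_genome("(+a+c-b-d)(+a-b)(+c+d)")
R <- parse_genome("(+a-c-b+d)")
pm <- polygons_from_cycles(contracted_breakpoint_graph(A, R))
glue(pm$pc, pm$matching)$components
```

This matching glues the single 8-gon into a one-vertex, one-face graph on a
genus-2 surface — two surgeries away from a sphere, hence `R` is two DCJs
away from the nearest halving solution.

## Bookkeeping conventions for partial gluings

A partial matching leaves unmatched sides, which close up into boundary
walks (*holes*). The package stores `v` as the number of corner classes, `e`
as the number of glued pairs and `e_boundary` as the number of unmatched
sides, and computes the genus from the Euler characteristic of the full cell
complex, `v − (e + e_boundary) + f = 2 − 2g − h`. Counting the boundary
1-cells is what makes the relation exact in all cases: gluing a pair of
sides from two different holes then loses two vertices, one edge and one
hole and raises the genus by exactly one, and an unglued `2k`-gon is a disc
(`g = 0`, one hole of length `2k`). Holes of length one and entirely unglued
polygons are legal throughout; both occur in the enumeration arguments
below. The boundary-walk rule — from an unmatched side, step to the next
side of its polygon and jump across matched sides until an unmatched one
reappears — is the standard rule for surfaces with boundary; the tests pin
it down through Euler consistency and the one-hole counts rather than by
fiat.

## Exact counts

Sphere gluings are counted in closed form: a `2k`-gon glues to a sphere in
`catalan(k)` ways, and a `(2m+1)`-gon plus a `(2n+1)`-gon glue to a single
sphere in `odd_pair_count(m, n)` ways, with
`T(m,n) = (2mn+m+n+1)/(m+n+1) · choose(2m+1,m) · choose(2n+1,n)`. The number
of halving solutions (`count_ghp_solutions()`) multiplies Catalan factors
over even A-cycles with a sum of `T` products over pairings of the odd
A-cycles, and the number of intermediate genomes (`count_intermediates()`)
is the Catalan product over PQ-cycle half-lengths. All arithmetic is exact
(integer-valued doubles below 2^53, with explicit divisibility checks).

One subtlety is worth recording. With the orientation of every polygon held
fixed, direct enumeration of side matchings gluing two 3-gons into a single
sphere yields 12, not `T(1,1) = 15`: three matchings need the *relative*
orientation of the two polygons flipped before they become sphere gluings.
Since a halving solution only requires *some* orientation of the A-cycles
to realize the maximal decomposition, the right notion of "sphere gluing"
for counting purposes quantifies over per-polygon orientations, and the
genome-level enumeration (`enumerate_ghp_solutions()`) confirms it: for an
all-duplicated genome with two odd 3-cycles, all 15 ordinary genomes on its
three genes are halving solutions. `sphere_gluing_count_bruteforce()`
therefore accepts a matching when any orientation assignment (the first
polygon fixed, since a global flip is a genus-preserving mirror) achieves
the all-sphere maximum.

```{r counts}
c(catalan(4), odd_pair_count(1, 1), sphere_gluing_count_bruteforce(c(3, 3)))
```

## The torus surgery solver

When the guide genome's embedded graph is connected with a single face on a
torus (`v = e − 1`), the shortest number of surgeries to reach a sphere is
`l` with `2l` the minimum of two quantities in the multigraph view: the
length of a shortest even *simple* cycle (`shortest_even_cycle()`), and the
minimal total length of two edge-disjoint odd simple cycles sharing exactly
one vertex (`shortest_odd_cycle_pair()`, two loops at one vertex being the
smallest case). The published algorithm searches only for the even cycle;
the odd-pair branch is included because an instance whose cheapest structure
is two loops at a vertex would otherwise get a suboptimal answer, and it is
sound by the same reduction argument. Both searches are exhaustive
enumerations of simple cycles, which at the solver's instance sizes (at most
a few dozen edges) is far below any cost worth optimizing; the published
`O(n²)` BFS bound applies to the even-cycle search alone.

Each reduction step must keep the graph a single-face torus while shortening
the tracked structure by two. No closed-form rule for choosing between the
two possible re-gluings is available, so the solver tries the candidate cuts
(adjacent edge pairs of a minimal structure first, then all pairs) and
verifies each candidate by recomputing the glued complex — `O(e)` work per
try. The final surgery cuts the remaining length-2 structure and picks the
re-gluing that lands on genus 0. Optimality is asserted in the tests against
a breadth-first search over entire matching space on small instances.

`solve_rgghp_torus()` wires this back to genomes: build the contracted
breakpoint graph of `(A, B)`, reject inputs without a single A-cycle or with
genus above one (a genus-0 input short-circuits: `B` is already a
solution), run the solver, translate surgeries to DCJs and replay them on
`B`. `solve_igmp_torus()` feeds the union genome of `P` and `Q` (an
artificial all-duplicated genome whose A-cycles are the PQ-cycles, all even
— so every orientation works) through the same path.

```{r torus}
inst <- random_torus_instance(4, seed = 306)
res <- solve_rgghp_torus(inst$A, inst$B)
res$l
dcj_distance(inst$B, res$R)
```

## Design choices and defaults

* **Canonical forms.** A circular chromosome equals its rotations and its
  reflection with flipped strands (a DNA circle has no reading direction);
  `write_genome()` rotates the smallest gene first, preferring the `+`
  strand, and sorts chromosomes, so genome equality is string equality of
  canonical forms. All orderings use C-locale radix order.
* **Determinism.** A-cycle traversal starts at the smallest extremity
  toward its smaller neighbour; this traversal *is* the "clockwise"
  orientation, and orientation flags reverse it. The greedy
  `shortest_scenario()` always splits at the canonically first extremity of
  a long cycle, and solver tie-breaks use canonical vertex/edge order, so
  every output is reproducible.
* **Halving construction.** `solve_ghp()` uses consecutive-pair chords
  inside even A-cycles and pairs odd A-cycles in canonical order, joining
  their smallest vertices with the single interedge — one deterministic
  representative of the noncrossing family; any noncrossing matching would
  do.
* **Oracle caps.** `brute_force_distance()` defaults to `n ≤ 5`
  (state space grows as `(2n−1)!!`), `cmax_bruteforce()` to `n ≤ 8`
  (`2^(2n)` transition choices), side-matching enumeration to 14 sides
  (135135 matchings). These are desk-scale verification tools, not
  production paths, and the caps are arguments, not constants.
* **Generator defaults.** `random_ordinary_genome()` draws a uniform signed
  arrangement into the requested number of chromosomes;
  `random_torus_instance()` rejection-samples a single-A-cycle duplicated
  genome and a guide until the glued graph has genus 1, falling back to a
  random DCJ walk from a halving solution after 1000 attempts. Property
  tests run at `n` between 3 and 7 with fixed seeds; the enumerative
  cross-checks use exhaustive spaces at `n ≤ 4` (105 matchings) so that
  "maximum over all genomes" is literal, not sampled.

## What the synthetic data does and does not show

The generators produce uniform random arrangements, not biologically
plausible ones: real genomes after WGD have correlated, rate-heterogeneous
rearrangements, unequal gene content, and linear chromosomes. Passing tests
therefore certify the combinatorics — distances, counts, genus bookkeeping
and optimality on the sampled and exhaustively enumerated instances — and
nothing about inference quality on real data. Known limitations are
explicit: linear chromosomes and unequal gene content are rejected at
parsing/validation; non-orientable gluings are out of scope; the surgery
solver handles exactly the connected single-face genus-1 case and refuses
anything else (for genus 0 it returns the empty scenario through the
guided-halving front-end).
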