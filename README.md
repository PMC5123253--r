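# dcjtopo

Ancestral genome reconstruction for circular genomes under the
double-cut-and-join (DCJ) model, with a topological twist: `dcjtopo`
implements breakpoint and contracted breakpoint graphs, DCJ distances and
shortest scenarios, genome halving after whole-genome duplication (WGD),
exact counts of halving solutions and intermediate genomes, and a solver for
the *restricted guided* halving and *intermediate genome* median problems
that works by gluing polygons into surfaces and performing DCJ-surgeries on
the resulting embedded graphs.

It is aimed at researchers in comparative genomics and combinatorics of
genome rearrangements who want small, exactly verifiable instances: every
closed-form count ships next to a brute-force oracle, and every solver
verifies its own output.

## The model in brief

A circular chromosome over signed genes induces *adjacencies* between gene
extremities (`x.t`, `x.h`). For ordinary genomes `P`, `Q` on the same `n`
genes the breakpoint graph decomposes into `c(P,Q)` alternating cycles and

```
d_DCJ(P,Q) = n − c(P,Q).
```

For an all-duplicated genome `A` (every gene twice, as after a WGD) the
contracted breakpoint graph carries A-cycles, `k` of them even; the minimal
distance to any doubled genome `2R` is `n − k`, attained exactly when the
maximal AR-cycle decomposition of the doubled graph reaches `n + k` cycles.
Choosing an orientation of the A-cycles turns each A-cycle into an oriented
polygon and each candidate genome `R` into a side matching; the orientable
(head-to-tail) gluing produces an embedded graph on a surface whose vertex
count equals the ht-decomposition cycle count, and whose genus, via the
Euler relation `v − e + f + h = 2 − 2g`, measures how far `R` is from a
halving solution. Halving solutions correspond to all-sphere gluings; their
number is a product of Catalan numbers `C_k = choose(2k,k)/(k+1)` over even
A-cycles times a sum of `T(m,n)` terms over pairings of odd A-cycles. On a
single-face torus, a shortest sequence of DCJ-surgeries to a sphere has
length `l`, where `2l` is the length of a shortest even simple cycle (or of
two odd cycles sharing one vertex) in the embedded multigraph — which is
what the guided-halving solver exploits.

## Worked example

```r
library(dcjtopo)

P <- parse_genome("(+a+d-c-b)")
Q <- parse_genome("(+a-b+d+c)")
dcj_distance(P, Q)        # 3
count_intermediates(P, Q) # 14  (one 8-edge cycle: C_4)

A <- parse_genome("(+a+c-b-d)(+a-b)(+c+d)")   # all-duplicated, one A-cycle
solve_ghp(A)              # (+a-b)(+c+d)
ghp_distance(A)           # 3
count_ghp_solutions(A)    # 14

# glue A's polygon against a non-solution matching: a 2-torus
cbg <- contracted_breakpoint_graph(A, parse_genome("(+a-c-b+d)"))
pm  <- polygons_from_cycles(cbg)
glue(pm$pc, pm$matching)
#> embedded graph: 1 component(s)
#>  component v e e_boundary f h g
#>          1 1 4          0 1 0 2

# guided halving on a torus instance
inst <- random_torus_instance(4, seed = 306)
res  <- solve_rgghp_torus(inst$A, inst$B)
res$R          # (+a-d+b+c)
res$scenario
#> DCJ scenario of length 2
#>   a.h-c.t, b.h-d.h -> a.h-d.h, b.h-c.t
#>   a.t-d.t, b.t-c.h -> a.t-c.h, b.t-d.t
```

The embedded-graph row says the glued complex has one vertex, four edges and
one face on a genus-2 surface, so that matching is 2 surgeries away from the
all-sphere (halving-solution) configuration; the scenario shows the two DCJs
that take `B` to an optimal halving solution `R` of `A`.

A thin command-line wrapper lives in `inst/scripts/dcjtool`
(subcommands `distance`, `halve`, `count-halvings`, `count-intermediates`,
`glue`, `rgghp-torus`, `igmp-torus`, `simulate`).

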