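# Shared test fixtures: small deterministic genome pairs and gluing helpers.

fx <- paper_examples()

random_pair <- function(n, seed) {
  list(P = random_ordinary_genome(n, seed = seed),
       Q = random_ordinary_genome(n, seed = seed + 5000L))
}

# Glue the embedded graph induced by (A, R) under orientation o.
glued_graph <- function(A, R, o = NULL) {
  pm <- polygons_from_cycles(contracted_breakpoint_graph(A, R), o)
  glue(pm$pc, pm$matching)
}

a_cycle_lengths <- function(A) {
  sort(vapply(contracted_breakpoint_graph(A)$a_cycles,
              function(cy) length(cy$vertices), integer(1)))
}

# All 3 * (2k-1)!!-style partial matchings with exactly `pairs` disjoint
# side pairs chosen from `n` sides.
partial_matchings <- function(n, pairs) {
  out <- list()
  sides <- seq_len(n)
  for (chosen in utils::combn(n, 2L * pairs, simplify = FALSE)) {
    for (m in dcjtopo:::enumerate_perfect_matchings(2L * pairs)) {
      out[[length(out) + 1L]] <- cbind(chosen[m[, 1L]], chosen[m[, 2L]])
    }
  }
  out
}
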