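#' Multigraph view of an embedded graph
#'
#' Vertices are the corner classes and edges the matched side pairs; loops
#' and parallel edges are kept.
#'
#' @param eg an `"embedded_graph"`.
#' @return data.frame with columns `edge`, `u`, `v`.
#' @export
multigraph_view <- function(eg) {
  eg$edges[, c("edge", "u", "v")]
}

# Enumerate all simple cycles of a multigraph given as a data.frame(edge,u,v).
# A loop is a length-1 cycle; a pair of parallel edges a length-2 cycle;
# longer cycles have pairwise-distinct vertices. Returns a list of
# list(edges, vertices, len), deduplicated, in deterministic order.
enumerate_simple_cycles <- function(mg) {
  out <- list()
  keyset <- new.env(parent = emptyenv())
  push <- function(edges, vertices) {
    key <- paste(sort(edges), collapse = ",")
    if (!exists(key, envir = keyset, inherits = FALSE)) {
      assign(key, TRUE, envir = keyset)
      out[[length(out) + 1L]] <<- list(edges = sort(edges),
                                       vertices = sort(unique(vertices)),
                                       len = length(edges))
    }
  }
  loops <- mg$edge[mg$u == mg$v]
  for (e in loops) push(e, mg$u[mg$edge == e])
  plain <- mg[mg$u != mg$v, , drop = FALSE]
  # parallel pairs
  if (nrow(plain) >= 2L) {
    ek <- paste(pmin(plain$u, plain$v), pmax(plain$u, plain$v))
    for (key in unique(ek[duplicated(ek)])) {
      es <- plain$edge[ek == key]
      cmb <- utils::combn(es, 2L)
      for (j in seq_len(ncol(cmb)))
        push(cmb[, j], unlist(plain[plain$edge == cmb[1L, j], c("u", "v")]))
    }
  }
  # simple cycles of length >= 3 by DFS over vertices (distinct vertices)
  verts <- sort(unique(c(mg$u, mg$v)))
  adj <- lapply(verts, function(v) {
    rows <- plain[plain$u == v | plain$v == v, , drop = FALSE]
    if (nrow(rows) == 0L) return(rows)
    rows$to <- ifelse(rows$u == v, rows$v, rows$u)
    rows
  })
  names(adj) <- as.character(verts)
  dfs <- function(start, v, path_v, path_e) {
    nb <- adj[[as.character(v)]]
    for (r in seq_len(nrow(nb))) {
      w <- nb$to[r]; e <- nb$edge[r]
      if (e %in% path_e) next
      if (w == start && length(path_e) >= 2L) {
        push(c(path_e, e), path_v)
      } else if (w > start && !(w %in% path_v)) {
        dfs(start, w, c(path_v, w), c(path_e, e))
      }
    }
  }
  for (s in verts) dfs(s, s, s, integer(0))
  out
}

pick_min_cycle <- function(cycles) {
  if (length(cycles) == 0L) return(NULL)
  lens <- vapply(cycles, `[[`, integer(1), "len")
  cand <- cycles[lens == min(lens)]
  keys <- vapply(cand, function(cy)
    paste(c(cy$vertices, cy$edges), collapse = ","), character(1))
  cand[[corder(keys)[1L]]]
}

#' Shortest even simple cycle of a multigraph
#'
#' Loops have length 1 (odd); a pair of parallel edges is a length-2 even
#' cycle. Ties are broken by canonical vertex then edge order.
#'
#' @param mg a data.frame as returned by [multigraph_view()].
#' @return a list with `edges`, `vertices`, `len`, or `NULL` when the graph
#'   has no even simple cycle.
#' @export
shortest_even_cycle <- function(mg) {
  cycles <- enumerate_simple_cycles(mg)
  pick_min_cycle(Filter(function(cy) cy$len %% 2L == 0L, cycles))
}

#' Shortest pair of odd simple cycles sharing one vertex
#'
#' Among edge-disjoint pairs of odd simple cycles that share exactly one
#' vertex, returns a pair minimizing the total length (e.g. two loops at one
#' vertex give total 2), or `NULL` if no such pair exists.
#'
#' @inheritParams shortest_even_cycle
#' @return list with `first`, `second`, `total`, or `NULL`.
#' @export
shortest_odd_cycle_pair <- function(mg) {
  odd <- Filter(function(cy) cy$len %% 2L == 1L, enumerate_simple_cycles(mg))
  if (length(odd) < 2L) return(NULL)
  best <- NULL
  for (a in seq_len(length(odd) - 1L)) {
    for (b in (a + 1L):length(odd)) {
      ca <- odd[[a]]; cb <- odd[[b]]
      if (length(intersect(ca$edges, cb$edges)) > 0L) next
      if (length(intersect(ca$vertices, cb$vertices)) != 1L) next
      tot <- ca$len + cb$len
      if (is.null(best) || tot < best$total)
        best <- list(first = ca, second = cb, total = tot)
    }
  }
  best
}

# The minimal "2l" quantity of the solver: min over the shortest even simple
# cycle length and the shortest odd-pair total. NULL if neither exists.
min_cycle_quantity <- function(mg) {
  ec <- shortest_even_cycle(mg)
  op <- shortest_odd_cycle_pair(mg)
  vals <- c(if (!is.null(ec)) ec$len, if (!is.null(op)) op$total)
  if (length(vals) == 0L) return(NULL)
  min(vals)
}

check_torus_instance <- function(eg) {
  comps <- eg$components
  if (nrow(comps) != 1L) stop2("not a single-face torus instance: not connected")
  if (comps$f != 1L) stop2("not a single-face torus instance: f != 1")
  if (comps$h != 0L) stop2("not a single-face torus instance: has holes")
  if (comps$g != 1L) stop2("not a single-face torus instance: genus != 1")
  stopifnot(comps$v == comps$e - 1L)
  invisible(TRUE)
}

#' Solve the genome surgery problem on a single-face torus
#'
#' Given a connected embedded graph with one face on a torus, finds a
#' shortest sequence of DCJ-surgeries producing an embedded graph on a
#' sphere. The minimal length is `l`, where `2l` is the smaller of the
#' shortest even simple cycle length and the minimal total length of two
#' odd simple cycles sharing one vertex. The reduction repeatedly applies a
#' surgery (verified by recomputation) that keeps the graph a single-face
#' torus while decreasing the tracked quantity by 2, and the final surgery
#' cuts the remaining length-2 structure to reach genus 0.
#'
#' @param eg an `"embedded_graph"` satisfying the single-face torus
#'   invariants (f = 1, connected, genus 1, no holes, `v = e - 1`).
#' @return list with `surgeries` (list of `"surgery"`), `result` (the final
#'   `"embedded_graph"`, genus 0) and `l` (the sequence length).
#' @export
solve_gsp_torus <- function(eg) {
  check_torus_instance(eg)
  q0 <- min_cycle_quantity(multigraph_view(eg))
  if (is.null(q0) || q0 %% 2L != 0L)
    stop2("internal: single-face torus must contain an even cycle structure")
  l <- q0 %/% 2L
  surgeries <- list()
  cur <- eg
  remaining <- l
  while (remaining > 1L) {
    step <- find_reduction_surgery(cur, 2L * (remaining - 1L))
    if (is.null(step)) stop2("internal: no torus-preserving reduction surgery found")
    surgeries[[length(surgeries) + 1L]] <- step$surgery
    cur <- step$eg
    remaining <- remaining - 1L
  }
  step <- find_final_surgery(cur)
  if (is.null(step)) stop2("internal: no sphere-producing final surgery found")
  surgeries[[length(surgeries) + 1L]] <- step$surgery
  cur <- step$eg
  stopifnot(is_all_spheres(cur), length(surgeries) == l)
  list(surgeries = surgeries, result = cur, l = l)
}

# One surgery keeping a single-face torus and reducing the tracked quantity
# to `target`. Candidate cuts are tried in deterministic order: first pairs
# of adjacent edges along a minimal tracked structure, then all pairs.
find_reduction_surgery <- function(eg, target) {
  mg <- multigraph_view(eg)
  ec <- shortest_even_cycle(mg)
  op <- shortest_odd_cycle_pair(mg)
  tracked <- c(if (!is.null(ec)) list(ec$edges),
               if (!is.null(op)) list(c(op$first$edges, op$second$edges)))
  cand <- list()
  for (edges in tracked) {
    if (length(edges) >= 2L) {
      cmb <- utils::combn(sort(edges), 2L)
      for (j in seq_len(ncol(cmb))) cand[[length(cand) + 1L]] <- cmb[, j]
    }
  }
  ne <- nrow(eg$matching)
  cmb <- utils::combn(seq_len(ne), 2L)
  for (j in seq_len(ncol(cmb))) cand[[length(cand) + 1L]] <- cmb[, j]
  tried <- character(0)
  for (cut in cand) {
    key <- paste(cut, collapse = ",")
    if (key %in% tried) next
    tried <- c(tried, key)
    for (reglue in surgery_reglues(eg, cut)) {
      s <- try(surgery(cut, reglue), silent = TRUE)
      if (inherits(s, "try-error")) next
      eg2 <- try(apply_surgery(eg, s), silent = TRUE)
      if (inherits(eg2, "try-error")) next
      comps <- eg2$components
      if (nrow(comps) != 1L || comps$g != 1L || comps$h != 0L) next
      q <- min_cycle_quantity(multigraph_view(eg2))
      if (!is.null(q) && q == target) return(list(surgery = s, eg = eg2))
    }
  }
  NULL
}

# Final step: cut a length-2 structure (parallel pair or two loops at one
# vertex) with the re-gluing that lands on spheres.
find_final_surgery <- function(eg) {
  mg <- multigraph_view(eg)
  ec <- shortest_even_cycle(mg)
  op <- shortest_odd_cycle_pair(mg)
  cand <- list()
  if (!is.null(ec) && ec$len == 2L) cand[[length(cand) + 1L]] <- ec$edges
  if (!is.null(op) && op$total == 2L)
    cand[[length(cand) + 1L]] <- c(op$first$edges, op$second$edges)
  for (cut in cand) {
    for (reglue in surgery_reglues(eg, sort(cut))) {
      s <- try(surgery(sort(cut), reglue), silent = TRUE)
      if (inherits(s, "try-error")) next
      eg2 <- try(apply_surgery(eg, s), silent = TRUE)
      if (inherits(eg2, "try-error")) next
      if (is_all_spheres(eg2)) return(list(surgery = s, eg = eg2))
    }
  }
  NULL
}

#' Solve the restricted guided genome halving problem (torus case)
#'
#' For an all-duplicated genome `A` whose contracted breakpoint graph has a
#' single (even) A-cycle and an ordinary genome `B` whose induced embedded
#' graph lies on a torus, returns a halving solution `R` for `A` at minimal
#' DCJ distance from `B`, together with the realizing scenario. When the
#' embedded graph is already on a sphere, `B` itself solves the halving
#' problem and the scenario is empty.
#'
#' @param A an all-duplicated genome with a single A-cycle.
#' @param B an ordinary genome on the same distinct-gene set.
#' @return list with `R` (genome), `scenario` (a `"dcj_scenario"` from `B`
#'   to `R`) and `l` (its length).
#' @export
solve_rgghp_torus <- function(A, B) {
  cbg <- contracted_breakpoint_graph(A, B)
  if (length(cbg$a_cycles) != 1L)
    stop2("precondition not met: contracted breakpoint graph must have a single A-cycle")
  pm <- polygons_from_cycles(cbg)  # either orientation gives the same result
  eg <- glue(pm$pc, pm$matching)
  g <- eg$components$g[1L]
  if (g == 0L) {
    scen <- structure(list(ops = list(), source = canonical_genome(B),
                           target = canonical_genome(B)), class = "dcj_scenario")
    return(list(R = canonical_genome(B), scenario = scen, l = 0L))
  }
  if (g != 1L)
    stop2("precondition not met: embedded graph has genus ", g, ", not a torus")
  sol <- solve_gsp_torus(eg)
  cur_eg <- eg
  cur_B <- canonical_genome(B)
  ops <- list()
  for (s in sol$surgeries) {
    op <- dcj_from_surgery(cur_eg, s)
    ops[[length(ops) + 1L]] <- op
    cur_B <- apply_dcj(cur_B, op)
    cur_eg <- apply_surgery(cur_eg, s)
  }
  scen <- structure(list(ops = ops, source = canonical_genome(B), target = cur_B),
                    class = "dcj_scenario")
  list(R = cur_B, scenario = scen, l = sol$l)
}

#' Solve the intermediate genome median problem (torus case)
#'
#' Forms the artificial all-duplicated union genome of `P` and `Q` and
#' delegates to [solve_rgghp_torus()]: the returned genome `I` is an
#' intermediate genome between `P` and `Q` minimizing the DCJ distance to
#' the outgroup `T`, provided the induced embedded graph is a single-face
#' torus instance (which requires `c(P,Q) = 1`).
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @param T_out an ordinary outgroup genome on the same gene set.
#' @return list with `I`, `scenario` (from `T_out` to `I`) and `l`.
#' @export
solve_igmp_torus <- function(P, Q, T_out) {
  check_same_ordinary(P, Q, T_out)
  PQ <- genome(c(P$chromosomes, Q$chromosomes))
  stopifnot(is_all_duplicated(PQ))
  res <- solve_rgghp_torus(PQ, T_out)
  list(I = res$R, scenario = res$scenario, l = res$l)
}
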