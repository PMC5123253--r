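#' DCJ operations
#'
#' A double-cut-and-join (DCJ, or 2-break) removes two adjacencies of a
#' genome and replaces them with a different pairing of the same four
#' extremity slots.
#'
#' @param removed,added each a 2-column character matrix (or list of two
#'   pairs) of adjacencies.
#' @return an object of class `"dcj_op"`.
#' @export
dcj_op <- function(removed, added) {
  removed <- as_adj_matrix(removed)
  added <- as_adj_matrix(added)
  if (nrow(removed) != 2L || nrow(added) != 2L)
    stop2("a DCJ removes exactly 2 adjacencies and adds exactly 2")
  if (!identical(csort(c(removed)), csort(c(added))))
    stop2("removed and added adjacencies must cover the same 4 extremity slots")
  if (identical(removed, added)) stop2("added must differ from removed")
  structure(list(removed = removed, added = added), class = "dcj_op")
}

#' @export
print.dcj_op <- function(x, ...) {
  cat(format_dcj(x), "\n")
  invisible(x)
}

format_dcj <- function(op) {
  fmt <- function(m) paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ", ")
  paste(fmt(op$removed), "->", fmt(op$added))
}

#' Apply a DCJ operation to a genome
#'
#' @param g an ordinary genome whose adjacencies contain `op$removed`.
#' @param op a [dcj_op()].
#' @return the rearranged genome (canonical form).
#' @export
apply_dcj <- function(g, op) {
  stopifnot(inherits(g, "genome"), inherits(op, "dcj_op"))
  adj <- adjacencies(g)
  keys <- adj_key(adj[, 1L], adj[, 2L])
  for (i in 1:2) {
    k <- adj_key(op$removed[i, 1L], op$removed[i, 2L])
    hit <- match(k, keys)
    if (is.na(hit)) stop2("removed adjacency absent from genome: ", k)
    keys <- keys[-hit]
    adj <- adj[-hit, , drop = FALSE]
  }
  genome_from_matching(rbind(adj, op$added))
}

#' DCJ distance between two genomes
#'
#' For ordinary circular genomes on the same `n` genes the DCJ distance is
#' `n - c(P,Q)`, with `c(P,Q)` the number of alternating cycles in their
#' breakpoint graph.
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @return a non-negative integer.
#' @examples
#' dcj_distance(parse_genome("(+a+d-c-b)"), parse_genome("(+a-b+d+c)"))
#' @export
dcj_distance <- function(P, Q) {
  bg <- breakpoint_graph(P, Q)
  bg$n - bg$c
}

#' Exact DCJ distance by breadth-first search (test oracle)
#'
#' Explores genomes reachable from `P` by DCJs until `Q` is found. Exponential
#' in `n`; intended purely as an independent check of [dcj_distance()] on tiny
#' instances.
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @param max_n refuse instances with more than this many genes.
#' @return the minimal number of DCJs transforming `P` into `Q`.
#' @export
brute_force_distance <- function(P, Q, max_n = 5L) {
  check_same_ordinary(P, Q)
  if (n_genes(P) > max_n) stop2("instance too large for oracle")
  target <- genome_key(Q)
  frontier <- list(P)
  dist <- 0L
  seen <- new.env(parent = emptyenv())
  assign(genome_key(P), TRUE, envir = seen)
  repeat {
    if (any(vapply(frontier, genome_key, character(1)) == target)) return(dist)
    nxt <- list()
    for (g in frontier) {
      for (h in dcj_neighbors(g)) {
        k <- genome_key(h)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- h
        }
      }
    }
    if (length(nxt) == 0L) stop2("target unreachable (should not happen)")
    frontier <- nxt
    dist <- dist + 1L
  }
}

# All genomes one DCJ away from g.
dcj_neighbors <- function(g) {
  adj <- adjacencies(g)
  m <- nrow(adj)
  out <- list()
  if (m < 2L) return(out)
  for (i in 1:(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- adj[i, ]; b <- adj[j, ]
      for (added in list(
        rbind(c(a[1L], b[1L]), c(a[2L], b[2L])),
        rbind(c(a[1L], b[2L]), c(a[2L], b[1L]))
      )) {
        op <- dcj_op(rbind(a, b), added)
        out[[length(out) + 1L]] <- apply_dcj(g, op)
      }
    }
  }
  out
}

#' Shortest DCJ scenario between two genomes
#'
#' Greedy cycle-splitting: while some PQ-cycle is longer than two edges, take
#' the first extremity (canonical order) on such a cycle and replace the two
#' P-edges flanking its Q-edge along the cycle so that the Q-edge becomes a
#' P-adjacency, splitting off a 2-cycle. Each step increases the cycle count
#' by one, so the scenario has length `dcj_distance(P, Q)` and every prefix
#' genome is intermediate.
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @return an object of class `"dcj_scenario"`: list with `ops` (list of
#'   [dcj_op()]), `source`, `target`.
#' @export
shortest_scenario <- function(P, Q) {
  check_same_ordinary(P, Q)
  ops <- list()
  cur <- canonical_genome(P)
  repeat {
    bg <- breakpoint_graph(cur, Q)
    long <- bg$pq_cycles[lengths(bg$pq_cycles) > 2L]
    if (length(long) == 0L) break
    firsts <- vapply(long, function(cy) csort(cy)[1L], character(1))
    cyc <- long[[corder(firsts)[1L]]]
    v <- csort(cyc)[1L]
    pm <- matching_map(bg$P_edges)
    qm <- matching_map(bg$Q_edges)
    q <- qm[[v]]             # Q-edge v--q to be created as a P-adjacency
    p1 <- pm[[v]]            # P-edge at v
    p2 <- pm[[q]]            # P-edge at q
    op <- dcj_op(rbind(c(v, p1), c(q, p2)), rbind(c(v, q), c(p1, p2)))
    cur <- apply_dcj(cur, op)
    ops[[length(ops) + 1L]] <- op
  }
  structure(list(ops = ops, source = canonical_genome(P), target = canonical_genome(Q)),
            class = "dcj_scenario")
}

#' @export
print.dcj_scenario <- function(x, ...) {
  cat("DCJ scenario of length", length(x$ops), "\n")
  for (op in x$ops) cat(" ", format_dcj(op), "\n")
  invisible(x)
}

#' @export
length.dcj_scenario <- function(x) length(x$ops)

#' Replay a scenario
#'
#' @param scenario a `"dcj_scenario"`.
#' @param from genome to start from (defaults to the scenario's source).
#' @return list of genomes visited, starting with `from`.
#' @export
replay_scenario <- function(scenario, from = scenario$source) {
  out <- list(canonical_genome(from))
  cur <- from
  for (op in scenario$ops) {
    cur <- apply_dcj(cur, op)
    out[[length(out) + 1L]] <- cur
  }
  out
}

#' Serialize / read a scenario
#'
#' One DCJ per line, `"u1-v1, u2-v2 -> w1-x1, w2-x2"` with extremities in
#' `gene.t` / `gene.h` form.
#'
#' @param scenario a `"dcj_scenario"`.
#' @return character vector of lines.
#' @export
write_scenario <- function(scenario) {
  vapply(scenario$ops, format_dcj, character(1))
}

#' Is a genome intermediate between two others?
#'
#' `I` lies on some shortest DCJ scenario between `P` and `Q` exactly when
#' `d(P,I) + d(I,Q) = d(P,Q)`; equivalently the total number of PI- and
#' QI-cycles equals `n + c(P,Q)` (see [count_intermediates()]).
#'
#' @param P,Q,I ordinary genomes with identical gene sets.
#' @return logical.
#' @export
is_intermediate <- function(P, Q, I) {
  check_same_ordinary(P, Q, I)
  dcj_distance(P, I) + dcj_distance(I, Q) == dcj_distance(P, Q)
}
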