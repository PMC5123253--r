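#' Breakpoint graph of two ordinary genomes
#'
#' The superposition of the adjacency matchings of `P` and `Q` on the common
#' extremity set. Since each extremity has exactly one P-edge and one Q-edge,
#' the graph decomposes into alternating PQ-cycles; their number `c(P,Q)`
#' drives the DCJ distance `n - c(P,Q)`.
#'
#' @param P,Q ordinary genomes on the same gene set.
#' @return an object of class `"breakpoint_graph"` with components
#'   `vertices`, `P_edges`, `Q_edges`, `pq_cycles` (list of extremity
#'   sequences, alternating P- then Q-edges), `c` (cycle count) and `n`.
#' @examples
#' bg <- breakpoint_graph(parse_genome("(+a+d-c-b)"), parse_genome("(+a-b+d+c)"))
#' bg$c
#' @export
breakpoint_graph <- function(P, Q) {
  check_same_ordinary(P, Q)
  genes <- gene_names(P)
  verts <- extremities(genes)
  pm <- matching_map(adjacencies(P))
  qm <- matching_map(adjacencies(Q))
  cycles <- list()
  seen <- stats::setNames(rep(FALSE, length(verts)), verts)
  for (v0 in verts) {
    if (seen[[v0]]) next
    cyc <- character(0)
    v <- v0
    use_p <- TRUE
    repeat {
      cyc <- c(cyc, v)
      seen[[v]] <- TRUE
      v <- if (use_p) pm[[v]] else qm[[v]]
      use_p <- !use_p
      if (v == v0) break
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  structure(list(
    vertices = verts,
    P_edges = adjacencies(P),
    Q_edges = adjacencies(Q),
    pq_cycles = cycles,
    c = length(cycles),
    n = length(genes)
  ), class = "breakpoint_graph")
}

check_same_ordinary <- function(...) {
  gs <- list(...)
  for (g in gs) {
    if (!inherits(g, "genome")) stop2("inputs must be genomes")
    if (!is_ordinary(g)) stop2("genome is not ordinary")
  }
  base <- gene_names(gs[[1L]])
  for (g in gs[-1L]) {
    if (!identical(gene_names(g), base))
      stop2("gene content must be restricted to genes present in all input genomes")
  }
  invisible(TRUE)
}

matching_map <- function(m) {
  as.list(c(stats::setNames(m[, 2L], m[, 1L]), stats::setNames(m[, 1L], m[, 2L])))
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("breakpoint graph: n =", x$n, ", c =", x$c,
      "( cycle half-lengths:", paste(lengths(x$pq_cycles) / 2L, collapse = " "), ")\n")
  invisible(x)
}

#' Contracted breakpoint graph of an all-duplicated genome
#'
#' For an all-duplicated genome `A`, the two copies of each gene are glued,
#' so the adjacency multiset of `A` projects onto the `2n` extremities of the
#' distinct genes. Every extremity then carries exactly two A-edge endpoints
#' (loops count twice), and the A-edges decompose uniquely into A-cycles.
#' `k` is the number of even A-cycles. If an ordinary genome `R` on the same
#' gene set is supplied, its adjacency matching is recorded as the R-edges
#' and classified into interedges (joining distinct A-cycles) and intraedges.
#'
#' @param A an all-duplicated genome.
#' @param R an optional ordinary genome on the same distinct-gene set.
#' @return an object of class `"contracted_breakpoint_graph"` with components
#'   `vertices`, `A_edges` (2-column matrix, multiset), `a_cycles` (list with
#'   `vertices` and `edges` per cycle, canonical traversal), `k`, `n`,
#'   `R_edges` (or `NULL`) and `cycle_of` (named vector: A-cycle index of
#'   each extremity).
#' @examples
#' cbg <- contracted_breakpoint_graph(parse_genome("(+a+c-b-d)(+a-b)(+c+d)"))
#' lengths(lapply(cbg$a_cycles, `[[`, "vertices"))
#' @export
contracted_breakpoint_graph <- function(A, R = NULL) {
  if (!inherits(A, "genome")) stop2("A must be a genome")
  if (!is_all_duplicated(A)) stop2("A is not all-duplicated")
  genes <- gene_names(A)
  verts <- extremities(genes)
  a_edges <- adjacencies(A)
  stopifnot(nrow(a_edges) == 2L * length(genes))
  cycles <- extract_degree2_cycles(verts, a_edges)
  lens <- vapply(cycles, function(cy) length(cy$vertices), integer(1))
  cycle_of <- integer(length(verts))
  names(cycle_of) <- verts
  for (i in seq_along(cycles)) cycle_of[cycles[[i]]$vertices] <- i
  r_edges <- NULL
  if (!is.null(R)) {
    if (!inherits(R, "genome") || !is_ordinary(R)) stop2("R must be an ordinary genome")
    if (!identical(gene_names(R), genes))
      stop2("gene content must be restricted to genes present in all input genomes")
    r_edges <- adjacencies(R)
  }
  structure(list(
    vertices = verts,
    A_edges = a_edges,
    a_cycles = cycles,
    k = sum(lens %% 2L == 0L),
    n = length(genes),
    R_edges = r_edges,
    cycle_of = cycle_of
  ), class = "contracted_breakpoint_graph")
}

#' @export
print.contracted_breakpoint_graph <- function(x, ...) {
  lens <- vapply(x$a_cycles, function(cy) length(cy$vertices), integer(1))
  cat("contracted breakpoint graph: n =", x$n, ", k =", x$k,
      "( A-cycle lengths:", paste(lens, collapse = " "), ")",
      if (is.null(x$R_edges)) "without R-edges\n" else "with R-edges\n")
  invisible(x)
}

# Decompose a multigraph in which every vertex has degree exactly 2 (a loop
# counting as degree 2) into its edge-disjoint cycles. Traversal is
# deterministic: each cycle starts at its smallest vertex and takes the
# smallest available (neighbour, edge index) step first, which also fixes
# the canonical "clockwise" orientation used elsewhere.
extract_degree2_cycles <- function(verts, edges) {
  ne <- nrow(edges)
  # incidence: for each vertex, the (edge, endpoint-slot) pairs at it
  inc <- stats::setNames(vector("list", length(verts)), verts)
  for (i in seq_len(ne)) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    inc[[u]] <- rbind(inc[[u]], c(i, 1L))
    inc[[v]] <- rbind(inc[[v]], c(i, 2L))
  }
  deg <- vapply(inc, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  if (!all(deg == 2L)) stop2("A-edges must give every extremity degree exactly 2")
  used <- rep(FALSE, ne)
  cycles <- list()
  for (v0 in verts) {
    pend <- inc[[v0]][!used[inc[[v0]][, 1L]], , drop = FALSE]
    if (nrow(pend) == 0L) next
    # pick the first edge deterministically: smaller opposite vertex, then id
    opp <- vapply(seq_len(nrow(pend)), function(j) {
      e <- pend[j, 1L]
      edges[e, 3L - pend[j, 2L]]
    }, character(1))
    first <- pend[corder(opp, pend[, 1L])[1L], ]
    cyc_v <- character(0)
    cyc_e <- integer(0)
    v <- v0
    e <- first[1L]
    repeat {
      cyc_v <- c(cyc_v, v)
      cyc_e <- c(cyc_e, e)
      used[e] <- TRUE
      # move across edge e to its other endpoint (loops stay put)
      ends <- edges[e, ]
      v <- if (ends[1L] == v && ends[2L] != v) ends[2L]
           else if (ends[2L] == v && ends[1L] != v) ends[1L]
           else v  # loop
      if (v == v0 && all(used[inc[[v0]][, 1L]])) break
      cand <- inc[[v]][!used[inc[[v]][, 1L]], , drop = FALSE]
      if (nrow(cand) == 0L) break
      e <- cand[corder(cand[, 1L])[1L], 1L]
    }
    cycles[[length(cycles) + 1L]] <- list(vertices = cyc_v, edges = cyc_e)
  }
  cycles
}
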