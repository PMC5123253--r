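#' Solve the genome halving problem
#'
#' For an all-duplicated genome `A`, returns an ordinary genome `R`
#' minimizing the DCJ distance between `A` and the doubled genome `2R`. The
#' optimum equals `n - k` (with `n` distinct genes and `k` even A-cycles),
#' attained exactly when the maximal AR-cycle decomposition of the doubled
#' contracted breakpoint graph has `n + k` cycles. The construction makes
#' the contracted breakpoint graph R-noncrossing: consecutive-pair chords
#' inside every even A-cycle, and odd A-cycles paired in canonical order with
#' a single interedge joining their smallest vertices plus consecutive-pair
#' chords on the remaining vertices.
#'
#' @param A an all-duplicated genome.
#' @return an ordinary [genome()] solving the halving problem for `A`.
#' @examples
#' solve_ghp(parse_genome("(+a-a+b-b)"))
#' @export
solve_ghp <- function(A) {
  cbg <- contracted_breakpoint_graph(A)
  lens <- vapply(cbg$a_cycles, function(cy) length(cy$vertices), integer(1))
  pairs <- list()
  add_pairs <- function(vs) {
    # consecutive-pair chords v1-v2, v3-v4, ... (noncrossing by construction)
    if (length(vs) %% 2L != 0L) stop2("internal: odd vertex run")
    for (i in seq(1L, length(vs), by = 2L))
      pairs[[length(pairs) + 1L]] <<- c(vs[i], vs[i + 1L])
  }
  for (cy in cbg$a_cycles[lens %% 2L == 0L]) add_pairs(cy$vertices)
  odd <- cbg$a_cycles[lens %% 2L == 1L]
  if (length(odd) > 0L) {
    starts <- vapply(odd, function(cy) cy$vertices[1L], character(1))
    odd <- odd[corder(starts)]
    for (i in seq(1L, length(odd), by = 2L)) {
      v1 <- odd[[i]]$vertices
      v2 <- odd[[i + 1L]]$vertices
      pairs[[length(pairs) + 1L]] <- c(v1[1L], v2[1L])  # interedge
      if (length(v1) > 1L) add_pairs(v1[-1L])
      if (length(v2) > 1L) add_pairs(v2[-1L])
    }
  }
  genome_from_matching(pairs)
}

#' Genome halving distance
#'
#' The minimal DCJ distance from `A` to any doubled genome:
#' `2n - (n + k) = n - k`.
#'
#' @param A an all-duplicated genome.
#' @return integer.
#' @export
ghp_distance <- function(A) {
  cbg <- contracted_breakpoint_graph(A)
  cbg$n - cbg$k
}

#' R-noncrossing test
#'
#' A contracted breakpoint graph with R-edges is R-noncrossing when every
#' connected component of the A-cycle/R-edge superposition is either a
#' single even A-cycle with noncrossing chords, or a pair of odd A-cycles
#' joined by exactly one interedge with noncrossing chords inside each cycle.
#' Two chords `{i,j}` and `{p,q}` on one cycle (positions along the cycle)
#' cross iff exactly one of `p`, `q` lies strictly between `i` and `j`
#' cyclically.
#'
#' @param cbg a [contracted_breakpoint_graph()] with `R_edges`.
#' @return logical.
#' @export
is_r_noncrossing <- function(cbg) {
  stopifnot(inherits(cbg, "contracted_breakpoint_graph"))
  if (is.null(cbg$R_edges)) stop2("missing R_edges")
  lens <- vapply(cbg$a_cycles, function(cy) length(cy$vertices), integer(1))
  nc <- length(cbg$a_cycles)
  r_cycles <- cbind(cbg$cycle_of[cbg$R_edges[, 1L]], cbg$cycle_of[cbg$R_edges[, 2L]])
  inter <- r_cycles[, 1L] != r_cycles[, 2L]
  # components over A-cycles induced by interedges
  uf <- uf_new(nc)
  for (r in which(inter)) uf <- uf_union(uf, r_cycles[r, 1L], r_cycles[r, 2L])
  comp <- uf_classes(uf)
  for (cmp in unique(comp)) {
    cyc_idx <- which(comp == cmp)
    n_inter <- sum(inter & comp[r_cycles[, 1L]] == cmp)
    if (length(cyc_idx) == 1L) {
      if (lens[cyc_idx] %% 2L != 0L) return(FALSE)
      if (n_inter != 0L) return(FALSE)
    } else if (length(cyc_idx) == 2L) {
      if (any(lens[cyc_idx] %% 2L != 1L)) return(FALSE)
      if (n_inter != 1L) return(FALSE)
    } else {
      return(FALSE)
    }
    for (ci in cyc_idx) {
      vs <- cbg$a_cycles[[ci]]$vertices
      pos <- stats::setNames(seq_along(vs), vs)
      intra <- which(!inter & r_cycles[, 1L] == ci)
      if (length(intra) >= 2L) {
        chords <- cbind(pos[cbg$R_edges[intra, 1L]], pos[cbg$R_edges[intra, 2L]])
        if (chords_cross_any(chords, length(vs))) return(FALSE)
      }
    }
  }
  TRUE
}

chords_cross_any <- function(chords, n) {
  m <- nrow(chords)
  between <- function(x, i, j) {
    # strictly between i and j going cyclically i -> j
    if (i < j) x > i & x < j else x > i | x < j
  }
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      i <- chords[a, 1L]; j <- chords[a, 2L]
      p <- chords[b, 1L]; q <- chords[b, 2L]
      if (xor(between(p, i, j), between(q, i, j))) return(TRUE)
    }
  }
  FALSE
}

#' Maximal AR-cycle decomposition size, by brute force
#'
#' Exact `c_max` of the doubled contracted breakpoint graph: at every
#' extremity there are two A-edge ends and two R-edge-copy ends, and an
#' AR-cycle decomposition corresponds to choosing one of the two A-end/R-end
#' pairings per extremity. All `2^(2n)` choices are enumerated and the
#' resulting alternating-cycle counts maximized. A desk-scale oracle, never
#' meant for large inputs.
#'
#' @param A an all-duplicated genome.
#' @param R an ordinary genome on the same distinct-gene set.
#' @param max_n refuse instances with more than this many distinct genes.
#' @return integer `c_max`.
#' @export
cmax_bruteforce <- function(A, R, max_n = 8L) {
  cbg <- contracted_breakpoint_graph(A, R)
  if (cbg$n > max_n) stop2("instance too large for oracle")
  verts <- cbg$vertices
  nv <- length(verts)
  # A-edge ends: 2 per edge; index ends 1..2*ne with end (e,slot)
  ae <- cbg$A_edges
  ne <- nrow(ae)
  a_end_vertex <- c(ae[, 1L], ae[, 2L])          # end i at this vertex
  other_a_end <- c(ne + seq_len(ne), seq_len(ne)) # the opposite end of the edge
  # R-edge copies: for vertex v with partner w, its two R-ends lead to w
  rp <- matching_map(cbg$R_edges)
  a_ends_at <- split(seq_len(2L * ne), a_end_vertex)[verts]
  stopifnot(all(lengths(a_ends_at) == 2L))
  vi <- stats::setNames(seq_len(nv), verts)
  best <- 0L
  nbits <- nv
  for (mask in 0:(2^nbits - 1L)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(nbits - 1L)), 1L) == 1L
    # pairing at vertex v: A-ends (x1,x2), R-copies (1,2):
    #   bits FALSE: x1<->copy1, x2<->copy2 ; TRUE: swapped.
    # Cycle successor on A-ends: from A-end x (at v) take its paired R-copy
    # to partner w; at w the A-end paired with the same copy index continues.
    succ <- integer(2L * ne)
    for (v in verts) {
      ends_v <- a_ends_at[[v]]
      w <- rp[[v]]
      ends_w <- a_ends_at[[w]]
      bv <- bits[vi[[v]]]; bw <- bits[vi[[w]]]
      # Entering v along an A-edge means arriving at A-end x in ends_v; we
      # then leave via x's paired R-copy to w, arriving at the A-end of w
      # paired with that copy, and continue across that A-edge.
      for (idx in 1:2) {
        x <- ends_v[idx]
        copy <- if (!bv) idx else 3L - idx
        cw <- if (!bw) copy else 3L - copy
        succ[x] <- other_a_end[ends_w[cw]]
      }
    }
    # count orbits of: A-end x -> succ[x]
    used <- rep(FALSE, 2L * ne)
    cnt <- 0L
    for (x in seq_len(2L * ne)) {
      if (used[x]) next
      cnt <- cnt + 1L
      y <- x
      repeat {
        used[y] <- TRUE
        y <- succ[y]
        if (used[y]) break
      }
    }
    # each AR-cycle is traversed once in each direction: orbits / 2
    if (cnt %/% 2L > best) best <- cnt %/% 2L
  }
  best
}

#' Maximal ht-decomposition size over orientations
#'
#' Maximizes the AR-cycle count of [ht_decomposition()] over all
#' `2^(#A-cycles)` orientations. Always a lower bound on
#' [cmax_bruteforce()]; equality holds whenever `R` solves the halving
#' problem for `A` (the orientation achieving the maximal decomposition is
#' found by search, as no constructive rule is available).
#'
#' @inheritParams cmax_bruteforce
#' @return integer.
#' @export
cmax_via_orientations <- function(A, R) {
  cbg <- contracted_breakpoint_graph(A, R)
  nc <- length(cbg$a_cycles)
  best <- 0L
  for (mask in 0:(2^nc - 1L)) {
    o <- bitwAnd(bitwShiftR(mask, 0:(nc - 1L)), 1L) == 1L
    cnt <- length(ht_decomposition(cbg, o))
    if (cnt > best) best <- cnt
  }
  best
}
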