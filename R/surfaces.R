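#' Polygon collections
#'
#' A polygon collection is an ordered list of oriented polygons; each polygon
#' is a cyclic sequence of labelled sides (the stored order is the
#' orientation, read "clockwise"). Sides carry consecutive global integer
#' ids, polygon by polygon.
#'
#' @param label_lists list of character vectors: the side labels of each
#'   polygon in cyclic orientation order. Labels need not be unique.
#' @return an object of class `"polygon_collection"` with components
#'   `polygons` (list of integer side-id vectors), `labels` (character vector
#'   indexed by side id), `poly_of` (polygon index per side),
#'   `next_side`/`prev_side` (cyclic successor/predecessor per side).
#' @examples
#' polygon_collection(list(c("s1", "s2", "s3", "s4")))
#' @export
polygon_collection <- function(label_lists) {
  if (!is.list(label_lists) || length(label_lists) == 0L)
    stop2("need at least one polygon")
  sizes <- lengths(label_lists)
  if (any(sizes == 0L)) stop2("every polygon must be non-empty")
  nsides <- sum(sizes)
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  polygons <- lapply(seq_along(sizes), function(i) offs[i] + seq_len(sizes[i]))
  labels <- as.character(unlist(label_lists))
  poly_of <- rep(seq_along(sizes), sizes)
  nxt <- integer(nsides)
  prv <- integer(nsides)
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    nxt[p] <- c(p[-1L], p[1L])
    prv[p] <- c(p[length(p)], p[-length(p)])
  }
  structure(list(polygons = polygons, labels = labels, poly_of = poly_of,
                 next_side = nxt, prev_side = prv, n_sides = nsides),
            class = "polygon_collection")
}

#' @export
print.polygon_collection <- function(x, ...) {
  cat("polygon collection:", length(x$polygons), "polygon(s),",
      x$n_sides, "sides\n")
  invisible(x)
}

check_matching <- function(pc, m) {
  m <- matrix(as.integer(m), ncol = 2)
  if (nrow(m) > 0L) {
    if (any(m < 1L | m > pc$n_sides)) stop2("matching references unknown sides")
    if (any(m[, 1L] == m[, 2L])) stop2("side matching must be fixed-point-free")
    if (anyDuplicated(c(m))) stop2("each side may appear in at most one pair")
    swap <- m[, 1L] > m[, 2L]
    tmp <- m[swap, 1L]; m[swap, 1L] <- m[swap, 2L]; m[swap, 2L] <- tmp
    m <- m[corder(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  m
}

#' Glue a polygon collection along a side matching
#'
#' Performs the orientable (head-to-tail) gluing: for matched sides `s`, `t`
#' the corner following `s` in its polygon's orientation is identified with
#' the corner preceding `t`, and vice versa. Graph vertices are the resulting
#' corner classes, edges the matched pairs, faces the polygons. With a
#' partial matching the unmatched sides partition into boundary walks
#' (holes) and every component is a surface with boundary. Per component the
#' Euler relation `v - (e + e_boundary) + f = 2 - 2g - h` determines the
#' genus, where `e_boundary` counts unmatched sides (the boundary 1-cells of
#' the complex).
#'
#' @param pc a [polygon_collection()].
#' @param matching a 2-column integer matrix of side-id pairs (possibly with
#'   zero rows); need not be perfect.
#' @return an object of class `"embedded_graph"`; see Details.
#' @details The returned object carries `pc`, `matching`, `vertex_class`
#'   (corner-class index per corner, where corner `s` is the corner at the
#'   head of side `s`), `components` (a data.frame with one row per connected
#'   component: `v`, `e` glued edges, `e_boundary`, `f`, `h`, `g`), `holes`
#'   (list of integer side-id walks with their component), and `edges`
#'   (data.frame of the multigraph view: one row per matched pair with
#'   endpoint vertex classes `u`, `v`).
#' @examples
#' pc <- polygon_collection(list(paste0("s", 1:4)))
#' glue(pc, rbind(c(1L, 3L), c(2L, 4L)))$components  # square -> torus
#' @export
glue <- function(pc, matching) {
  stopifnot(inherits(pc, "polygon_collection"))
  m <- check_matching(pc, matching)
  S <- pc$n_sides
  partner <- rep(NA_integer_, S)
  if (nrow(m) > 0L) {
    partner[m[, 1L]] <- m[, 2L]
    partner[m[, 2L]] <- m[, 1L]
  }
  # corner classes: corner s = head corner of side s = tail corner of next(s)
  uf <- uf_new(S)
  for (r in seq_len(nrow(m))) {
    s <- m[r, 1L]; t <- m[r, 2L]
    uf <- uf_union(uf, s, pc$prev_side[t])   # head(s) ~ tail(t)
    uf <- uf_union(uf, pc$prev_side[s], t)   # tail(s) ~ head(t)
  }
  cls_raw <- uf_classes(uf)
  cls <- match(cls_raw, unique(cls_raw))
  # component structure over polygons
  np <- length(pc$polygons)
  pf <- uf_new(np)
  for (r in seq_len(nrow(m)))
    pf <- uf_union(pf, pc$poly_of[m[r, 1L]], pc$poly_of[m[r, 2L]])
  pcls_raw <- uf_classes(pf)
  pcls <- match(pcls_raw, unique(pcls_raw))
  ncomp <- max(pcls)
  # boundary walks over unmatched sides
  unmatched <- which(is.na(partner))
  holes <- list()
  if (length(unmatched) > 0L) {
    succ <- function(s) {
      x <- pc$next_side[s]
      while (!is.na(partner[x])) x <- pc$next_side[partner[x]]
      x
    }
    visited <- rep(FALSE, S)
    for (s0 in unmatched) {
      if (visited[s0]) next
      walk <- integer(0)
      s <- s0
      repeat {
        walk <- c(walk, s)
        visited[s] <- TRUE
        s <- succ(s)
        if (s == s0) break
      }
      holes[[length(holes) + 1L]] <- list(sides = walk,
                                          component = pcls[pc$poly_of[s0]])
    }
  }
  # per-component bookkeeping
  comp_of_side <- pcls[pc$poly_of]
  comp_of_class <- integer(max(cls))
  comp_of_class[cls] <- comp_of_side          # all corners of a class share a component
  edge_comp <- if (nrow(m) > 0L) comp_of_side[m[, 1L]] else integer(0)
  hole_comp <- vapply(holes, `[[`, integer(1), "component")
  comps <- data.frame(component = seq_len(ncomp))
  comps$v <- vapply(seq_len(ncomp), function(i) sum(comp_of_class == i), integer(1))
  comps$e <- vapply(seq_len(ncomp), function(i) sum(edge_comp == i), integer(1))
  comps$e_boundary <- vapply(seq_len(ncomp), function(i)
    sum(comp_of_side[unmatched] == i), integer(1))
  comps$f <- vapply(seq_len(ncomp), function(i) sum(pcls == i), integer(1))
  comps$h <- vapply(seq_len(ncomp), function(i) sum(hole_comp == i), integer(1))
  comps$g <- mapply(function(v, e, eb, f, h) genus_from_euler(v, e + eb, f, h),
                    comps$v, comps$e, comps$e_boundary, comps$f, comps$h)
  edges <- if (nrow(m) > 0L) {
    data.frame(edge = seq_len(nrow(m)),
               side1 = m[, 1L], side2 = m[, 2L],
               u = cls[pc$prev_side[m[, 1L]]],  # tail-corner class of side1
               v = cls[m[, 1L]],                # head-corner class of side1
               component = edge_comp)
  } else {
    data.frame(edge = integer(0), side1 = integer(0), side2 = integer(0),
               u = integer(0), v = integer(0), component = integer(0))
  }
  structure(list(pc = pc, matching = m, partner = partner,
                 vertex_class = cls, poly_component = pcls,
                 components = comps, holes = holes, edges = edges),
            class = "embedded_graph")
}

#' @rdname glue
#' @export
partial_glue <- function(pc, matching) {
  m <- check_matching(pc, matching)
  if (2L * nrow(m) >= pc$n_sides)
    stop2("partial_glue expects a non-perfect matching; use glue()")
  glue(pc, m)
}

#' @export
print.embedded_graph <- function(x, ...) {
  cat("embedded graph:", nrow(x$components), "component(s)\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Genus from the Euler relation
#'
#' For a connected embedded graph on an orientable surface with `v` vertices,
#' `e` edges (including boundary 1-cells when holes are present), `f` faces
#' and `h` holes, `v - e + f + h = 2 - 2g`.
#'
#' @param v,e,f,h non-negative integers.
#' @return the genus `g = (2 - v + e - f - h) / 2`.
#' @examples
#' genus_from_euler(5, 8, 3, 0)  # torus
#' genus_from_euler(1, 4, 1, 0)  # 2-torus
#' @export
genus_from_euler <- function(v, e, f, h = 0L) {
  gg <- 2L - v + e - f - h
  if (gg %% 2L != 0L || gg < 0L)
    stop2("not a valid orientable component (v=", v, " e=", e,
          " f=", f, " h=", h, ")")
  as.integer(gg / 2L)
}

#' Total genus and sphere check
#'
#' @param eg an `"embedded_graph"`.
#' @return `total_genus()`: sum of component genera. `is_all_spheres()`: TRUE
#'   iff every component has genus 0 and no holes.
#' @export
total_genus <- function(eg) sum(eg$components$g)

#' @rdname total_genus
#' @export
is_all_spheres <- function(eg) all(eg$components$g == 0L) && all(eg$components$h == 0L)

#' Polygon collection of a contracted breakpoint graph
#'
#' Each A-cycle with `k` edges becomes an oriented `k`-gon whose sides are
#' labelled by the cycle's vertices (extremities) in traversal order under
#' the orientation `o`; the R-matching on extremities induces the side
#' matching. Gluing this collection yields the embedded graph whose vertices
#' correspond one-to-one to the AR-cycles of the ht-decomposition for `o`.
#'
#' @param cbg a [contracted_breakpoint_graph()] with `R_edges`.
#' @param o logical vector, one flag per A-cycle: `FALSE` (default) keeps the
#'   canonical ("clockwise") traversal, `TRUE` reverses it.
#' @return list with components `pc` (a [polygon_collection()]) and
#'   `matching` (2-column integer matrix of side ids).
#' @export
polygons_from_cycles <- function(cbg, o = NULL) {
  stopifnot(inherits(cbg, "contracted_breakpoint_graph"))
  if (is.null(cbg$R_edges)) stop2("missing R_edges")
  o <- check_orientation(cbg, o)
  seqs <- oriented_cycle_vertices(cbg, o)
  pc <- polygon_collection(seqs)
  side_of <- stats::setNames(seq_len(pc$n_sides), pc$labels)
  m <- cbind(unname(side_of[cbg$R_edges[, 1L]]),
             unname(side_of[cbg$R_edges[, 2L]]))
  list(pc = pc, matching = check_matching(pc, m))
}

check_orientation <- function(cbg, o) {
  nc <- length(cbg$a_cycles)
  if (is.null(o)) o <- rep(FALSE, nc)
  if (length(o) != nc || !is.logical(o))
    stop2("orientation must be a logical vector with one flag per A-cycle")
  o
}

# Vertex sequences of the A-cycles under orientation o. Reversal keeps the
# starting vertex (the canonically smallest) and reverses the tour.
oriented_cycle_vertices <- function(cbg, o) {
  lapply(seq_along(cbg$a_cycles), function(i) {
    v <- cbg$a_cycles[[i]]$vertices
    if (o[i] && length(v) > 1L) v <- c(v[1L], rev(v[-1L]))
    v
  })
}

#' ht-decomposition of the doubled contracted breakpoint graph
#'
#' Doubling every R-edge makes each extremity incident to two A-edge ends and
#' two R-edge copies, so the graph decomposes into alternating AR-cycles.
#' The ht-decomposition for an orientation `o` is the unique decomposition in
#' which every R-edge joins the head of one directed A-edge to the tail of
#' another: after the A-edge ending at `v`, continue along `v`'s R-edge to
#' its partner `w` and then along the A-edge leaving `w`.
#'
#' @inheritParams polygons_from_cycles
#' @return list of AR-cycles, each a list with `a_edges` (matrix of directed
#'   A-edges, columns `from`/`to`).
#' @export
ht_decomposition <- function(cbg, o = NULL) {
  stopifnot(inherits(cbg, "contracted_breakpoint_graph"))
  if (is.null(cbg$R_edges)) stop2("missing R_edges")
  o <- check_orientation(cbg, o)
  seqs <- oriented_cycle_vertices(cbg, o)
  from <- unlist(lapply(seqs, function(v) v))
  to <- unlist(lapply(seqs, function(v) c(v[-1L], v[1L])))
  rp <- matching_map(cbg$R_edges)
  # successor of directed A-edge i (ending at to[i]): the edge leaving
  # R-partner(to[i])
  idx_from <- stats::setNames(seq_along(from), from)
  succ <- unname(idx_from[vapply(to, function(v) rp[[v]], character(1))])
  ne <- length(from)
  used <- rep(FALSE, ne)
  cycles <- list()
  for (i in seq_len(ne)) {
    if (used[i]) next
    path <- integer(0)
    j <- i
    repeat {
      path <- c(path, j)
      used[j] <- TRUE
      j <- succ[j]
      if (j == i) break
    }
    cycles[[length(cycles) + 1L]] <-
      list(a_edges = cbind(from = from[path], to = to[path]))
  }
  cycles
}

#' DCJ-surgeries on embedded graphs
#'
#' A surgery cuts two glued edges (matched side pairs) and re-glues the four
#' freed sides according to one of the two alternative pairings. It is the
#' embedded-graph counterpart of a DCJ acting on the matching genome.
#'
#' @param cut integer vector of length 2: indices into `eg$matching` rows.
#' @param reglue 2-column integer matrix: the new pairing of the 4 freed
#'   sides (must differ from the cut pairs).
#' @return `surgery()`: an object of class `"surgery"`.
#' @export
surgery <- function(cut, reglue) {
  cut <- as.integer(cut)
  if (length(cut) != 2L || cut[1L] == cut[2L]) stop2("cut must name two distinct edges")
  reglue <- matrix(as.integer(reglue), ncol = 2)
  if (nrow(reglue) != 2L) stop2("reglue must pair the 4 freed sides")
  structure(list(cut = csort_int(cut), reglue = reglue), class = "surgery")
}

csort_int <- function(x) sort(x)

#' @rdname surgery
#' @param eg an `"embedded_graph"`.
#' @param s a `"surgery"`.
#' @return `apply_surgery()`: the re-glued `"embedded_graph"` (polygons,
#'   faces and edge count unchanged).
#' @export
apply_surgery <- function(eg, s) {
  stopifnot(inherits(eg, "embedded_graph"), inherits(s, "surgery"))
  m <- eg$matching
  if (any(s$cut < 1L | s$cut > nrow(m))) stop2("invalid edge ids in cut")
  freed <- c(m[s$cut[1L], ], m[s$cut[2L], ])
  if (!identical(csort_int(c(s$reglue)), csort_int(freed)))
    stop2("reglue must repair exactly the 4 freed sides")
  old <- m[s$cut, , drop = FALSE]
  new <- check_matching(eg$pc, s$reglue)
  if (identical(check_matching(eg$pc, old), new)) stop2("reglue equals cut")
  m2 <- rbind(m[-s$cut, , drop = FALSE], new)
  glue(eg$pc, m2)
}

# The two alternative re-gluings for cutting matched pairs (a1,a2), (b1,b2).
surgery_reglues <- function(eg, cut) {
  a <- eg$matching[cut[1L], ]
  b <- eg$matching[cut[2L], ]
  list(rbind(c(a[1L], b[1L]), c(a[2L], b[2L])),
       rbind(c(a[1L], b[2L]), c(a[2L], b[1L])))
}

#' Translate between DCJ-surgeries and DCJs
#'
#' When the polygon sides are labelled with gene extremities (as produced by
#' [polygons_from_cycles()]), a surgery cutting side pairs corresponds to the
#' DCJ removing the matching R-adjacencies and adding the re-glued ones.
#'
#' @param eg an `"embedded_graph"` whose side labels are extremities.
#' @param s a `"surgery"` on `eg`.
#' @return `dcj_from_surgery()`: the corresponding [dcj_op()].
#' @export
dcj_from_surgery <- function(eg, s) {
  lab <- eg$pc$labels
  m <- eg$matching
  removed <- rbind(lab[m[s$cut[1L], ]], lab[m[s$cut[2L], ]])
  added <- rbind(lab[s$reglue[1L, ]], lab[s$reglue[2L, ]])
  dcj_op(removed, added)
}

#' @rdname dcj_from_surgery
#' @param op a [dcj_op()] whose removed adjacencies are present in `eg`'s
#'   matching (as label pairs).
#' @return `surgery_from_dcj()`: the corresponding `"surgery"`.
#' @export
surgery_from_dcj <- function(eg, op) {
  lab <- eg$pc$labels
  m <- eg$matching
  mkeys <- adj_key(lab[m[, 1L]], lab[m[, 2L]])
  cut <- vapply(1:2, function(i) {
    k <- adj_key(op$removed[i, 1L], op$removed[i, 2L])
    hit <- match(k, mkeys)
    if (is.na(hit)) stop2("removed adjacency not present in matching: ", k)
    hit
  }, integer(1))
  side_of <- stats::setNames(seq_along(lab), lab)
  reglue <- cbind(unname(side_of[op$added[, 1L]]), unname(side_of[op$added[, 2L]]))
  surgery(cut, reglue)
}

#' Read / write polygon-collection specifications
#'
#' JSON files with fields `polygons` (list of side-label lists in cyclic
#' orientation order) and `matching` (list of 2-element side-id pairs,
#' 1-based).
#'
#' @param path file path.
#' @return `read_polygon_spec()`: list with `pc` and `matching`.
#' @export
read_polygon_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(spec$polygons)) stop2("polygon spec needs a 'polygons' field")
  pc <- polygon_collection(lapply(spec$polygons, function(p) as.character(unlist(p))))
  mm <- if (is.null(spec$matching) || length(spec$matching) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    do.call(rbind, lapply(spec$matching, function(p) as.integer(unlist(p))))
  }
  list(pc = pc, matching = check_matching(pc, mm))
}

#' @rdname read_polygon_spec
#' @param pc a [polygon_collection()].
#' @param matching a side matching.
#' @export
write_polygon_spec <- function(pc, matching, path) {
  polys <- lapply(pc$polygons, function(ids) pc$labels[ids])
  m <- check_matching(pc, matching)
  pairs <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  jsonlite::write_json(list(polygons = polys, matching = pairs), path)
  invisible(path)
}
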