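#' Catalan numbers
#'
#' `C_k = choose(2k, k) / (k + 1)` counts, among much else, the noncrossing
#' perfect matchings on `2k` points -- equivalently the sphere gluings of a
#' `2k`-gon.
#'
#' @param k non-negative integer (vectorized).
#' @return exact integer-valued numeric.
#' @examples
#' catalan(0:5)
#' @export
catalan <- function(k) {
  if (any(k < 0)) stop2("k must be non-negative")
  vapply(k, function(ki) {
    num <- exact_choose(2 * ki, ki)
    stopifnot(num %% (ki + 1) == 0)
    num / (ki + 1)
  }, numeric(1))
}

#' Count sphere gluings by brute force
#'
#' Enumerates every perfect matching on the sides of the given polygons and
#' counts those whose gluing yields only spheres with the maximal possible
#' number of components (one per even-gon plus one per pair of odd-gons).
#' As in the halving correspondence -- where a solution genome only needs
#' *some* orientation of the A-cycles to realize the maximal decomposition --
#' a matching is counted when any assignment of per-polygon orientations
#' achieves the all-sphere maximum. (Reversing every polygon mirrors the
#' whole complex and preserves genus, so the first polygon's orientation can
#' be fixed; with a single polygon the flip is immaterial.) A desk-scale
#' oracle for the closed-form counts [catalan()] and [odd_pair_count()].
#'
#' @param polygon_sizes integer vector of side counts.
#' @param max_sides refuse instances with more than this many sides
#'   (13!! = 135135 matchings at the default 14).
#' @return integer count.
#' @export
sphere_gluing_count_bruteforce <- function(polygon_sizes, max_sides = 14L) {
  total <- sum(polygon_sizes)
  if (total %% 2L != 0L) stop2("total number of sides must be even")
  if (total > max_sides) stop2("too many sides for brute-force enumeration")
  k <- sum(polygon_sizes %% 2L == 0L)
  l2 <- sum(polygon_sizes %% 2L == 1L)
  if (l2 %% 2L != 0L) stop2("number of odd-gons must be even")
  max_comp <- k + l2 %/% 2L
  np <- length(polygon_sizes)
  # one polygon collection per flip subset (polygon 1 kept fixed); flipping
  # reverses a polygon's stored cyclic order while keeping side ids
  flips <- if (np == 1L) list(rep(FALSE, 1L)) else {
    lapply(0:(2^(np - 1L) - 1L), function(mask)
      c(FALSE, bitwAnd(bitwShiftR(mask, 0:(np - 2L)), 1L) == 1L))
  }
  base_labels <- lapply(seq_along(polygon_sizes), function(i)
    paste0("p", i, "s", seq_len(polygon_sizes[i])))
  pcs <- lapply(flips, function(fl) {
    polygon_collection(lapply(seq_along(base_labels), function(i)
      if (fl[i]) rev(base_labels[[i]]) else base_labels[[i]]))
  })
  # side id i in the unflipped numbering corresponds, in a flipped pc, to the
  # side carrying the same label
  side_maps <- lapply(pcs, function(pc)
    match(unlist(base_labels), pc$labels))
  count <- 0L
  for (m in enumerate_perfect_matchings(total)) {
    hit <- FALSE
    for (j in seq_along(pcs)) {
      mm <- cbind(side_maps[[j]][m[, 1L]], side_maps[[j]][m[, 2L]])
      eg <- glue(pcs[[j]], check_matching(pcs[[j]], mm))
      if (is_all_spheres(eg) && nrow(eg$components) == max_comp) {
        hit <- TRUE
        break
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

#' Sphere gluings of a pair of odd polygons
#'
#' Closed form for the number of ways to glue the sides of a `(2m+1)`-gon
#' and a `(2n+1)`-gon into a single sphere:
#' `T(m,n) = (2mn + m + n + 1) / (m + n + 1) * choose(2m+1, m) * choose(2n+1, n)`.
#' Exact integer arithmetic; symmetric in `m` and `n`.
#'
#' @param m,n non-negative integers.
#' @return exact integer-valued numeric.
#' @examples
#' odd_pair_count(1, 1)  # 15
#' @export
odd_pair_count <- function(m, n) {
  if (m < 0 || n < 0) stop2("m and n must be non-negative")
  num <- (2 * m * n + m + n + 1) * exact_choose(2 * m + 1, m) * exact_choose(2 * n + 1, n)
  den <- m + n + 1
  stopifnot(num %% den == 0)
  num / den
}

#' One-hole partial gluings of an odd polygon
#'
#' The number of ways to glue `k - l` disjoint pairs of sides of a
#' `(2k+1)`-gon so that the result is a sphere with a single hole (of length
#' `2l + 1`): `choose(2k+1, k-l)`.
#'
#' @param k,l integers with `0 <= l <= k`.
#' @return exact integer-valued numeric.
#' @export
one_hole_partial_count <- function(k, l) {
  if (l < 0 || l > k) stop2("need 0 <= l <= k")
  exact_choose(2 * k + 1, k - l)
}

# A-cycle length profile of an all-duplicated genome.
cycle_length_profile <- function(A) {
  cbg <- contracted_breakpoint_graph(A)
  lens <- vapply(cbg$a_cycles, function(cy) length(cy$vertices), integer(1))
  list(even = sort(lens[lens %% 2L == 0L]), odd = sort(lens[lens %% 2L == 1L]))
}

#' Count the solutions of the genome halving problem
#'
#' The number of ordinary genomes solving the halving problem for an
#' all-duplicated genome `A` depends only on its A-cycle length profile:
#' with even A-cycle lengths `2 n_1, ..., 2 n_k` and odd lengths
#' `2 m_1 + 1, ..., 2 m_{2l} + 1`, it equals
#' `prod(C_{n_i}) * sum over perfect matchings M of the odd-cycle indices of
#' prod_{(i,j) in M} T(m_i, m_j)`.
#'
#' @param A an all-duplicated genome.
#' @return exact integer-valued numeric.
#' @examples
#' count_ghp_solutions(parse_genome("(+a+c-b-d)(+a-b)(+c+d)"))  # 14
#' @export
count_ghp_solutions <- function(A) {
  prof <- cycle_length_profile(A)
  even_part <- prod(catalan(prof$even / 2L))
  if (length(prof$odd) == 0L) return(even_part)
  ms <- (prof$odd - 1L) / 2L
  total <- 0
  for (mm in enumerate_perfect_matchings(length(ms))) {
    total <- total + prod(vapply(seq_len(nrow(mm)), function(r)
      odd_pair_count(ms[mm[r, 1L]], ms[mm[r, 2L]]), numeric(1)))
  }
  even_part * total
}

#' Count intermediate genomes
#'
#' The genomes lying on some shortest DCJ scenario between `P` and `Q`
#' number `prod(C_{n_i})` where `2 n_i` are the PQ-cycle lengths of the
#' breakpoint graph.
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @return exact integer-valued numeric.
#' @examples
#' count_intermediates(parse_genome("(+a+d-c-b)"), parse_genome("(+a-b+d+c)"))
#' @export
count_intermediates <- function(P, Q) {
  bg <- breakpoint_graph(P, Q)
  half <- lengths(bg$pq_cycles) / 2L
  prod(catalan(half))
}

#' Enumerate intermediate genomes (test oracle)
#'
#' Enumerates all perfect matchings on the `2n` extremities, realizes each as
#' an ordinary genome, and keeps those that are intermediate between `P` and
#' `Q`. Exponential; intended as the independent check of
#' [count_intermediates()].
#'
#' @param P,Q ordinary genomes with identical gene sets.
#' @param max_n refuse instances with more than this many genes.
#' @return list of genomes.
#' @export
enumerate_intermediates <- function(P, Q, max_n = 6L) {
  check_same_ordinary(P, Q)
  if (n_genes(P) > max_n) stop2("instance too large for oracle")
  out <- list()
  for (g in all_ordinary_genomes(gene_names(P))) {
    if (is_intermediate(P, Q, g)) out[[length(out) + 1L]] <- g
  }
  out
}

#' Enumerate all ordinary genomes on a gene set
#'
#' One genome per perfect matching on the extremities.
#'
#' @param genes character vector of gene names.
#' @return list of genomes.
#' @export
all_ordinary_genomes <- function(genes) {
  exts <- extremities(genes)
  lapply(enumerate_perfect_matchings(length(exts)), function(m)
    genome_from_matching(cbind(exts[m[, 1L]], exts[m[, 2L]])))
}

#' Enumerate halving solutions (test oracle)
#'
#' All ordinary genomes `R` whose maximal AR-cycle decomposition attains
#' `n + k`; the brute-force counterpart of [count_ghp_solutions()].
#'
#' @param A an all-duplicated genome.
#' @param max_n refuse instances with more than this many distinct genes.
#' @return list of genomes.
#' @export
enumerate_ghp_solutions <- function(A, max_n = 4L) {
  if (!is_all_duplicated(A)) stop2("A is not all-duplicated")
  if (n_genes(A) > max_n) stop2("instance too large for oracle")
  cbg <- contracted_breakpoint_graph(A)
  target <- cbg$n + cbg$k
  Filter(function(R) cmax_bruteforce(A, R) == target,
         all_ordinary_genomes(gene_names(A)))
}
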