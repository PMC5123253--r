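#' Random ordinary genome
#'
#' A uniform random signed circular arrangement of `n` distinct genes
#' (named `a`, `b`, ... for `n <= 26`, `g1`, `g2`, ... beyond) into
#' `n_chromosomes` non-empty circular chromosomes.
#'
#' @param n number of genes (`n >= n_chromosomes >= 1`).
#' @param n_chromosomes number of chromosomes.
#' @param seed optional integer seed; the same seed reproduces the genome.
#' @return an ordinary [genome()].
#' @export
random_ordinary_genome <- function(n, n_chromosomes = 1L, seed = NULL) {
  if (n < n_chromosomes || n_chromosomes < 1L) stop2("need n >= n_chromosomes >= 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- default_gene_names(n)
  arrange_tokens(sample(genes), n_chromosomes)
}

default_gene_names <- function(n) {
  if (n <= 26L) letters[seq_len(n)] else paste0("g", seq_len(n))
}

# Split a shuffled token vector into n_chromosomes non-empty circular
# chromosomes with random signs.
arrange_tokens <- function(toks, n_chromosomes) {
  m <- length(toks)
  signs <- sample(c(-1L, 1L), m, replace = TRUE)
  cuts <- if (n_chromosomes > 1L) sort(sample(m - 1L, n_chromosomes - 1L)) else integer(0)
  bounds <- c(0L, cuts, m)
  chroms <- lapply(seq_len(n_chromosomes), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    list(genes = toks[idx], signs = signs[idx])
  })
  canonical_genome(genome(chroms))
}

#' Random all-duplicated genome
#'
#' A random arrangement of two copies of each of `n` genes.
#'
#' @inheritParams random_ordinary_genome
#' @return an all-duplicated [genome()].
#' @export
random_all_duplicated_genome <- function(n, n_chromosomes = 1L, seed = NULL) {
  if (2L * n < n_chromosomes || n_chromosomes < 1L)
    stop2("need 2n >= n_chromosomes >= 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- default_gene_names(n)
  arrange_tokens(sample(rep(genes, 2L)), n_chromosomes)
}

#' Doubled genome of an ordinary genome
#'
#' The all-duplicated genome a whole-genome duplication produces from `R`,
#' represented as two copies of each chromosome (the two possible duplicated
#' chromosome types share the same contracted genome graph, so this
#' representative is canonical).
#'
#' @param R an ordinary genome.
#' @return an all-duplicated [genome()], with `ghp_distance()` zero.
#' @export
doubled_genome <- function(R) {
  if (!inherits(R, "genome") || !is_ordinary(R)) stop2("R must be an ordinary genome")
  canonical_genome(genome(c(R$chromosomes, R$chromosomes)))
}

#' Random single-face torus instance
#'
#' Rejection-samples a pair `(A, B)` -- `A` all-duplicated with a single
#' A-cycle, `B` ordinary -- whose induced embedded graph is a connected
#' one-face graph of genus 1 (so `v = e - 1`). If sampling stalls, the
#' constructive fallback perturbs a halving solution of `A` with random DCJs
#' until the genus reaches 1.
#'
#' @param n number of distinct genes (`n >= 3`).
#' @param seed optional integer seed.
#' @param max_attempts sampling budget before switching to the constructive
#'   route.
#' @return list with `A`, `B` and the glued `eg`.
#' @export
random_torus_instance <- function(n, seed = NULL, max_attempts = 1000L) {
  if (n < 3L) stop2("need n >= 3")
  if (!is.null(seed)) set.seed(seed)
  A <- random_single_cycle_duplicated(n)
  build <- function(B) {
    cbg <- contracted_breakpoint_graph(A, B)
    pm <- polygons_from_cycles(cbg)
    glue(pm$pc, pm$matching)
  }
  for (i in seq_len(max_attempts)) {
    B <- random_ordinary_genome(n)
    eg <- build(B)
    if (eg$components$g[1L] == 1L) return(list(A = A, B = B, eg = eg))
  }
  # constructive fallback: random DCJ walk from a halving solution
  B <- solve_ghp(A)
  for (i in seq_len(max_attempts)) {
    nb <- dcj_neighbors(B)
    B <- nb[[sample(length(nb), 1L)]]
    eg <- build(B)
    if (eg$components$g[1L] == 1L) return(list(A = A, B = B, eg = eg))
  }
  stop2("sampling budget exceeded")
}

# All-duplicated genome whose contracted graph has one A-cycle (length 2n).
random_single_cycle_duplicated <- function(n, max_attempts = 2000L) {
  for (i in seq_len(max_attempts)) {
    A <- random_all_duplicated_genome(n)
    if (length(contracted_breakpoint_graph(A)$a_cycles) == 1L) return(A)
  }
  stop2("sampling budget exceeded while looking for a single-A-cycle genome")
}

#' Random single-face torus gluing of a polygon
#'
#' Samples perfect matchings on the sides of a single `2n`-gon until the
#' glued graph has genus 1 and satisfies the supplied predicate.
#'
#' @param n_sides even number of sides.
#' @param predicate function of the glued `"embedded_graph"` returning TRUE
#'   to accept.
#' @param seed optional integer seed.
#' @param max_attempts sampling budget.
#' @return the accepted `"embedded_graph"`.
#' @export
random_torus_polygon_gluing <- function(n_sides, predicate = function(eg) TRUE,
                                        seed = NULL, max_attempts = 20000L) {
  if (n_sides %% 2L != 0L) stop2("n_sides must be even")
  if (!is.null(seed)) set.seed(seed)
  pc <- polygon_collection(list(paste0("s", seq_len(n_sides))))
  for (i in seq_len(max_attempts)) {
    perm <- sample(n_sides)
    m <- matrix(perm, ncol = 2)
    eg <- glue(pc, check_matching(pc, m))
    if (eg$components$g[1L] == 1L && isTRUE(predicate(eg))) return(eg)
  }
  stop2("sampling budget exceeded")
}

#' Worked examples from the literature
#'
#' A registry of small named genomes used throughout the tests and
#' documentation: `fig1_A`/`fig1_R` (an all-duplicated genome on 7 genes and
#' a halving candidate), `fig2_P`/`fig2_Q` (an ordinary pair at DCJ distance
#' 3 with a single 8-edge breakpoint cycle) and `fig4_A`/`fig4_R` (a
#' duplicated genome with one 8-vertex A-cycle whose gluing against `R`
#' lands on a 2-torus).
#'
#' @return named list of genomes.
#' @export
paper_examples <- function() {
  list(
    fig1_A = parse_genome("(-a-b+g+d+f+g+e)(-a+c-f-c-b-d-e)"),
    fig1_R = parse_genome("(-a-b-d-g+f-c-e)"),
    fig2_P = parse_genome("(+a+d-c-b)"),
    fig2_Q = parse_genome("(+a-b+d+c)"),
    fig4_A = parse_genome("(+a+c-b-d)(+a-b)(+c+d)"),
    fig4_R = parse_genome("(+a-c-b+d)")
  )
}
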