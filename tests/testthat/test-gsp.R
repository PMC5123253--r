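mg_from <- function(u, v) data.frame(edge = seq_along(u), u = u, v = v)

test_that("shortest even cycles are found in multigraphs with loops and parallels", {
  # two parallel edges: even cycle of length 2
  expect_equal(shortest_even_cycle(mg_from(c(1, 1), c(2, 2)))$len, 2L)
  # triangle: no even cycle
  expect_null(shortest_even_cycle(mg_from(c(1, 2, 3), c(2, 3, 1))))
  # square with one diagonal: the even 4-cycle wins over the two triangles
  sq <- mg_from(c(1, 2, 3, 4, 1), c(2, 3, 4, 1, 3))
  ec <- shortest_even_cycle(sq)
  expect_equal(ec$len, 4L)
  expect_setequal(ec$vertices, 1:4)
  # a loop is odd, not an even cycle
  expect_null(shortest_even_cycle(mg_from(1, 1)))
})

test_that("odd cycle pairs sharing one vertex are found", {
  # two loops at one vertex
  op <- shortest_odd_cycle_pair(mg_from(c(1, 1), c(1, 1)))
  expect_equal(op$total, 2L)
  # figure-eight of two triangles
  fig8 <- mg_from(c(1, 2, 3, 1, 4, 5), c(2, 3, 1, 4, 5, 1))
  op8 <- shortest_odd_cycle_pair(fig8)
  expect_equal(op8$total, 6L)
  # a single even cycle has no odd pair
  expect_null(shortest_odd_cycle_pair(mg_from(c(1, 2, 3, 4), c(2, 3, 4, 1))))
  # loops at different vertices share no vertex
  expect_null(shortest_odd_cycle_pair(mg_from(c(1, 2, 3), c(1, 2, 3))[c(1, 2), ]))
})

test_that("the square-to-torus gluing is solved with one surgery", {
  sq <- polygon_collection(list(paste0("s", 1:4)))
  eg <- glue(sq, rbind(c(1L, 3L), c(2L, 4L)))  # v=1, two loops at one vertex
  sol <- solve_gsp_torus(eg)
  expect_equal(sol$l, 1L)
  expect_true(is_all_spheres(sol$result))
})

test_that("parallel-pair instances are solved with one surgery", {
  set.seed(71)
  eg <- random_torus_polygon_gluing(8L, function(eg) {
    mg <- multigraph_view(eg)
    q <- dcjtopo:::min_cycle_quantity(mg)
    !is.null(q) && q == 2L
  })
  sol <- solve_gsp_torus(eg)
  expect_equal(sol$l, 1L)
  expect_true(is_all_spheres(sol$result))
})

test_that("solver length matches exhaustive surgery search on small tori", {
  # exhaustive minimal surgery sequences by breadth-first search over matchings
  exhaustive_min <- function(eg, cap = 3L) {
    key <- function(m) paste(t(m), collapse = ",")
    frontier <- list(eg)
    seen <- key(eg$matching)
    for (d in 0:cap) {
      for (g in frontier) if (is_all_spheres(g)) return(d)
      nxt <- list()
      for (g in frontier) {
        ne <- nrow(g$matching)
        for (cut in utils::combn(ne, 2L, simplify = FALSE)) {
          for (rg in dcjtopo:::surgery_reglues(g, cut)) {
            g2 <- apply_surgery(g, surgery(cut, rg))
            k2 <- key(g2$matching)
            if (!k2 %in% seen) {
              seen <- c(seen, k2)
              nxt[[length(nxt) + 1L]] <- g2
            }
          }
        }
      }
      frontier <- nxt
    }
    stop("cap exceeded")
  }
  set.seed(73)
  sizes <- c(6L, 6L, 8L, 8L)
  for (ns in sizes) {
    eg <- random_torus_polygon_gluing(ns, function(e) nrow(e$components) == 1L)
    sol <- solve_gsp_torus(eg)
    expect_true(is_all_spheres(sol$result))
    expect_equal(sol$l, exhaustive_min(eg))
    q <- dcjtopo:::min_cycle_quantity(multigraph_view(eg))
    expect_equal(sol$l, q %/% 2L)
  }
})

test_that("reduction steps keep a single-face torus and shrink the tracked cycle", {
  set.seed(79)
  eg <- random_torus_polygon_gluing(12L, function(e) {
    q <- dcjtopo:::min_cycle_quantity(multigraph_view(e))
    !is.null(q) && q >= 4L
  })
  q0 <- dcjtopo:::min_cycle_quantity(multigraph_view(eg))
  sol <- solve_gsp_torus(eg)
  expect_equal(sol$l, q0 %/% 2L)
  cur <- eg
  for (i in seq_along(sol$surgeries)) {
    cur <- apply_surgery(cur, sol$surgeries[[i]])
    expect_equal(sum(cur$components$f), 1L)
    if (i < length(sol$surgeries)) {
      expect_equal(cur$components$g, 1L)
      expect_equal(dcjtopo:::min_cycle_quantity(multigraph_view(cur)), q0 - 2L * i)
    } else {
      expect_true(is_all_spheres(cur))
    }
  }
})

test_that("non-torus inputs are rejected", {
  sq <- polygon_collection(list(paste0("s", 1:4)))
  sphere <- glue(sq, rbind(c(1L, 2L), c(3L, 4L)))
  expect_error(solve_gsp_torus(sphere), "genus")
  pm <- polygons_from_cycles(contracted_breakpoint_graph(fx$fig4_A, fx$fig4_R))
  two_torus <- glue(pm$pc, pm$matching)
  expect_error(solve_gsp_torus(two_torus), "genus")
})

test_that("solve_rgghp_torus returns an optimal halving solution", {
  for (i in 1:4) {
    inst <- random_torus_instance(4L, seed = 300L + i)
    res <- solve_rgghp_torus(inst$A, inst$B)
    cbg <- contracted_breakpoint_graph(inst$A)
    expect_equal(cmax_bruteforce(inst$A, res$R), cbg$n + cbg$k)
    expect_equal(dcj_distance(inst$B, res$R), res$l)
    expect_length(res$scenario$ops, res$l)
    states <- replay_scenario(res$scenario, from = inst$B)
    expect_true(genomes_equal(states[[length(states)]], res$R))
    # optimality against exhaustive enumeration of all halving solutions
    dmin <- min(vapply(enumerate_ghp_solutions(inst$A),
                       function(R) dcj_distance(inst$B, R), integer(1)))
    expect_equal(res$l, dmin)
  }
})

test_that("sphere inputs short-circuit: B itself is a halving solution", {
  A <- random_all_duplicated_genome(4L, seed = 91L)
  # make sure we have a single A-cycle
  while (length(contracted_breakpoint_graph(A)$a_cycles) != 1L)
    A <- random_all_duplicated_genome(4L, seed = sample.int(10000L, 1L))
  B <- solve_ghp(A)
  res <- solve_rgghp_torus(A, B)
  expect_equal(res$l, 0L)
  expect_true(genomes_equal(res$R, B))
  # genus-2 and multi-A-cycle inputs are rejected with specific reasons
  expect_error(solve_rgghp_torus(fx$fig4_A, fx$fig4_R), "genus 2")
  expect_error(solve_rgghp_torus(parse_genome("(+a-a+b-b)"), parse_genome("(+a-b)")),
               "single A-cycle")
})

test_that("solve_igmp_torus returns an optimal intermediate genome", {
  for (i in 1:3) {
    n <- 4L
    pr <- random_pair(n, 700L + i)
    if (breakpoint_graph(pr$P, pr$Q)$c != 1L) next
    T_out <- random_ordinary_genome(n, seed = 800L + i)
    res <- tryCatch(solve_igmp_torus(pr$P, pr$Q, T_out), error = function(e) NULL)
    if (is.null(res)) next  # genus > 1: outside the torus case
    expect_true(is_intermediate(pr$P, pr$Q, res$I))
    expect_equal(dcj_distance(T_out, res$I), res$l)
    dmin <- min(vapply(enumerate_intermediates(pr$P, pr$Q),
                       function(I) dcj_distance(T_out, I), integer(1)))
    expect_equal(res$l, dmin)
  }
  # an already intermediate outgroup yields an empty scenario
  res0 <- solve_igmp_torus(fx$fig2_P, fx$fig2_Q, fx$fig2_P)
  expect_equal(res0$l, 0L)
  expect_true(genomes_equal(res0$I, fx$fig2_P))
})
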