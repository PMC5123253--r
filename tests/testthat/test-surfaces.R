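test_that("genus_from_euler recovers the genus and rejects bad data", {
  expect_equal(genus_from_euler(5, 8, 3, 0), 1L)
  expect_equal(genus_from_euler(1, 4, 1, 0), 2L)
  expect_equal(genus_from_euler(2, 1, 1, 0), 0L)
  expect_equal(genus_from_euler(11, 10, 1, 0), 0L)
  expect_error(genus_from_euler(2, 2, 1, 0), "not a valid orientable")
  expect_error(genus_from_euler(10, 1, 1, 0), "not a valid orientable")
})

test_that("classic gluings land on the expected surfaces", {
  sq <- polygon_collection(list(paste0("s", 1:4)))
  torus <- glue(sq, rbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(torus$components[, c("v", "e", "f", "g")],
               data.frame(v = 1L, e = 2L, f = 1L, g = 1L))
  bigon <- glue(polygon_collection(list(c("x", "y"))), rbind(c(1L, 2L)))
  expect_equal(bigon$components$g, 0L)
  expect_equal(bigon$components$v, 2L)
  # two monogons glue to a sphere
  mono <- glue(polygon_collection(list("a", "b")), rbind(c(1L, 2L)))
  expect_equal(mono$components$g, 0L)
  expect_error(glue(sq, rbind(c(1L, 9L))), "unknown sides")
  expect_error(glue(sq, rbind(c(1L, 1L))), "fixed-point-free")
})

test_that("partial gluings expose holes and satisfy the Euler relation", {
  sq <- polygon_collection(list(paste0("s", 1:4)))
  disc <- partial_glue(sq, matrix(integer(0), ncol = 2))
  expect_equal(disc$components$h, 1L)
  expect_equal(disc$components$g, 0L)
  expect_length(disc$holes[[1L]]$sides, 4L)

  tri <- polygon_collection(list(c("p", "q", "r")))
  cone <- partial_glue(tri, rbind(c(1L, 2L)))
  expect_equal(cone$components$h, 1L)
  expect_equal(cone$components$g, 0L)
  expect_length(cone$holes[[1L]]$sides, 1L)

  # Euler consistency over random partial gluings of an 8-gon
  oct <- polygon_collection(list(paste0("s", 1:8)))
  set.seed(42)
  for (i in 1:25) {
    k <- sample(0:4, 1L)
    m <- if (k == 0L) matrix(integer(0), ncol = 2) else matrix(sample(8L, 2L * k), ncol = 2)
    eg <- glue(oct, m)
    comp <- eg$components
    # the full cell complex (boundary sides included) satisfies Euler exactly
    chi <- comp$v - (comp$e + comp$e_boundary) + comp$f
    expect_equal(chi, 2L - 2L * comp$g - comp$h)
    expect_true(all(comp$g >= 0L))
  }
})

test_that("gluing one pair of sides from two different holes adds a handle", {
  oct <- polygon_collection(list(paste0("s", 1:8)))
  set.seed(99)
  checked <- 0L
  for (i in 1:40) {
    k <- sample(1:3, 1L)
    m <- matrix(sample(8L, 2L * k), ncol = 2)
    eg <- glue(oct, m)
    if (length(eg$holes) < 2L) next
    s1 <- eg$holes[[1L]]$sides[1L]
    s2 <- eg$holes[[2L]]$sides[1L]
    eg2 <- glue(oct, rbind(eg$matching, c(s1, s2)))
    expect_equal(eg2$components$g, eg$components$g + 1L)
    checked <- checked + 1L
  }
  expect_gt(checked, 3L)
})

test_that("a one-face partial gluing extends to a sphere iff it sits on a sphere with even holes", {
  hex <- polygon_collection(list(paste0("s", 1:6)))
  for (m in partial_matchings(6L, 1L)) {
    eg <- glue(hex, m)
    free <- setdiff(1:6, c(m))
    extendable <- FALSE
    for (mm in dcjtopo:::enumerate_perfect_matchings(length(free))) {
      full <- rbind(m, cbind(free[mm[, 1L]], free[mm[, 2L]]))
      if (is_all_spheres(glue(hex, full))) { extendable <- TRUE; break }
    }
    sphere_even_holes <- eg$components$g == 0L &&
      all(vapply(eg$holes, function(h) length(h$sides) %% 2L, integer(1)) == 0L)
    expect_equal(extendable, sphere_even_holes)
  }
})

test_that("polygons_from_cycles builds one polygon per A-cycle with the R side-matching", {
  cbg <- contracted_breakpoint_graph(fx$fig4_A, fx$fig4_R)
  pm <- polygons_from_cycles(cbg)
  expect_length(pm$pc$polygons, 1L)
  expect_equal(pm$pc$n_sides, 8L)
  expect_equal(nrow(pm$matching), 4L)
  eg <- glue(pm$pc, pm$matching)
  expect_equal(eg$components[, c("v", "e", "f", "g")],
               data.frame(v = 1L, e = 4L, f = 1L, g = 2L))

  cbg2 <- contracted_breakpoint_graph(parse_genome("(+a-a+b-b)"),
                                      parse_genome("(+a-b)"))
  pm2 <- polygons_from_cycles(cbg2)
  expect_equal(sort(lengths(pm2$pc$polygons)), c(1L, 1L, 2L))
  expect_error(polygons_from_cycles(contracted_breakpoint_graph(fx$fig4_A)),
               "missing R_edges")
})

test_that("ht-decompositions match the figure captions and the vertex count", {
  cbg4 <- contracted_breakpoint_graph(fx$fig4_A, fx$fig4_R)
  expect_length(ht_decomposition(cbg4), 1L)
  # clockwise ht-decomposition of the larger worked example is maximal
  cbg1 <- contracted_breakpoint_graph(fx$fig1_A, fx$fig1_R)
  expect_length(ht_decomposition(cbg1), cbg1$n + cbg1$k)
  # vertex-count correspondence on random instances and orientations
  set.seed(17)
  for (i in 1:12) {
    n <- sample(3:6, 1L)
    A <- random_all_duplicated_genome(n)
    R <- random_ordinary_genome(n)
    cbg <- contracted_breakpoint_graph(A, R)
    o <- sample(c(TRUE, FALSE), length(cbg$a_cycles), replace = TRUE)
    pm <- polygons_from_cycles(cbg, o)
    eg <- glue(pm$pc, pm$matching)
    expect_equal(length(ht_decomposition(cbg, o)), sum(eg$components$v))
  }
})

test_that("perfect gluings never exceed the sphere vertex bound", {
  # k even-gons and 2l odd-gons on 2n sides glue to at most n + k vertices,
  # with equality exactly on maximal sphere configurations
  set.seed(31)
  sizes_list <- list(c(4L), c(6L), c(3L, 3L), c(4L, 2L), c(3L, 1L, 2L))
  for (sizes in sizes_list) {
    total <- sum(sizes)
    k <- sum(sizes %% 2L == 0L)
    l <- sum(sizes %% 2L == 1L) / 2L
    n <- total / 2L
    pc <- polygon_collection(lapply(seq_along(sizes), function(i)
      paste0("p", i, "_", seq_len(sizes[i]))))
    for (rep in 1:15) {
      m <- matrix(sample(total), ncol = 2)
      eg <- glue(pc, m)
      v <- sum(eg$components$v)
      expect_lte(v, n + k)
      if (v == n + k) {
        expect_true(all(eg$components$g == 0L))
        expect_equal(nrow(eg$components), k + l)
      }
    }
  }
})

test_that("surgeries preserve faces and edges, and invert cleanly", {
  cbg <- contracted_breakpoint_graph(fx$fig4_A, fx$fig4_R)
  pm <- polygons_from_cycles(cbg)
  eg <- glue(pm$pc, pm$matching)
  s <- surgery(c(1L, 2L), dcjtopo:::surgery_reglues(eg, c(1L, 2L))[[1L]])
  eg2 <- apply_surgery(eg, s)
  expect_equal(sum(eg2$components$f), sum(eg$components$f))
  expect_equal(sum(eg2$components$e), sum(eg$components$e))
  expect_lte(abs(sum(eg2$components$v) - sum(eg$components$v)), 2L)
  # inverse surgery restores the matching
  cut2 <- which(apply(eg2$matching, 1L, function(r)
    any(apply(s$reglue, 1L, function(q) all(sort(q) == sort(r))))))
  inv <- surgery(cut2, eg$matching[s$cut, ])
  eg3 <- apply_surgery(eg2, inv)
  expect_identical(eg3$matching, eg$matching)
  # the 2-torus of the figure reaches genus <= 1 within two surgeries
  found <- FALSE
  ne <- nrow(eg$matching)
  for (cut in utils::combn(ne, 2L, simplify = FALSE)) {
    for (rg in dcjtopo:::surgery_reglues(eg, cut)) {
      egx <- apply_surgery(eg, surgery(cut, rg))
      if (sum(egx$components$g) <= 1L) found <- TRUE
    }
  }
  expect_true(found)
})

test_that("the surgery/DCJ bridge commutes with gluing", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(3:5, 1L)
    A <- random_all_duplicated_genome(n)
    B <- random_ordinary_genome(n)
    cbg <- contracted_breakpoint_graph(A, B)
    pm <- polygons_from_cycles(cbg)
    eg <- glue(pm$pc, pm$matching)
    adj <- adjacencies(B)
    ij <- sample(nrow(adj), 2L)
    a <- adj[ij[1L], ]; b <- adj[ij[2L], ]
    op <- dcj_op(rbind(a, b), rbind(c(a[1L], b[1L]), c(a[2L], b[2L])))
    s <- surgery_from_dcj(eg, op)
    round_trip <- dcj_from_surgery(eg, s)
    expect_identical(round_trip$removed, op$removed)
    expect_identical(round_trip$added, op$added)
    eg2 <- apply_surgery(eg, s)
    pm2 <- polygons_from_cycles(contracted_breakpoint_graph(A, apply_dcj(B, op)))
    expect_identical(eg2$matching, pm2$matching)
  }
})

test_that("polygon spec files round-trip through JSON", {
  pm <- polygons_from_cycles(contracted_breakpoint_graph(fx$fig4_A, fx$fig4_R))
  path <- withr::local_tempfile(fileext = ".json")
  write_polygon_spec(pm$pc, pm$matching, path)
  spec <- read_polygon_spec(path)
  expect_identical(spec$pc$labels, pm$pc$labels)
  expect_identical(spec$matching, pm$matching)
  eg <- glue(spec$pc, spec$matching)
  expect_equal(eg$components$g, 2L)
})
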