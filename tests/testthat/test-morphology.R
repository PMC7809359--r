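test_that("SWC parsing mirrors the sample points and resolves parents", {
  m <- read_swc(swc_chain6())
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m$nodes), 6L)
  expect_equal(sum(!is.na(m$nodes$parent)), 5L)
  expect_equal(m$nodes$parent[match(2:6, m$nodes$id)], 1:5)
  expect_equal(m$nodes$type[match(1L, m$nodes$id)], 1L)
})

test_that("malformed SWC input is rejected with informative errors", {
  expect_error(read_swc(swc_file(c("# only comments", "# nothing else"))),
               "no data lines")
  expect_error(read_swc(swc_file("1 1 0 0 0 1")), "line 1.*7 fields")
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 a 0 0 1 1"))),
               "line 2.*non-numeric")
  # self-parent
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 2"))),
               "itself as parent")
  # dangling parent reference
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 9"))),
               "nonexistent parent")
  # two-cycle detached from the root
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1",
                                   "2 3 1 0 0 1 3",
                                   "3 3 2 0 0 1 2"))),
               "not connected")
  # no root at all
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 2", "2 3 1 0 0 1 1"))),
               "no root")
})

test_that("collapse_soma merges contiguous soma points and re-attaches dendrites", {
  m <- collapse_soma(read_swc(swc_multisoma()))
  expect_equal(sum(m$nodes$type == 1L), 1L)
  expect_equal(m$soma_id, 1L)
  mm <- morphometrics(m)
  expect_equal(mm$n_somatic_branches, 3L)
  expect_equal(mm$n_compartments, 3L)
  # merged soma sits at the centroid of the three soma points
  k <- match(1L, m$nodes$id)
  expect_equal(m$nodes$x[k], 1)
  # already-single soma: unchanged node table
  m1 <- read_swc(swc_chain6())
  m2 <- collapse_soma(m1)
  expect_equal(m2$nodes, m1$nodes)
  # no soma at all
  nosoma <- morphology(data.frame(id = 1:3, parent = c(NA, 1L, 2L), type = 3L,
                                  x = 0, y = 0, z = 0, radius = 1))
  expect_error(collapse_soma(nosoma), "no soma")
})

test_that("strip_axon removes axonal subtrees and nothing else", {
  m <- prepared(swc_with_axon())
  expect_equal(sort(m$nodes$id), c(1L, 4L, 5L))
  expect_true(all(m$nodes$type %in% c(1L, 3L)))
  # no axon: identity
  m2 <- collapse_soma(read_swc(swc_chain6()))
  expect_equal(strip_axon(m2)$nodes, m2$nodes)
})

test_that("morphometrics counts compartments, bifurcations, stems by hand-checkable rules", {
  # soma + two chains of 3
  m <- make_chain(6, soma = "center")
  mm <- morphometrics(m)
  expect_equal(mm$n_compartments, 6L)
  expect_equal(mm$n_compartments_total, 7L)
  expect_equal(mm$n_bifurcations, 0L)
  expect_equal(mm$n_somatic_branches, 2L)

  # full binary dendritic tree of depth 2 on a single stem:
  # stem + 2 children + 4 grandchildren = 7 dendritic compartments,
  # 3 bifurcating compartments (stem and both children)
  nodes <- data.frame(
    id = 1:8,
    parent = c(NA, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
    type = c(1L, rep(3L, 7)),
    x = 0, y = 0, z = 0, radius = 1)
  mb <- morphology(nodes, soma_id = 1L)
  mmb <- morphometrics(mb)
  expect_equal(mmb$n_compartments, 7L)
  expect_equal(mmb$n_bifurcations, 3L)
  expect_equal(mmb$n_somatic_branches, 1L)
  expect_true(mmb$n_bifurcations <= mmb$n_compartments)
})

test_that("morphometrics are invariant under SWC line-order permutation", {
  m <- make_random_tree(40, seed = 7)
  mm1 <- morphometrics(m)
  set.seed(99)
  perm <- sample(nrow(m$nodes))
  m2 <- morphology(m$nodes[perm, ], soma_id = m$soma_id)
  mm2 <- morphometrics(m2)
  expect_equal(unclass(mm1), unclass(mm2))
})

test_that("eccentricity follows path lengths to the farthest terminus", {
  # standalone 5-compartment chain (no soma designation needed)
  chain5 <- morphology(data.frame(id = 1:5, parent = c(NA, 1:4),
                                  type = 3L, x = 0, y = 0, z = 0, radius = 1))
  expect_equal(eccentricity(chain5, 1L), 4L)
  expect_equal(eccentricity(chain5, 3L), 2L)
  expect_error(eccentricity(chain5, 99L), "unknown compartment")
  # soma of a star with three length-4 arms
  expect_equal(eccentricity(make_star(3, 4), 1L), 4L)
})

test_that("eccentricities match the igraph all-pairs oracle on random trees", {
  for (seed in 1:12) {
    n <- sample(2:49, 1)
    m <- make_random_tree(n, seed = seed)
    expect_equal(unname(eccentricities(m)), oracle_eccentricities(m),
                 info = paste("seed", seed))
  }
})

test_that("soma centrality is min-max normalised over all compartments", {
  expect_equal(soma_centrality(make_chain(5, "end")), 0)
  expect_equal(soma_centrality(make_star(3, 4)), 1)
  expect_equal(soma_centrality(make_chain(0)), 1)  # degenerate convention
  # range and attainment on random trees
  for (seed in 20:24) {
    m <- make_random_tree(30, seed = seed)
    ecc <- eccentricities(m)
    cen <- (max(ecc) - ecc) / (max(ecc) - min(ecc))
    expect_true(soma_centrality(m) >= 0 && soma_centrality(m) <= 1)
    expect_equal(soma_centrality(m), unname(cen[as.character(m$soma_id)]))
    expect_true(all(cen[ecc == min(ecc)] == 1) && all(cen[ecc == max(ecc)] == 0))
  }
})

test_that("SWC write/read round-trips generated morphologies exactly", {
  gens <- list(make_chain(7), make_chain(6, "center"), make_star(4, 3),
               make_cayley(2, 3), make_random_tree(25, seed = 3),
               make_synthetic_pyramidal(5))
  for (m in gens) {
    path <- tempfile(fileext = ".swc")
    write_swc(m, path)
    m2 <- read_swc(path)
    o1 <- order(m$nodes$id); o2 <- order(m2$nodes$id)
    expect_equal(m2$nodes$id[o2], m$nodes$id[o1])
    expect_equal(m2$nodes$parent[o2], m$nodes$parent[o1])
    expect_equal(m2$nodes$type[o2], m$nodes$type[o1])
    expect_equal(m2$nodes$x[o2], m$nodes$x[o1], tolerance = 1e-8)
  }
})
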