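test_that("Louvain recovers the two-triangle partition with Q = 0.5", {
  g <- twoTrianglesGraph()
  part <- louvainModularity(g)
  memb <- communityMembership(part)
  expect_equal(unname(partitionQuality(part)), 0.5, tolerance = 1e-12)
  expect_length(unique(memb), 2)
  expect_length(unique(memb[c("a", "b", "c")]), 1)
  expect_length(unique(memb[c("d", "e", "f")]), 1)

  single <- igraph::make_graph(c("x", "y"), directed = FALSE)
  ps <- louvainModularity(single)
  expect_length(unique(communityMembership(ps)), 1)
  expect_equal(unname(partitionQuality(ps)), 0)

  expect_error(louvainModularity(igraph::make_empty_graph(3,
                                                          directed = FALSE)),
               "at least one edge")
})

test_that("modularity evaluation agrees with igraph as a cross-check", {
  for (g in smallGraphSuite()) {
    part <- louvainModularity(g)
    memb <- communityMembership(part)
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
    expect_equal(unname(partitionQuality(part)),
                 igraph::modularity(g, memb[nm],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
    # never worse than igraph's own Louvain by more than heuristic noise
    ig <- igraph::cluster_louvain(g)
    expect_gte(unname(partitionQuality(part)),
               igraph::modularity(g, igraph::membership(ig),
                                  weights = igraph::E(g)$weight) - 0.05)
  }
})

test_that("Louvain quality trace is non-decreasing across passes", {
  for (g in smallGraphSuite()[c(1, 3, 5, 9)]) {
    tr <- adhesomics:::.louvain(g, "modularity")$trace
    expect_true(all(diff(tr) >= -1e-12))
  }
  net <- simulatePpiNetwork(nNodes = 120, meanDegree = 5, moduleSize = 15,
                            seed = 3)
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  tr <- adhesomics:::.louvain(g, "modularity")$trace
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("CPM limits: single community at gamma 0, singletons above max weight", {
  g <- twoTrianglesGraph()
  g2 <- igraph::add_edges(g, c("c", "d"))  # connect the triangles
  p0 <- cpmPartition(g2, gamma = 0)
  expect_length(unique(communityMembership(p0)), 1)

  pBig <- cpmPartition(g2, gamma = 1.5)  # above max (unit) edge weight
  expect_length(unique(communityMembership(pBig)),
                igraph::vcount(g2))
  expect_error(cpmPartition(g2, gamma = -1), "gamma")
})

test_that("Louvain and CPM optima match brute-force partition search", {
  for (g in smallGraphSuite()) {
    n <- igraph::vcount(g)
    parts <- allPartitions(n)
    # modularity
    best <- max(vapply(parts, function(pp)
      igraph::modularity(g, pp, weights = igraph::E(g)$weight), numeric(1)))
    got <- unname(partitionQuality(louvainModularity(g)))
    expect_lte(got, best + 1e-9)
    expect_gte(got, best - 0.15)   # heuristic may fall short, never exceed
    # CPM at a mid resolution
    bestH <- max(vapply(parts, function(pp) cpmOracle(g, pp, 0.5),
                        numeric(1)))
    gotH <- unname(partitionQuality(cpmPartition(g, 0.5)))
    expect_lte(gotH, bestH + 1e-9)
  }
})

test_that("CPM community count is non-decreasing in gamma", {
  for (g in smallGraphSuite()[c(2, 4, 9)]) {
    ks <- vapply(c(0.05, 0.3, 0.8, 1.5), function(gam)
      length(unique(communityMembership(cpmPartition(g, gam)))),
      numeric(1))
    expect_true(all(diff(ks) >= -1))  # monotone up to heuristic noise
  }
})

test_that("surprise matches the exact hypergeometric tail", {
  g <- twoTrianglesGraph()
  part <- louvainModularity(g)
  expect_equal(surprise(g, part), log(5005), tolerance = 1e-9)

  # relabeled membership gives the same value
  memb <- communityMembership(part)
  relab <- setNames(3L - memb, names(memb))
  expect_equal(surprise(g, relab), log(5005), tolerance = 1e-9)

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- letters[1:5]
  one <- setNames(rep(1L, 5), letters[1:5])
  expect_equal(surprise(full, one), 0)

  # mixing the components strictly lowers Surprise
  mixed <- setNames(c(1L, 1L, 2L, 2L, 1L, 2L),
                    c("a", "b", "c", "d", "e", "f"))
  expect_lt(surprise(g, mixed), log(5005))
  expect_gte(surprise(g, mixed), 0)
})

test_that("gamma scan maximises Surprise and recovers planted cliques", {
  g <- twoTrianglesGraph()
  conn <- igraph::add_edges(g, c("c", "d"))
  p0 <- scanGamma(conn, grid = 0)
  expect_length(unique(communityMembership(p0)), 1)

  # two 5-cliques joined by a single edge
  cl <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  cl <- igraph::add_edges(cl, c(1, 6))
  igraph::V(cl)$name <- sprintf("n%02d", 1:10)
  part <- scanGamma(cl)
  memb <- communityMembership(part)
  expect_length(unique(memb), 2)
  expect_length(unique(memb[sprintf("n%02d", 1:5)]), 1)
  expect_length(unique(memb[sprintf("n%02d", 6:10)]), 1)
  # reported quality is self-consistent with surprise()
  expect_equal(unname(partitionQuality(part)), surprise(cl, part),
               tolerance = 1e-12)
})

test_that("hub cartography matches hand-computed z and participation", {
  # two modules of 5; node h1 in module 1 with edges to all of module 1
  # and two edges into module 2
  edges <- rbind(
    t(utils::combn(sprintf("a%d", 1:4), 2))[c(1, 4, 6), ],  # sparse mod 1
    cbind("h1", sprintf("a%d", 1:4)),                        # hub edges
    cbind("h1", c("b1", "b2")),
    t(utils::combn(sprintf("b%d", 1:5), 2)))
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  memb <- setNames(c(rep(1L, 5), rep(2L, 5)),
                   c(sprintf("a%d", 1:4), "h1", sprintf("b%d", 1:5)))
  hubs <- classifyHubs(g, memb, zThr = 1.2)
  h <- hubs[hubs$node == "h1", ]
  # hand arithmetic: within-module degrees in module 1 are (2,3,3,2,4)
  # (a1-a2, a2-a3, a3-a4 plus one hub edge each)
  kin <- c(2, 3, 3, 2, 4)
  zExp <- (4 - mean(kin)) / sd(kin)
  pExp <- 1 - (4 / 6)^2 - (2 / 6)^2
  expect_equal(h$z, zExp, tolerance = 1e-12)
  expect_equal(h$participation, pExp, tolerance = 1e-12)
  expect_identical(h$label, "connector_hub")
  # pure-internal node: participation 0
  b3 <- hubs[hubs$node == "b3", ]
  expect_equal(b3$participation, 0)
})

test_that("participation is 0.5 for an equal two-module split", {
  g <- igraph::graph_from_edgelist(
    cbind(c("x", "x"), c("in1", "out1")), directed = FALSE)
  memb <- setNames(c(1L, 1L, 2L), c("x", "in1", "out1"))
  hubs <- classifyHubs(g, memb)
  expect_equal(hubs$participation[hubs$node == "x"], 0.5)
})

test_that("abundance edge weights follow the rho + 1 / clamped-rho rules", {
  m <- rbind(p1 = c(1, 2, 3, 4, 5, 6),
             p2 = c(2, 4, 6, 8, 10, 12),    # identical ranks -> rho 1
             p3 = c(6, 5, 4, 3, 2, 1),      # reversed -> rho -1
             p4 = c(2, 1, 4, 3, 6, 5))      # positive but imperfect
  colnames(m) <- sprintf("s%d", 1:6)
  se <- abundanceExperiment(m, rep(c("A", "B"), each = 3))
  edges <- rbind(c("p1", "p2"), c("p1", "p3"), c("p1", "p4"),
                 c("p1", "zz"))
  wMod <- abundanceEdgeWeights(se, edges, "modularity")$weight
  expect_equal(wMod[1], 2)
  expect_equal(wMod[2], 0)
  expect_equal(wMod[4], 1)   # unknown endpoint -> neutral weight
  wCpm <- abundanceEdgeWeights(se, edges, "cpm")$weight
  expect_equal(wCpm[2], 0)   # negative rho clamped
  expect_equal(wCpm[1], 1)
  expect_equal(wCpm[4], 0)
})

test_that("partitions are deterministic for a fixed seed", {
  net <- simulatePpiNetwork(nNodes = 80, meanDegree = 5, moduleSize = 12,
                            seed = 5)
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  p1 <- louvainModularity(g, seed = 11)
  p2 <- louvainModularity(g, seed = 11)
  expect_identical(communityMembership(p1), communityMembership(p2))
  c1 <- cpmPartition(g, 0.4, seed = 11)
  c2 <- cpmPartition(g, 0.4, seed = 11)
  expect_identical(communityMembership(c1), communityMembership(c2))
})
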