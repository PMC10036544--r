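test_that("BUM fit recovers generator parameters", {
  pU <- simulateBumPvalues(1e4, lam = 1, a = 0.5, seed = 2)
  fitU <- fitBum(pU)
  expect_gte(fitU@piUpper, 0.95)

  p <- simulateBumPvalues(1e4, lam = 0.7, a = 0.3, seed = 3)
  fit <- fitBum(p)
  expect_lt(abs(fit@lambda - 0.7), 0.05)
  expect_lt(abs(fit@a - 0.3), 0.05)
  # fitted likelihood at least that of the uniform-only candidate
  uniLik <- -adhesomics:::.bumNegLogLik(c(1 - 1e-6, 0.5), p)
  expect_gte(fit@logLik, uniLik)

  expect_error(fitBum(runif(50)), "at least 100")
  expect_error(fitBum(c(runif(200), 1.5)), "above 1")
  expect_warning(fitBum(c(runif(200), 0)), "clamped")
})

test_that("BUM tau matches the closed form and a numeric root-solve", {
  fit0 <- new("BumFit", lambda = 0, a = 0.5, logLik = 0,
              piUpper = 0.5, n = 100L)
  expect_equal(bumTau(fit0, 0.05), 0.01, tolerance = 1e-12)

  fit <- new("BumFit", lambda = 0.5, a = 0.5, logLik = 0,
             piUpper = 0.75, n = 100L)
  tau <- bumTau(fit, 0.05)
  # independent route: solve FDR(tau) = pi*tau / (lam*tau + (1-lam)*tau^a)
  fdrOf <- function(t) fit@piUpper * t /
    (fit@lambda * t + (1 - fit@lambda) * t^fit@a)
  root <- stats::uniroot(function(t) fdrOf(t) - 0.05,
                         c(1e-12, 0.999), tol = 1e-14)$root
  expect_equal(tau, root, tolerance = 1e-8)
  expect_gt(tau, 0); expect_lt(tau, 1)

  fitNoSig <- new("BumFit", lambda = 1 - 1e-15, a = 0.5, logLik = 0,
                  piUpper = 1, n = 100L)
  expect_error(bumTau(fitNoSig, 0.05), "lambda = 1")
})

test_that("node scores are zero at tau and match the formula everywhere", {
  fit <- new("BumFit", lambda = 0.6, a = 0.25, logLik = 0,
             piUpper = 0.6 + 0.4 * 0.25, n = 500L)
  tau <- bumTau(fit, 0.05)
  expect_equal(unname(scoreNodes(fit, c(x = tau))), 0, tolerance = 1e-12)
  expect_equal(unname(scoreNodes(fit, c(x = tau / exp(1)))), 1 - fit@a,
               tolerance = 1e-12)
  set.seed(4)
  p <- setNames(runif(50), sprintf("n%02d", 1:50))
  s <- scoreNodes(fit, p)
  expect_equal(unname(s), (fit@a - 1) * (log(p) - log(tau)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(sign(unname(s)), sign(tau - unname(p)))  # sign sanity
  # default score for unmapped nodes = score at p = 0.5
  s2 <- scoreNodes(fit, p[1:10], nodes = names(p))
  expect_equal(unname(s2[names(p)[11]]),
               (fit@a - 1) * (log(0.5) - log(tau)), tolerance = 1e-12)
})

test_that("PCST transform preserves the MWCS objective up to an offset", {
  net <- scoredNetwork(cbind(c("a", "b"), c("b", "c")),
                       c(a = 3, b = -2, c = 1))
  inst <- mwcsToPcst(net)
  expect_equal(inst$edgeCost, 2)
  expect_equal(unname(inst$profits[c("a", "b", "c")]), c(5, 0, 3))
  expect_true(all(inst$profits >= 0))

  allPos <- scoredNetwork(cbind("a", "b"), c(a = 1, b = 2))
  expect_equal(mwcsToPcst(allPos)$edgeCost, 0)

  # on every spanning subtree the two objectives differ by the offset
  net2 <- mwcsFixture(99, nMin = 6, nMax = 7)
  inst2 <- mwcsToPcst(net2)
  g <- interactionGraph(net2)
  s <- nodeScores(net2)
  nm <- igraph::V(g)$name
  for (mask in sample(seq_len(2^length(nm) - 1L), 40)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(nm) - 1L)) != 0L)
    sub <- igraph::induced_subgraph(g, nm[idx])
    if (!igraph::is_connected(sub)) next
    nEdgesTree <- length(idx) - 1L   # a spanning tree of the subset
    expect_equal(sum(inst2$profits[nm[idx]]) - inst2$edgeCost * nEdgesTree,
                 sum(s[nm[idx]]) + inst2$offset, tolerance = 1e-9)
  }
})

test_that("exact solver finds true optima with deterministic tie-breaks", {
  allPos <- scoredNetwork(cbind(c("a", "b"), c("b", "c")),
                          c(a = 1, b = 0.5, c = 2))
  expect_setequal(moduleMembers(solveMwcsExact(allPos)), c("a", "b", "c"))

  negs <- scoredNetwork(cbind("a", "b"), c(a = -1, b = -2))
  mod <- solveMwcsExact(negs)
  expect_identical(moduleMembers(mod), "a")
  expect_equal(moduleScore(mod), -1)

  # 7-node path, scores (2, -1, -1, 3, -5, -1, 4): the singleton {v7}
  # scores 4 and beats the {v1..v4} stretch (score 3); confirmed by an
  # independent exhaustive enumeration
  ids <- sprintf("v%d", 1:7)
  path <- scoredNetwork(cbind(ids[-7], ids[-1]),
                        setNames(c(2, -1, -1, 3, -5, -1, 4), ids))
  exact <- solveMwcsExact(path)
  oracle <- bruteForceMwcs(path)
  expect_equal(moduleScore(exact), oracle$score)
  expect_identical(sort(moduleMembers(exact)), oracle$members)
  expect_equal(moduleScore(exact), 4)
  expect_identical(moduleMembers(exact), "v7")

  big <- mwcsFixture(1, nMin = 25, nMax = 25)
  expect_error(solveMwcsExact(big), "solveMwcsHeuristic")
})

test_that("exact solver equals brute-force enumeration on random graphs", {
  for (seed in 1:10) {
    net <- mwcsFixture(seed + 400, nMin = 5, nMax = 8)
    exact <- solveMwcsExact(net)
    oracle <- bruteForceMwcs(net)
    expect_equal(moduleScore(exact), oracle$score, tolerance = 1e-9)
  }
})

test_that("heuristic bridges positives and always returns connected output", {
  bridge <- scoredNetwork(cbind(c("a", "m"), c("m", "b")),
                          c(a = 5, m = -0.1, b = 5))
  mod <- solveMwcsHeuristic(bridge)
  expect_setequal(moduleMembers(mod), c("a", "m", "b"))
  expect_equal(moduleScore(mod), 9.9)

  lone <- scoredNetwork(cbind(c("a", "b"), c("b", "c")),
                        c(a = -3, b = 2, c = -4))
  expect_identical(moduleMembers(solveMwcsHeuristic(lone)), "b")

  for (seed in 101:115) {
    net <- mwcsFixture(seed)
    mod <- solveMwcsHeuristic(net)
    sub <- igraph::induced_subgraph(interactionGraph(net),
                                    moduleMembers(mod))
    expect_true(igraph::is_connected(sub))
    expect_gte(moduleScore(mod), max(nodeScores(net)))
    # spanning tree edges join members and span them
    te <- treeEdges(mod)
    if (length(moduleMembers(mod)) > 1L) {
      expect_equal(nrow(te), length(moduleMembers(mod)) - 1L)
      expect_true(all(as.vector(te) %in% moduleMembers(mod)))
    }
  }
})
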