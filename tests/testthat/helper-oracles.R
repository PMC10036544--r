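# Independent oracles and generated fixture suites. Everything here is
# deliberately written by a different route than the package code it
# checks: brute-force enumeration, quadratic scans, closed forms.

# --- graphs ----------------------------------------------------------------

twoTrianglesGraph <- function() {
  igraph::make_graph(c("a", "b", "b", "c", "a", "c",
                       "d", "e", "e", "f", "d", "f"), directed = FALSE)
}

# random connected scored networks for the MWCS fixture suite
mwcsFixture <- function(seed, nMin = 6L, nMax = 12L) {
  set.seed(seed)
  n <- sample(nMin:nMax, 1L)
  repeat {
    g <- igraph::sample_gnp(n, min(1, 2.2 / n))
    if (igraph::is_connected(g)) break
    g <- igraph::add_edges(g, as.vector(rbind(
      seq_len(n - 1L), 2:n)))  # fall back: thread a path
    break
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  scores <- round(rnorm(n, mean = -0.3, sd = 1.5), 3)
  scores[sample.int(n, max(1L, n %/% 4L))] <-
    round(abs(rnorm(max(1L, n %/% 4L), 1.5, 1)), 3)
  scoredNetwork(igraph::as_edgelist(g),
                stats::setNames(scores, igraph::V(g)$name))
}

# brute-force MWCS: enumerate every non-empty vertex subset, keep connected
# ones (igraph connectivity test), maximise the score sum
bruteForceMwcs <- function(net) {
  g <- interactionGraph(net)
  s <- nodeScores(net)
  nm <- igraph::V(g)$name
  n <- length(nm)
  best <- -Inf; bestSet <- NULL
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    sub <- igraph::induced_subgraph(g, nm[idx])
    if (!igraph::is_connected(sub)) next
    sc <- sum(s[nm[idx]])
    if (sc > best) { best <- sc; bestSet <- sort(nm[idx]) }
  }
  list(score = best, members = bestSet)
}

# all set partitions of 1..n as membership vectors (restricted growth)
allPartitions <- function(n) {
  out <- list()
  recur <- function(memb, k) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return() }
    for (c in seq_len(k + 1L)) recur(c(memb, c), max(k, c))
  }
  recur(integer(0), 0L)
  out
}

# independent CPM evaluation from the adjacency matrix
cpmOracle <- function(g, memb, gamma) {
  A <- igraph::as_adjacency_matrix(g, attr =
    if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = FALSE)
  tot <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    nc <- length(idx)
    tot <- tot + sum(A[idx, idx, drop = FALSE]) / 2 -
      gamma * nc * (nc - 1) / 2
  }
  tot
}

# small-graph fixture suite for partition brute force
smallGraphSuite <- function() {
  gs <- list()
  set.seed(42)
  for (i in 1:8) {
    n <- sample(5:8, 1L)
    g <- igraph::sample_gnp(n, 0.5)
    while (igraph::ecount(g) < 2L) g <- igraph::sample_gnp(n, 0.6)
    igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.5, 2), 2)
    gs[[i]] <- g
  }
  gs[[9]] <- twoTrianglesGraph()
  gs
}

# ratio-only window track on adjacent 500-bp windows of one chromosome
mkRatioTrack <- function(ratios, winSize = 500L) {
  n <- length(ratios)
  gr <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = seq(1L, by = winSize,
                                         length.out = n),
                             width = winSize))
  new("GatcWindowTrack", windows = gr,
      counts = matrix(numeric(), n, 0L),
      rpm = matrix(numeric(), n, 0L),
      log2Ratio = as.numeric(ratios),
      totals = stats::setNames(numeric(0), character(0)))
}

# quadratic reference read counter (window containment of read starts)
bruteForceCount <- function(track, starts0) {
  w <- gatcWindows(track)
  s <- GenomicRanges::start(w) - 1L   # 0-based window start
  e <- GenomicRanges::end(w)          # 0-based half-open end
  vapply(seq_along(w), function(i)
    sum(starts0 >= s[i] & starts0 < e[i]), numeric(1))
}

# exhaustive hypergeometric tail by enumerating all C(N, n) draws
bruteForceHyperTail <- function(x, K, N, n) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% annotated))
  mean(hits >= x)
}

# independent Otsu scan: exhaustive over the 256 bin boundaries
bruteForceOtsu <- function(v, nBins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(findInterval(v, breaks, all.inside = TRUE), nBins)
  mids <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  bestVar <- -Inf; bestThr <- NA_real_
  for (b in seq_len(nBins - 1L)) {
    lo <- bin <= b
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(mids[bin][lo]); mu1 <- mean(mids[bin][!lo])
    v2 <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v2 > bestVar) { bestVar <- v2; bestThr <- breaks[b + 1L] }
  }
  bestThr
}

# 0-based base-level coverage helpers for peak/LAD comparison
coveredBases <- function(intervals, lo, hi) {
  # number of bases of [lo, hi) covered by the union of intervals
  if (!nrow(intervals)) return(0L)
  cov <- rep(FALSE, hi - lo)
  for (r in seq_len(nrow(intervals))) {
    s <- max(lo, intervals$start[r]); e <- min(hi, intervals$end[r])
    if (e > s) cov[(s - lo + 1L):(e - lo)] <- TRUE
  }
  sum(cov)
}
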