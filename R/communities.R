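# Community detection on active modules: a deterministic two-phase Louvain
# engine shared by Girvan-Newman modularity and the constant Potts model
# (CPM), the hypergeometric Surprise quality, a Surprise-maximising gamma
# scan, and within-module-degree/participation hub cartography.

.edgeTable <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  if (any(w < 0)) stop("negative edge weights not supported")
  list(el = el, w = as.numeric(w))
}

#' Girvan-Newman modularity of a partition
#'
#' `Q = (1/2W) * sum_ij [A_ij - k_i k_j / (2W)] delta(c_i, c_j)` with `W`
#' the total edge weight.
#'
#' @param g Weighted undirected igraph (missing weights default to 1).
#' @param membership Integer community labels in vertex order.
#' @return Modularity Q.
#' @export
modularityQ <- function(g, membership) {
  et <- .edgeTable(g)
  W <- sum(et$w)
  k <- numeric(igraph::vcount(g))
  for (r in seq_along(et$w)) {
    k[et$el[r, 1]] <- k[et$el[r, 1]] + et$w[r]
    k[et$el[r, 2]] <- k[et$el[r, 2]] + et$w[r]
  }
  if (W == 0) return(0)
  intra <- sum(et$w[membership[et$el[, 1]] == membership[et$el[, 2]]])
  Ktot <- tapply(k, membership, sum)
  intra / W - sum((Ktot / (2 * W))^2)
}

#' Constant Potts model quality of a partition
#'
#' `H(gamma) = sum_c [w_c - gamma * n_c (n_c - 1) / 2]`, `w_c` the
#' intra-community edge weight, `n_c` the community size; maximised by
#' [cpmPartition()].
#'
#' @param g Weighted undirected igraph.
#' @param membership Integer community labels in vertex order.
#' @param gamma Resolution parameter (>= 0).
#' @return CPM quality H.
#' @export
cpmH <- function(g, membership, gamma) {
  et <- .edgeTable(g)
  intra <- sum(et$w[membership[et$el[, 1]] == membership[et$el[, 2]]])
  sizes <- table(membership)
  intra - gamma * sum(sizes * (sizes - 1) / 2)
}

# One local-move + aggregation Louvain cycle stack. Deterministic: sweep in
# ascending node id (optionally shuffled once by seed), best-gain move with
# ties to the smallest community id. Returns membership on the original
# nodes plus the per-level quality trace.
.louvain <- function(g, mode = c("modularity", "cpm"), gamma = 1,
                     seed = NULL) {
  mode <- match.arg(mode)
  et0 <- .edgeTable(g)
  n0 <- igraph::vcount(g)
  order0 <- seq_len(n0)
  if (!is.null(seed)) order0 <- withSeed(seed, sample(order0))

  el <- et0$el; w <- et0$w
  selfW <- numeric(n0)
  nodeSize <- rep(1L, n0)
  assign0 <- seq_len(n0)        # original node -> current-level node
  trace <- numeric(0)
  sweep <- order0

  evalQuality <- function(memb) {
    if (mode == "modularity") modularityQ(g, memb) else cpmH(g, memb, gamma)
  }

  repeat {
    n <- length(selfW)
    # adjacency lists for this level
    adjI <- vector("list", n); adjW <- vector("list", n)
    if (nrow(el)) {
      for (r in seq_len(nrow(el))) {
        i <- el[r, 1]; j <- el[r, 2]
        adjI[[i]] <- c(adjI[[i]], j); adjW[[i]] <- c(adjW[[i]], w[r])
        adjI[[j]] <- c(adjI[[j]], i); adjW[[j]] <- c(adjW[[j]], w[r])
      }
    }
    k <- vapply(adjW, function(x) sum(x), numeric(1)) + 2 * selfW
    twoW <- sum(k)
    comm <- seq_len(n)
    commTot <- k
    commSize <- as.numeric(nodeSize)
    improved <- FALSE
    repeat {
      nMoves <- 0L
      for (i in sweep) {
        ci <- comm[i]
        commTot[ci] <- commTot[ci] - k[i]
        commSize[ci] <- commSize[ci] - nodeSize[i]
        nbc <- comm[adjI[[i]]]
        wto <- if (length(nbc)) tapply(adjW[[i]], nbc, sum) else numeric(0)
        cand <- as.integer(names(wto))
        if (!ci %in% cand) { cand <- c(cand, ci); wto <- c(wto, 0) }
        gain <- if (mode == "modularity") {
          if (twoW > 0) wto - k[i] * commTot[cand] / twoW else wto
        } else {
          wto - gamma * nodeSize[i] * commSize[cand]
        }
        best <- order(-gain, cand)[1]
        target <- if (gain[best] > gain[match(ci, cand)] + 1e-12)
          cand[best] else ci
        comm[i] <- target
        commTot[target] <- commTot[target] + k[i]
        commSize[target] <- commSize[target] + nodeSize[i]
        if (target != ci) nMoves <- nMoves + 1L
      }
      if (nMoves == 0L) break
      improved <- TRUE
    }
    # compact labels in order of first appearance over ascending node id
    lab <- match(comm, unique(comm[order(seq_len(n))]))
    assign0 <- lab[assign0]
    trace <- c(trace, evalQuality(assign0))
    nNew <- max(lab)
    if (!improved || nNew == n) break
    # aggregate
    newSelf <- numeric(nNew)
    newSize <- integer(nNew)
    for (i in seq_len(n)) {
      newSelf[lab[i]] <- newSelf[lab[i]] + selfW[i]
      newSize[lab[i]] <- newSize[lab[i]] + nodeSize[i]
    }
    if (nrow(el)) {
      a <- pmin(lab[el[, 1]], lab[el[, 2]])
      b <- pmax(lab[el[, 1]], lab[el[, 2]])
      intra <- a == b
      for (r in which(intra)) newSelf[a[r]] <- newSelf[a[r]] + w[r]
      key <- paste(a[!intra], b[!intra])
      agg <- tapply(w[!intra], key, sum)
      if (length(agg)) {
        kp <- do.call(rbind, strsplit(names(agg), " "))
        el <- cbind(as.integer(kp[, 1]), as.integer(kp[, 2]))
        w <- as.numeric(agg)
      } else { el <- matrix(integer(), 0L, 2L); w <- numeric(0) }
    }
    selfW <- newSelf; nodeSize <- newSize
    sweep <- seq_len(nNew)
  }
  list(membership = assign0, trace = trace)
}

.mkPartition <- function(g, membership, quality, kind, gamma = NA_real_) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  new("Partition", membership = setNames(as.integer(membership), nm),
      quality = quality, qualityKind = kind, gamma = gamma)
}

#' Louvain modularity partition
#'
#' Two-phase Louvain maximisation of Girvan-Newman modularity on a
#' non-negatively weighted undirected graph. Deterministic for a given seed
#' and node ordering.
#'
#' @param g Undirected igraph; edge attribute `weight` (>= 0) defaults to 1.
#' @param seed Optional integer seed shuffling the sweep order once; `NULL`
#'   sweeps in ascending node id.
#' @return A [Partition-class] with `qualityKind = "modularity_Q"`.
#' @export
louvainModularity <- function(g, seed = NULL) {
  if (igraph::ecount(g) < 1L) stop("graph must have at least one edge")
  res <- .louvain(g, "modularity", seed = seed)
  .mkPartition(g, res$membership, modularityQ(g, res$membership),
               "modularity_Q")
}

#' Constant Potts model partition
#'
#' Louvain-style maximisation of the CPM quality `H(gamma)`; unlike
#' modularity, CPM is free of the resolution limit and `gamma` directly
#' sets the intra-community density scale.
#'
#' @param g Undirected igraph with non-negative weights.
#' @param gamma Resolution parameter (>= 0).
#' @param seed Optional integer sweep-shuffle seed.
#' @return A [Partition-class] with `qualityKind = "cpm_H"`.
#' @export
cpmPartition <- function(g, gamma, seed = NULL) {
  if (gamma < 0) stop("'gamma' must be >= 0")
  res <- .louvain(g, "cpm", gamma = gamma, seed = seed)
  .mkPartition(g, res$membership, cpmH(g, res$membership, gamma),
               "cpm_H", gamma = gamma)
}

#' Surprise of a partition
#'
#' Minus the log upper-tail hypergeometric probability of drawing at least
#' the observed number of intra-community edges when placing the graph's
#' `m` edges uniformly among all `N(N-1)/2` node pairs, of which `M_int`
#' are intra-community. Computed in log space on the binarised (unweighted)
#' topology; invariant under community relabeling and always >= 0.
#'
#' @param g Simple undirected igraph.
#' @param part A [Partition-class] covering the vertices of `g` (or a named
#'   membership vector).
#' @return Surprise S (natural-log units).
#' @export
surprise <- function(g, part) {
  memb <- if (is(part, "Partition")) part@membership else part
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (!all(nm %in% names(memb))) stop("partition must cover all nodes")
  memb <- memb[nm]
  N <- igraph::vcount(g)
  M <- N * (N - 1) / 2
  m <- igraph::ecount(g)
  sizes <- table(memb)
  Mint <- sum(sizes * (sizes - 1) / 2)
  el <- igraph::as_edgelist(g, names = FALSE)
  mint <- sum(memb[el[, 1]] == memb[el[, 2]])
  logTail <- phyper(mint - 1, Mint, M - Mint, m, lower.tail = FALSE,
                    log.p = TRUE)
  max(0, -logTail)
}

#' Resolution scan maximising Surprise
#'
#' Runs [cpmPartition()] at each gamma of the grid, evaluates [surprise()]
#' of the resulting partition on the binarised topology, and returns the
#' partition with maximal Surprise (ties resolved towards the smaller
#' gamma). The returned [Partition-class] reports `quality` as the Surprise
#' value with the winning gamma recorded.
#'
#' @param g Undirected igraph with non-negative weights.
#' @param grid Numeric vector of gamma values (non-empty).
#' @param seed Optional sweep-shuffle seed passed to each CPM run.
#' @return A [Partition-class] with `qualityKind = "surprise_S"`.
#' @export
scanGamma <- function(g, grid = exp(seq(log(0.01), log(2),
                                        length.out = 25)),
                      seed = NULL) {
  if (!length(grid)) stop("'grid' must be non-empty")
  best <- NULL; bestS <- -Inf; bestGamma <- NA_real_
  for (gam in sort(grid)) {
    part <- cpmPartition(g, gam, seed = seed)
    S <- surprise(g, part)
    if (S > bestS) { best <- part; bestS <- S; bestGamma <- gam }
  }
  new("Partition", membership = best@membership, quality = bestS,
      qualityKind = "surprise_S", gamma = bestGamma)
}

#' Hub classification by within-module degree and participation
#'
#' Network cartography: for each node, the within-module degree z-score
#' `z = (k_in - mean_module) / sd_module` (0 where the module sd is 0) and
#' the participation coefficient `P = 1 - sum_s (k_is / k_i)^2` over
#' communities s. Nodes with `z >= zThr` are connector hubs when
#' `P` lies in `(pConnector[1], pConnector[2]]` and kinless hubs when
#' `P > pKinless`.
#'
#' @param g Undirected igraph (topology; weights ignored).
#' @param part A [Partition-class] covering the vertices.
#' @param zThr Hub z threshold (default 2.5).
#' @param pConnector Participation interval for connector hubs, default
#'   (0.30, 0.75].
#' @param pKinless Participation threshold for kinless hubs (default 0.75).
#' @return data.frame with columns `node`, `z`, `participation`, `label`.
#' @export
classifyHubs <- function(g, part, zThr = 2.5, pConnector = c(0.30, 0.75),
                         pKinless = 0.75) {
  memb <- if (is(part, "Partition")) part@membership else part
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  memb <- memb[nm]
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- length(nm)
  kin <- numeric(n)                       # within-module degree
  kis <- matrix(0, n, max(memb))          # degree into each community
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1]; j <- el[r, 2]
    kis[i, memb[j]] <- kis[i, memb[j]] + 1
    kis[j, memb[i]] <- kis[j, memb[i]] + 1
    if (memb[i] == memb[j]) { kin[i] <- kin[i] + 1; kin[j] <- kin[j] + 1 }
  }
  ktot <- rowSums(kis)
  z <- numeric(n)
  for (s in unique(memb)) {
    idx <- which(memb == s)
    mu <- mean(kin[idx]); sdv <- sd(kin[idx])
    z[idx] <- if (length(idx) < 2L || is.na(sdv) || sdv == 0) 0
              else (kin[idx] - mu) / sdv
  }
  P <- ifelse(ktot > 0, 1 - rowSums((kis / pmax(ktot, 1))^2), 0)
  label <- rep("none", n)
  isHub <- z >= zThr
  label[isHub & P > pConnector[1] & P <= pConnector[2]] <- "connector_hub"
  label[isHub & P > pKinless] <- "kinless_hub"
  data.frame(node = nm, z = z, participation = P, label = label,
             stringsAsFactors = FALSE)
}

#' Correlation edge weights from abundance profiles
#'
#' Weights each edge by the Spearman rank correlation of its endpoints'
#' abundance profiles: `rho + 1` (range \[0, 2\]) for modularity clustering,
#' or `max(rho, 0)` for CPM (negative correlations clamped, since the
#' local-move gain rules assume non-negative weights). Edges with an
#' endpoint absent from the matrix (or an undefined correlation) get the
#' neutral weight: 1 for modularity, 0 for CPM.
#'
#' @param se Abundance SummarizedExperiment (fully observed rows are used
#'   pairwise-complete).
#' @param edges Two-column character matrix/data.frame of edges.
#' @param mode `"modularity"` or `"cpm"`.
#' @return data.frame `from`, `to`, `weight`.
#' @export
abundanceEdgeWeights <- function(se, edges, mode = c("modularity", "cpm")) {
  mode <- match.arg(mode)
  m <- .assayMat(se)
  el <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(el) <- "character"
  wt <- numeric(nrow(el))
  for (r in seq_len(nrow(el))) {
    u <- el[r, 1]; v <- el[r, 2]
    rho <- NA_real_
    if (u %in% rownames(m) && v %in% rownames(m)) {
      ok <- !is.na(m[u, ]) & !is.na(m[v, ])
      if (sum(ok) >= 3L) rho <- spearmanRho(m[u, ok], m[v, ok])
    }
    wt[r] <- if (mode == "modularity") {
      if (is.na(rho)) 1 else rho + 1
    } else {
      if (is.na(rho)) 0 else max(rho, 0)
    }
  }
  data.frame(from = el[, 1], to = el[, 2], weight = wt,
             stringsAsFactors = FALSE)
}
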