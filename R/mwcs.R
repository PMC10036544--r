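# Maximum-weight connected subgraph (MWCS) solvers: an exact enumerator
# used as an oracle on small instances, and a diffusion-flow-style heuristic
# for realistic network sizes.

.lexLess <- function(a, b) {
  # TRUE if sorted character vector a precedes b lexicographically
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

.spanningEdges <- function(g, members) {
  if (length(members) < 2L)
    return(matrix(character(), 0L, 2L))
  sub <- igraph::induced_subgraph(g, members)
  tree <- igraph::mst(sub)
  igraph::as_edgelist(tree, names = TRUE)
}

.bestSingleNode <- function(scores) {
  best <- max(scores)
  cand <- sort(names(scores)[scores == best])
  cand[1]
}

#' Exact maximum-weight connected subgraph by exhaustive enumeration
#'
#' Enumerates every connected induced subgraph (bitmask subsets with a
#' bit-parallel connectivity check) and returns the maximum-total-score one.
#' The empty module is disallowed: if every score is negative, the single
#' best-scoring node is returned. Ties are broken towards the
#' lexicographically smallest sorted node-id set, making the solver
#' deterministic. Intended as the oracle for the heuristic; refuses
#' instances above `maxNodes`.
#'
#' @param net A [ScoredNetwork-class] with at most `maxNodes` nodes.
#' @param maxNodes Enumeration cap (default 20).
#' @return An [ActiveModule-class].
#' @export
solveMwcsExact <- function(net, maxNodes = 20L) {
  stopifnot(is(net, "ScoredNetwork"))
  g <- net@graph
  n <- igraph::vcount(g)
  if (n > maxNodes)
    stop("instance has ", n, " nodes (> ", maxNodes,
         "); use solveMwcsHeuristic()")
  nm <- igraph::V(g)$name
  s <- net@scores[nm]
  adj <- integer(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  bestScore <- -Inf; bestMask <- 0L
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    idx <- which(bitwAnd(mask, bits) != 0L)
    sc <- sum(s[idx])
    if (sc < bestScore) next
    # connectivity: expand from the lowest member until closure
    comp <- bits[idx[1]]
    repeat {
      nb <- comp
      for (i in idx) if (bitwAnd(comp, bits[i]) != 0L)
        nb <- bitwOr(nb, bitwAnd(adj[i], mask))
      if (nb == comp) break
      comp <- nb
    }
    if (comp != mask) next
    if (sc > bestScore ||
        (sc == bestScore && .lexLess(nm[idx],
                                     nm[which(bitwAnd(bestMask, bits) != 0L)]))) {
      bestScore <- sc; bestMask <- mask
    }
  }
  members <- sort(nm[which(bitwAnd(bestMask, bits) != 0L)])
  new("ActiveModule", members = members,
      treeEdges = .spanningEdges(g, members), totalScore = bestScore)
}

# optimal pruning of a tree: bottom-up DP (value(v) = s(v) + sum of
# positive child values), tried from every root, returning the best-scoring
# subtree
.strongPrune <- function(tree, s) {
  nm <- igraph::V(tree)$name
  n <- length(nm)
  best <- NULL
  for (rootIdx in seq_len(n)) {
    df <- igraph::dfs(tree, root = rootIdx, order = TRUE, father = TRUE)
    ord <- as.integer(df$order)
    father <- as.integer(df$father)
    value <- s[nm]
    for (v in rev(ord)) {
      p <- father[v]
      if (!is.na(p)) value[p] <- value[p] + max(0, value[v])
    }
    # extract: walk down from the root, keeping positive-value children
    keep <- logical(n); keep[rootIdx] <- TRUE
    for (v in ord) {
      p <- father[v]
      if (!is.na(p) && keep[p] && value[v] > 0) keep[v] <- TRUE
    }
    sc <- sum(s[nm[keep]])
    if (is.null(best) || sc > best$score ||
        (sc == best$score && .lexLess(nm[keep], best$members)))
      best <- list(members = sort(nm[keep]), score = sc)
  }
  best
}

.heuristicComponent <- function(g, s) {
  nm <- igraph::V(g)$name
  pos <- nm[s[nm] > 0]
  if (!length(pos)) {
    b <- .bestSingleNode(s[nm])
    return(list(members = b, score = s[b]))
  }
  # (1) contract adjacent positive nodes into super-nodes
  posSub <- igraph::induced_subgraph(g, pos)
  comps <- igraph::components(posSub)
  superMembers <- split(igraph::V(posSub)$name, comps$membership)
  superScore <- vapply(superMembers, function(v) sum(s[v]), numeric(1))
  # (2) node-cost metric: directed edges weighted by the cost of the target
  cost <- pmax(0, -s[nm])
  dg <- igraph::as_directed(g, mode = "mutual")
  head <- igraph::head_of(dg, igraph::E(dg))$name
  igraph::E(dg)$weight <- cost[match(head, nm)]
  # (3) greedy accretion: start at the best super-node; repeatedly attach
  # the super-node with the best (score - connection cost) while gain >= 0
  ordStart <- order(-superScore, vapply(superMembers, function(v)
    sort(v)[1], character(1)))
  included <- superMembers[[ordStart[1]]]
  remaining <- setdiff(seq_along(superMembers), ordStart[1])
  while (length(remaining)) {
    w <- igraph::E(dg)$weight
    hid <- match(head, nm)
    w[nm[hid] %in% included] <- 0
    d <- igraph::distances(dg, v = included, mode = "out", weights = w)
    dmin <- apply(d, 2L, min)
    names(dmin) <- colnames(d)
    connCost <- vapply(remaining, function(k)
      min(dmin[superMembers[[k]]]), numeric(1))
    gain <- superScore[remaining] - connCost
    if (max(gain) < 0) break
    pick <- remaining[order(-gain, vapply(superMembers[remaining],
                                          function(v) sort(v)[1],
                                          character(1)))[1]]
    # recover one cheapest path into the picked super-node
    srcRow <- which.min(apply(d[, superMembers[[pick]], drop = FALSE],
                              1L, min))
    tgt <- superMembers[[pick]][
      which.min(d[srcRow, superMembers[[pick]]])]
    sp <- igraph::shortest_paths(dg, from = rownames(d)[srcRow], to = tgt,
                                 mode = "out", weights = w)$vpath[[1]]
    included <- union(included, c(names(sp), superMembers[[pick]]))
    remaining <- setdiff(remaining, pick)
  }
  # (4) prune: drop negative-score nodes whose removal keeps connectivity
  repeat {
    negs <- included[s[included] < 0]
    dropped <- FALSE
    for (v in sort(negs)) {
      rest <- setdiff(included, v)
      if (length(rest) &&
          igraph::is_connected(igraph::induced_subgraph(g, rest))) {
        included <- rest; dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  greedy <- list(members = sort(included), score = sum(s[included]))

  # alternative route: connect ALL positive super-nodes via a metric-closure
  # minimum spanning tree, then strong pruning — catches configurations
  # where several attachments share a connector that no single attachment
  # justifies
  steiner <- .steinerCandidate(g, s, superMembers, dg, head, nm, cost)
  cand <- list(greedy, steiner)
  cand <- cand[!vapply(cand, is.null, logical(1))]
  best <- cand[[1]]
  for (x in cand[-1])
    if (x$score > best$score ||
        (x$score == best$score && .lexLess(x$members, best$members)))
      best <- x
  best
}

.steinerCandidate <- function(g, s, superMembers, dg, head, nm, cost) {
  k <- length(superMembers)
  w <- cost[match(head, nm)]
  if (k > 1L) {
    # pairwise super-node distances and one representative shortest path
    reps <- vector("list", k)
    dmat <- matrix(Inf, k, k)
    dAll <- igraph::distances(dg, v = unlist(superMembers), mode = "out",
                              weights = w)
    srcOf <- rep(seq_len(k), lengths(superMembers))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      rows <- which(srcOf == i)
      sub <- dAll[rows, superMembers[[j]], drop = FALSE]
      dmat[i, j] <- dmat[j, i] <- min(sub)
    }
    sg <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    mstSg <- igraph::mst(sg, weights = igraph::E(sg)$weight)
    verts <- unlist(superMembers)
    for (e in seq_len(igraph::ecount(mstSg))) {
      ij <- igraph::ends(mstSg, e)
      i <- as.integer(ij[1]); j <- as.integer(ij[2])
      rows <- which(srcOf == i)
      sub <- dAll[rows, superMembers[[j]], drop = FALSE]
      hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      from <- unlist(superMembers)[rows[hit[1]]]
      to <- superMembers[[j]][hit[2]]
      sp <- igraph::shortest_paths(dg, from = from, to = to, mode = "out",
                                   weights = w)$vpath[[1]]
      verts <- union(verts, names(sp))
    }
  } else verts <- superMembers[[1]]
  sub <- igraph::induced_subgraph(g, verts)
  if (!igraph::is_connected(sub)) return(NULL)
  # spanning tree biased towards cheap (positive) nodes
  endCost <- matrix(cost[match(igraph::as_edgelist(sub), nm)],
                    ncol = 2L)
  tree <- igraph::mst(sub, weights = rowSums(endCost))
  .strongPrune(tree, s)
}

#' Heuristic maximum-weight connected subgraph
#'
#' A diffusion-flow-style heuristic: adjacent positive-score nodes are
#' contracted into super-nodes; cheapest connecting paths between
#' super-nodes are measured in a node-cost metric (traversing node v costs
#' `max(0, -score(v))`, already-included nodes cost 0); super-nodes are
#' greedily attached while the net gain is non-negative; finally,
#' negative-score nodes whose removal preserves connectivity are pruned.
#' Multi-component inputs are solved per component and the global best is
#' returned. The result is always connected and scores at least as well as
#' the best single node.
#'
#' @param net A [ScoredNetwork-class].
#' @return An [ActiveModule-class].
#' @export
solveMwcsHeuristic <- function(net) {
  stopifnot(is(net, "ScoredNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  s <- net@scores
  comps <- igraph::components(g)
  best <- NULL
  for (c in seq_len(comps$no)) {
    sub <- igraph::induced_subgraph(g, which(comps$membership == c))
    res <- .heuristicComponent(sub, s)
    if (is.null(best) || res$score > best$score ||
        (res$score == best$score && .lexLess(res$members, best$members)))
      best <- res
  }
  # never worse than the best single node anywhere
  single <- .bestSingleNode(s)
  if (s[single] > best$score)
    best <- list(members = single, score = unname(s[single]))
  new("ActiveModule", members = best$members,
      treeEdges = .spanningEdges(g, best$members),
      totalScore = unname(best$score))
}
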