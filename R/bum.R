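# Beta-uniform mixture (BUM) calibration of p-values into FDR-controlled
# node scores: the signal-noise decomposition behind active-module scoring.

.bumNegLogLik <- function(par, pv) {
  lam <- par[1]; a <- par[2]
  -sum(log(lam + (1 - lam) * a * pv^(a - 1)))
}

#' Fit a beta-uniform mixture to p-values
#'
#' Maximum-likelihood fit of the mixture density
#' `f(p) = lambda + (1 - lambda) * a * p^(a - 1)` on (0, 1], by bounded
#' quasi-Newton optimisation from multiple starts. `piUpper = lambda +
#' (1 - lambda) * a = f(1)` bounds the noise fraction.
#'
#' @param p Numeric vector of p-values (>= 100 values). Values of exactly 0
#'   are clamped to the smallest positive double with a warning; values > 1
#'   are an error.
#' @param nStarts Number of optimiser starts (default 5; a deterministic
#'   grid is used, so the fit needs no seed).
#' @return A [BumFit-class] object.
#' @export
fitBum <- function(p, nStarts = 5L) {
  p <- as.numeric(p)
  if (length(p) < 100L) stop("need at least 100 p-values")
  if (any(p > 1)) stop("p-values above 1")
  if (any(p <= 0)) {
    warning("p-values <= 0 clamped to the smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  eps <- 1e-6
  starts <- cbind(lam = seq(0.05, 0.95, length.out = nStarts),
                  a = seq(0.1, 0.9, length.out = nStarts))
  best <- NULL
  for (i in seq_len(nStarts)) {
    fit <- tryCatch(
      optim(starts[i, ], .bumNegLogLik, pv = p, method = "L-BFGS-B",
            lower = c(0, eps), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("BUM optimisation failed from every start")
  lam <- unname(best$par[1]); a <- unname(best$par[2])
  new("BumFit", lambda = lam, a = a, logLik = -best$value,
      piUpper = lam + (1 - lam) * a, n = length(p))
}

#' BUM p-value threshold at a target FDR
#'
#' The p-value `tau` at which the mixture's estimated false-discovery rate
#' equals `fdr`:
#' `tau = ((piUpper - lambda * fdr) / (fdr * (1 - lambda)))^(1 / (a - 1))`.
#' P-values below `tau` map to positive node scores.
#'
#' @param fit A [BumFit-class].
#' @param fdr Target false-discovery rate in (0, 1), default 0.05.
#' @return Threshold `tau` in (0, 1).
#' @export
bumTau <- function(fit, fdr = 0.05) {
  stopifnot(is(fit, "BumFit"))
  if (fdr <= 0 || fdr >= 1) stop("'fdr' must lie in (0, 1)")
  lam <- fit@lambda; a <- fit@a
  if (lam >= 1 - 1e-12)
    stop("no signal component (lambda = 1); scores undefined")
  if (fit@piUpper <= lam * fdr)
    stop("requested FDR not attainable: piUpper <= lambda * fdr")
  ((fit@piUpper - lam * fdr) / (fdr * (1 - lam)))^(1 / (a - 1))
}

#' FDR-calibrated node scores from p-values
#'
#' `s(p) = (a - 1) * (log(p) - log(tau))`: zero at `p = tau`, positive for
#' smaller p, monotone decreasing in p. Nodes without a p-value receive the
#' score of `defaultP` (0.5 by default), keeping them available as
#' connectors.
#'
#' @param fit A [BumFit-class].
#' @param p Named numeric vector of p-values (node -> p).
#' @param fdr Score-calibration FDR (default 0.05).
#' @param nodes Optional character vector of node ids to score; defaults to
#'   `names(p)`.
#' @param defaultP p-value assumed for nodes absent from `p` (default 0.5).
#' @return Named numeric vector of scores.
#' @export
scoreNodes <- function(fit, p, fdr = 0.05, nodes = names(p),
                       defaultP = 0.5) {
  stopifnot(is(fit, "BumFit"))
  tau <- bumTau(fit, fdr)
  pv <- setNames(rep(defaultP, length(nodes)), nodes)
  known <- intersect(nodes, names(p))
  pv[known] <- p[known]
  (fit@a - 1) * (log(pv) - log(tau))
}

#' Build a scored interaction network
#'
#' Assembles a simple undirected graph from an edge list and attaches node
#' scores (dropping edges whose endpoints are absent from `scores` is not
#' done: every node appearing in `edges` must be scored, or is given
#' `defaultScore`).
#'
#' @param edges Two-column character matrix or data.frame of undirected
#'   edges.
#' @param scores Named numeric vector of node scores.
#' @param defaultScore Score for nodes present in `edges` but absent from
#'   `scores` (default NA = error on such nodes).
#' @return A [ScoredNetwork-class].
#' @export
scoredNetwork <- function(edges, scores, defaultScore = NA_real_) {
  el <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(el) <- "character"
  nodes <- sort(unique(c(as.vector(el), names(scores))))
  s <- setNames(rep(defaultScore, length(nodes)), nodes)
  s[names(scores)] <- scores
  if (any(is.na(s)))
    stop("unscored nodes: ", paste(head(names(s)[is.na(s)], 5L),
                                   collapse = ", "))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  g <- igraph::simplify(g)
  new("ScoredNetwork", graph = g, scores = s[igraph::V(g)$name])
}

#' Transform a scored network into a prize-collecting Steiner tree instance
#'
#' With `wNeg = min(0, min(score))`, node profits are `score - wNeg` (>= 0)
#' and every edge gets uniform cost `-wNeg`, so for any subtree T,
#' `sum(profits) - cost * |edges(T)| = sum(scores) - wNeg`: the optima of
#' the maximum-weight connected subgraph problem and of the PCST instance
#' coincide (up to the constant offset).
#'
#' @param net A [ScoredNetwork-class].
#' @return List with `profits` (named, >= 0), `edgeCost` (scalar >= 0) and
#'   `offset` (`-wNeg`).
#' @export
mwcsToPcst <- function(net) {
  stopifnot(is(net, "ScoredNetwork"))
  s <- net@scores
  wNeg <- min(0, min(s))
  list(profits = s - wNeg, edgeCost = -wNeg, offset = -wNeg)
}
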