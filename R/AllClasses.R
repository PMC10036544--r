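#' @import methods
#' @importFrom stats median optim phyper quantile rnorm runif rbeta rchisq
#'   sd var cor p.adjust pf setNames
#' @importFrom utils head read.delim write.table combn packageVersion
NULL

#' Beta-uniform mixture fit of a p-value distribution
#'
#' Models a p-value vector as a two-component mixture of uniform noise
#' (weight \code{lambda}) and a Beta(a, 1) signal component (weight
#' \code{1 - lambda}, shape \code{0 < a < 1}), the classical calibration used
#' to convert p-values into FDR-controlled node scores for active-module
#' discovery.
#'
#' @slot lambda Mixture weight of the uniform (noise) component, in \[0, 1\].
#' @slot a Beta shape parameter of the signal component, in (0, 1).
#' @slot logLik Maximised log-likelihood.
#' @slot piUpper Upper bound on the fraction of noise p-values,
#'   \code{lambda + (1 - lambda) * a} (the mixture density at p = 1).
#' @slot n Number of p-values used in the fit.
#'
#' @seealso [fitBum()], [bumTau()], [scoreNodes()]
#' @export
setClass("BumFit",
  representation(lambda = "numeric", a = "numeric", logLik = "numeric",
                 piUpper = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "'lambda' must lie in [0, 1]")
    if (object@a <= 0 || object@a >= 1)
      msg <- c(msg, "'a' must lie in (0, 1)")
    if (abs(object@piUpper - (object@lambda + (1 - object@lambda) * object@a)) > 1e-8)
      msg <- c(msg, "'piUpper' inconsistent with lambda and a")
    if (length(msg)) msg else TRUE
  })

#' Protein-interaction graph with calibrated node scores
#'
#' An undirected simple graph whose vertices carry finite real scores
#' (positive = signal, negative = background); the substrate of
#' maximum-weight connected subgraph search.
#'
#' @slot graph An [igraph::graph] object (undirected, simple), with a vertex
#'   attribute \code{name}.
#' @slot scores Named numeric vector of node scores, one per vertex.
#'
#' @seealso [scoredNetwork()], [solveMwcsExact()], [nodeScores()]
#' @export
setClass("ScoredNetwork",
  representation(graph = "ANY", scores = "numeric"),
  validity = function(object) {
    msg <- character()
    g <- object@graph
    if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
      msg <- c(msg, "graph must be simple (no loops or multi-edges)")
    nm <- igraph::V(g)$name
    if (is.null(nm)) msg <- c(msg, "vertices must be named")
    else if (!identical(sort(nm), sort(names(object@scores))))
      msg <- c(msg, "'scores' names must match vertex names")
    if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
    if (length(msg)) msg else TRUE
  })

#' A maximal-scoring connected subnetwork (active module)
#'
#' @slot members Character vector of member node identifiers.
#' @slot treeEdges Two-column character matrix of spanning edges (a subset of
#'   the parent graph's edges connecting all members).
#' @slot totalScore Sum of member node scores.
#' @export
setClass("ActiveModule",
  representation(members = "character", treeEdges = "matrix",
                 totalScore = "numeric"),
  validity = function(object) {
    msg <- character()
    te <- object@treeEdges
    if (nrow(te) > 0L && ncol(te) != 2L)
      msg <- c(msg, "'treeEdges' must have two columns")
    if (nrow(te) > 0L && !all(as.vector(te) %in% object@members))
      msg <- c(msg, "tree edges must join member nodes")
    if (length(msg)) msg else TRUE
  })

#' GATC fragment-window track for DamID profiling
#'
#' Ordered genomic windows (one per GATC motif, motif centre +/- flank,
#' 500 bp by default) with per-condition raw read counts, reads-per-million
#' normalised values and per-window log2 fusion/control ratios. All external
#' coordinates are 0-based half-open (BED convention); windows are stored
#' internally as a [GenomicRanges::GRanges].
#'
#' @slot windows GRanges of windows, sorted by (chrom, start).
#' @slot counts Numeric matrix, windows x conditions, raw read counts.
#' @slot rpm Numeric matrix, reads-per-million normalised counts.
#' @slot log2Ratio Numeric vector of per-window log2 ratios (fusion vs
#'   control), or length 0 before [logRatio()] is applied.
#' @slot totals Named numeric vector of total mapped reads per condition.
#' @export
setClass("GatcWindowTrack",
  representation(windows = "ANY", counts = "matrix", rpm = "matrix",
                 log2Ratio = "numeric", totals = "numeric"),
  validity = function(object) {
    msg <- character()
    w <- object@windows
    if (!is(w, "GRanges")) return("'windows' must be a GRanges")
    if (is.unsorted(order(as.character(GenomicRanges::seqnames(w)),
                          GenomicRanges::start(w))))
      msg <- c(msg, "windows must be sorted by (chrom, start)")
    for (slot in c("counts", "rpm")) {
      m <- methods::slot(object, slot)
      if (nrow(m) > 0L && nrow(m) != length(w))
        msg <- c(msg, sprintf("'%s' rows must match number of windows", slot))
    }
    if (length(object@log2Ratio) &&
        length(object@log2Ratio) != length(w))
      msg <- c(msg, "'log2Ratio' length must match number of windows")
    if (nrow(object@rpm) > 0L && any(object@rpm < 0))
      msg <- c(msg, "normalised values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' A node partition with its quality value
#'
#' @slot membership Named integer vector mapping node to community id
#'   (1-based, contiguous).
#' @slot quality Quality value of the partition.
#' @slot qualityKind One of \code{"modularity_Q"}, \code{"cpm_H"},
#'   \code{"surprise_S"}.
#' @slot gamma Resolution parameter (constant Potts model), or \code{NA}.
#' @export
setClass("Partition",
  representation(membership = "integer", quality = "numeric",
                 qualityKind = "character", gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@membership)))
      msg <- c(msg, "'membership' must be named by node")
    if (!object@qualityKind %in% c("modularity_Q", "cpm_H", "surprise_S"))
      msg <- c(msg, "unknown 'qualityKind'")
    if (object@qualityKind == "cpm_H" && is.na(object@gamma))
      msg <- c(msg, "CPM partitions must record gamma")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "BumFit", function(object) {
  cat("BumFit: beta-uniform mixture of", object@n, "p-values\n")
  cat(sprintf("  lambda = %.4f  a = %.4f  piUpper = %.4f  logLik = %.2f\n",
              object@lambda, object@a, object@piUpper, object@logLik))
})

setMethod("show", "ScoredNetwork", function(object) {
  g <- object@graph
  cat("ScoredNetwork:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges\n")
  s <- object@scores
  cat(sprintf("  scores: %d positive / %d non-positive; range [%.3g, %.3g]\n",
              sum(s > 0), sum(s <= 0), min(s), max(s)))
})

setMethod("show", "ActiveModule", function(object) {
  cat("ActiveModule:", length(object@members), "nodes, total score",
      format(object@totalScore, digits = 6), "\n")
  cat("  members:", paste(head(object@members, 8L), collapse = ", "),
      if (length(object@members) > 8L) "..." else "", "\n")
})

setMethod("show", "GatcWindowTrack", function(object) {
  cat("GatcWindowTrack:", length(object@windows), "GATC windows on",
      length(GenomicRanges::seqinfo(object@windows)), "sequence(s)\n")
  if (ncol(object@counts)) cat("  conditions:",
      paste(colnames(object@counts), collapse = ", "), "\n")
  if (length(object@log2Ratio))
    cat(sprintf("  log2 ratio range [%.3f, %.3f]\n",
                min(object@log2Ratio), max(object@log2Ratio)))
})

setMethod("show", "Partition", function(object) {
  cat("Partition:", length(unique(object@membership)), "communities over",
      length(object@membership), "nodes\n")
  cat(sprintf("  %s = %.6g%s\n", object@qualityKind, object@quality,
              if (!is.na(object@gamma))
                sprintf(" (gamma = %g)", object@gamma) else ""))
})
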