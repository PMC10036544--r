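#' Accessors for adhesomics S4 classes
#'
#' Small accessor generics: node scores and the underlying igraph of a
#' [ScoredNetwork-class], members/edges/score of an [ActiveModule-class],
#' windows and value matrices of a [GatcWindowTrack-class], and
#' membership/quality of a [Partition-class].
#'
#' @param x An object of the documented class.
#' @return The slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeScores", function(x) standardGeneric("nodeScores"))
#' @rdname accessors
#' @export
setMethod("nodeScores", "ScoredNetwork", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))
#' @rdname accessors
#' @export
setMethod("interactionGraph", "ScoredNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setMethod("moduleMembers", "ActiveModule", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))
#' @rdname accessors
#' @export
setMethod("moduleScore", "ActiveModule", function(x) x@totalScore)

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))
#' @rdname accessors
#' @export
setMethod("treeEdges", "ActiveModule", function(x) x@treeEdges)

#' @rdname accessors
#' @export
setGeneric("gatcWindows", function(x) standardGeneric("gatcWindows"))
#' @rdname accessors
#' @export
setMethod("gatcWindows", "GatcWindowTrack", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setMethod("readCounts", "GatcWindowTrack", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("rpmValues", function(x) standardGeneric("rpmValues"))
#' @rdname accessors
#' @export
setMethod("rpmValues", "GatcWindowTrack", function(x) x@rpm)

#' @rdname accessors
#' @export
setGeneric("log2Ratios", function(x) standardGeneric("log2Ratios"))
#' @rdname accessors
#' @export
setMethod("log2Ratios", "GatcWindowTrack", function(x) x@log2Ratio)

#' @rdname accessors
#' @export
setGeneric("communityMembership",
           function(x) standardGeneric("communityMembership"))
#' @rdname accessors
#' @export
setMethod("communityMembership", "Partition", function(x) x@membership)

#' @rdname accessors
#' @export
setGeneric("partitionQuality", function(x) standardGeneric("partitionQuality"))
#' @rdname accessors
#' @export
setMethod("partitionQuality", "Partition",
          function(x) setNames(x@quality, x@qualityKind))

#' @rdname accessors
#' @export
setGeneric("resolutionGamma", function(x) standardGeneric("resolutionGamma"))
#' @rdname accessors
#' @export
setMethod("resolutionGamma", "Partition", function(x) x@gamma)
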