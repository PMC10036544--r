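# Over-representation annotation of differential sets and network clusters.

#' Read a gene-set collection in GMT format
#'
#' Tab-separated lines: set id, description, then member identifiers.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (members), with a `description`
#'   attribute carrying set descriptions.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
  names(sets) <- ids
  attr(sets, "description") <- setNames(
    vapply(parts, `[`, character(1), 2L), ids)
  sets
}

#' Over-representation analysis of a query set
#'
#' Hypergeometric upper-tail test of each gene set against the query,
#' restricted to the universe, with Benjamini-Hochberg correction across
#' the tested sets. Returns the sets passing `q < qThr` and
#' `enrichment ratio >= minRatio`, sorted by q ascending (ties by set id,
#' so the output is invariant to set iteration order).
#'
#' @param query Character vector of identifiers (must be a subset of
#'   `universe`).
#' @param universe Character vector: the reference identifier universe.
#' @param gsc Gene-set collection (named list of character vectors, e.g.
#'   from [readGmt()]).
#' @param qThr q-value threshold (default 0.05).
#' @param minRatio Minimum enrichment ratio to report (default 1).
#' @return data.frame with columns `setId`, `overlap`, `setSize`,
#'   `querySize`, `universeSize`, `p`, `q`, `enrichmentRatio`.
#' @export
annotateSets <- function(query, universe, gsc, qThr = 0.05, minRatio = 1) {
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query identifiers outside universe: ",
         paste(head(bad, 5L), collapse = ", "))
  N <- length(universe); n <- length(query)
  recs <- lapply(sort(names(gsc)), function(sid) {
    members <- intersect(gsc[[sid]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    x <- length(intersect(members, query))
    ora <- hypergeomORA(x, K, n, N)
    data.frame(setId = sid, overlap = x, setSize = K, querySize = n,
               universeSize = N, p = ora$p,
               enrichmentRatio = ora$enrichmentRatio,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs))
    return(data.frame(setId = character(), overlap = integer(),
                      setSize = integer(), querySize = integer(),
                      universeSize = integer(), p = numeric(),
                      q = numeric(), enrichmentRatio = numeric()))
  recs$q <- bhAdjust(recs$p)
  recs <- recs[recs$q < qThr & !is.na(recs$enrichmentRatio) &
                 recs$enrichmentRatio >= minRatio, , drop = FALSE]
  recs <- recs[order(recs$q, recs$setId), ,
               drop = FALSE][, c("setId", "overlap", "setSize", "querySize",
                                 "universeSize", "p", "q",
                                 "enrichmentRatio")]
  rownames(recs) <- NULL
  recs
}

#' Annotate network communities with their top enriched functions
#'
#' Runs [annotateSets()] for each community (BH correction within each
#' community's scan, or globally across all communities' tests when
#' `globalCorrection = TRUE`) and keeps the `topK` most significant set
#' names; communities with no significant set are labelled "unannotated".
#'
#' @param part A [Partition-class] (or named membership vector).
#' @param universe Character identifier universe (community members must
#'   belong to it).
#' @param gsc Gene-set collection.
#' @param topK Labels kept per community (default 2).
#' @param qThr q-value threshold (default 0.05).
#' @param globalCorrection Apply BH across all communities jointly.
#' @return Named list community -> character vector of set ids (or
#'   "unannotated").
#' @export
annotateClusters <- function(part, universe, gsc, topK = 2L, qThr = 0.05,
                             globalCorrection = FALSE) {
  memb <- if (is(part, "Partition")) part@membership else part
  comms <- sort(unique(memb))
  if (globalCorrection) {
    # pool raw p-values across communities, correct once, then pick top K
    all <- lapply(comms, function(cc) {
      q <- names(memb)[memb == cc]
      r <- annotateSets(q, universe, gsc, qThr = 1.01, minRatio = 0)
      if (nrow(r)) r$community <- cc
      r
    })
    tab <- do.call(rbind, all[vapply(all, nrow, integer(1)) > 0])
    out <- setNames(vector("list", length(comms)), comms)
    if (!is.null(tab) && nrow(tab)) {
      tab$q <- bhAdjust(tab$p)
      tab <- tab[tab$q < qThr & tab$enrichmentRatio >= 1, , drop = FALSE]
      for (cc in comms) {
        sub <- tab[tab$community == cc, , drop = FALSE]
        sub <- sub[order(sub$q, sub$setId), , drop = FALSE]
        out[[as.character(cc)]] <- if (nrow(sub)) head(sub$setId, topK)
                                   else "unannotated"
      }
    } else for (cc in comms) out[[as.character(cc)]] <- "unannotated"
    return(out)
  }
  out <- lapply(comms, function(cc) {
    q <- names(memb)[memb == cc]
    r <- annotateSets(q, universe, gsc, qThr = qThr, minRatio = 1)
    if (nrow(r)) head(r$setId, topK) else "unannotated"
  })
  setNames(out, comms)
}
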