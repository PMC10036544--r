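# Plain-text interchange: abundance TSV (first column = protein id, header
# = sample ids, empty cell = missing), edge lists (TSV or SIF), score and
# partition tables. Every table written by the pipeline carries a header
# comment naming the producing stage and a parameter hash.

#' Read an abundance matrix TSV
#'
#' First column protein ids, remaining columns samples; empty cells are
#' missing values.
#'
#' @param path TSV path.
#' @param group Character vector of group labels, one per sample column.
#' @return Abundance SummarizedExperiment (see [abundanceExperiment()]).
#' @export
readAbundanceTsv <- function(path, group) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  abundanceExperiment(m, group)
}

.stageHeader <- function(stage, params) {
  s <- paste(names(params),
             vapply(params, function(x) paste(format(x), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(paste0(stage, "|", s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("# stage=%s params=%08x", stage, h)
}

.writeTable <- function(df, path, stage, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stageHeader(stage, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an abundance matrix TSV
#'
#' @param se Abundance SummarizedExperiment.
#' @param path Output path.
#' @param stage Stage name recorded in the header comment.
#' @param params Parameter list recorded (hashed) in the header comment.
#' @export
writeAbundanceTsv <- function(se, path, stage = "prep", params = list()) {
  m <- SummarizedExperiment::assay(se, 1L)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stageHeader(stage, params), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}

#' Read an undirected edge list (TSV or SIF)
#'
#' Two-column TSV (from, to), or three-column SIF
#' (from, interaction, to).
#'
#' @param path File path.
#' @return Two-column character matrix.
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  el <- if (ncol(df) >= 3L && grepl("\\.sif$", path))
    cbind(as.character(df[[1]]), as.character(df[[3]]))
  else
    cbind(as.character(df[[1]]), as.character(df[[2]]))
  el[el[, 1] != el[, 2], , drop = FALSE]
}

#' Write a module's spanning tree as SIF
#'
#' @param module An [ActiveModule-class].
#' @param path Output path.
#' @export
writeModuleSif <- function(module, path) {
  te <- treeEdges(module)
  if (nrow(te))
    write.table(data.frame(te[, 1], "pp", te[, 2]), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  else
    writeLines(moduleMembers(module), path)
  invisible(path)
}
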