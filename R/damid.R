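# DamID lamina-association profiling: GATC fragment windows, read counting,
# reads-per-million normalisation, log2 fusion/control ratios, and
# shuffle-based peak FDR. All external coordinates are 0-based half-open
# (BED convention).

#' Build the GATC fragment-window map of a genome
#'
#' Scans each chromosome for GATC motifs (case-insensitive; GATC is its own
#' reverse complement, so a forward scan suffices) and creates one window
#' per motif, centred on the motif centre (motif start + 2 in 0-based
#' coordinates) and extended by `flank` bp on either side (500-bp windows
#' by default), clipped at chromosome ends. Windows may overlap.
#'
#' @param genome A [Biostrings::DNAStringSet] (named chromosomes) or path
#'   to a FASTA file.
#' @param flank Half-window size in bp (default 250).
#' @return A [GatcWindowTrack-class] skeleton (no counts yet).
#' @export
buildGatcMap <- function(genome, flank = 250L) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!length(genome) || all(Biostrings::width(genome) == 0L))
    stop("empty genome")
  names(genome) <- sub("\\s.*$", "", names(genome))
  wins <- list()
  for (chrom in names(genome)) {
    hits <- Biostrings::matchPattern("GATC", genome[[chrom]], fixed = TRUE)
    if (!length(hits)) next
    center0 <- BiocGenerics::start(hits) + 1L  # 1-based start + 2 - 1
    chromLen <- length(genome[[chrom]])
    s0 <- pmax(center0 - flank, 0L)
    e0 <- pmin(center0 + flank, chromLen)
    wins[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = s0 + 1L, end = e0))
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                              seqlengths = Biostrings::width(genome))
  if (!length(wins)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
  } else {
    gr <- suppressWarnings(do.call(c, unname(wins)))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqinfo(gr) <- si
    gr <- GenomicRanges::sort(gr)
  }
  new("GatcWindowTrack", windows = gr,
      counts = matrix(numeric(), length(gr), 0L,
                      dimnames = list(NULL, NULL)),
      rpm = matrix(numeric(), length(gr), 0L),
      log2Ratio = numeric(0),
      totals = setNames(numeric(0), character(0)))
}

.readBed3 <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write read start positions as 3-column BED
#'
#' Each read becomes a 1-bp interval `start, start + 1` (0-based
#' half-open).
#'
#' @param starts Integer vector of 0-based read start positions.
#' @param chrom Chromosome name (recycled).
#' @param path Output path.
#' @export
writeReadsBed <- function(starts, chrom, path) {
  write.table(data.frame(chrom, as.integer(starts),
                         as.integer(starts) + 1L),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Count reads per GATC window
#'
#' A read contributes 1 to every window whose interval contains its start
#' position (windows overlap, so a read can count twice). Read length is
#' ignored throughout: inputs are start positions.
#'
#' @param track A [GatcWindowTrack-class].
#' @param reads Data frame with columns `chrom` and `start` (0-based), a
#'   path to a BED file, or an integer vector of starts (single-chromosome
#'   tracks only).
#' @param condition Condition label for the count column (e.g. "fusion",
#'   "control").
#' @return The track with a `condition` column added to its counts.
#' @export
countReads <- function(track, reads, condition) {
  stopifnot(is(track, "GatcWindowTrack"))
  w <- track@windows
  if (is.character(reads) && length(reads) == 1L) reads <- .readBed3(reads)
  if (is.numeric(reads)) {
    chroms <- unique(as.character(GenomicRanges::seqnames(w)))
    if (length(chroms) != 1L)
      stop("bare start positions need a single-chromosome track")
    reads <- data.frame(chrom = chroms, start = as.integer(reads))
  }
  unknown <- setdiff(unique(reads$chrom), GenomeInfoDb::seqlevels(w))
  if (length(unknown))
    stop("reads on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L,
                                                 width = 1L))
  cnt <- GenomicRanges::countOverlaps(w, pts)
  counts <- cbind(track@counts, as.numeric(cnt))
  colnames(counts) <- c(colnames(track@counts), condition)
  methods::initialize(track, counts = counts)
}

#' Normalise window counts to reads per million
#'
#' `rpm = raw * 1e6 / totalMapped`, per condition; totals default to the
#' condition's column sum of raw read counts but should be the library's
#' total mapped reads when windows cover only part of the genome.
#'
#' @param track A [GatcWindowTrack-class] with counts.
#' @param totals Named numeric vector of total mapped reads per condition;
#'   defaults to column sums.
#' @return Track with the `rpm` matrix filled.
#' @export
normalizeRpm <- function(track, totals = NULL) {
  stopifnot(is(track, "GatcWindowTrack"))
  cn <- colnames(track@counts)
  if (is.null(totals)) totals <- colSums(track@counts)
  if (is.null(names(totals))) names(totals) <- cn
  if (any(totals[cn] <= 0)) stop("zero total mapped reads")
  rpm <- sweep(track@counts, 2L, totals[cn], function(x, t) x * 1e6 / t)
  methods::initialize(track, rpm = rpm, totals = totals[cn])
}

#' Per-window log2 fusion/control ratio
#'
#' `log2((rpm_fusion + eps) / (rpm_control + eps))` with a pseudo-value
#' `eps` (0.5 RPM by default) guarding zero counts; a window with zero
#' reads in both conditions gets ratio exactly 0.
#'
#' @param track A normalised [GatcWindowTrack-class].
#' @param fusion,control Condition column names (defaults "fusion",
#'   "control").
#' @param eps Pseudo-value in RPM units (>= 0).
#' @return Track with `log2Ratio` filled.
#' @export
logRatio <- function(track, fusion = "fusion", control = "control",
                     eps = 0.5) {
  stopifnot(is(track, "GatcWindowTrack"))
  if (eps < 0) stop("'eps' must be non-negative")
  if (!all(c(fusion, control) %in% colnames(track@rpm)))
    stop("both conditions must be normalised first")
  lr <- log2((track@rpm[, fusion] + eps) / (track@rpm[, control] + eps))
  methods::initialize(track, log2Ratio = unname(lr))
}

.runsAtThreshold <- function(vals, chromId, t, minRun) {
  # maximal runs of >= minRun consecutive windows (same chromosome) with
  # value >= t; returns start/end window indices. chromId: integer codes.
  code <- chromId * 2L + (vals >= t)   # odd codes = above-threshold runs
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values %% 2L == 1L) & r$lengths >= minRun
  cbind(start = starts[keep], end = ends[keep])
}

#' Shuffle-FDR peak calling on the log2-ratio track
#'
#' Candidate thresholds are the quantiles of the log2 ratios at levels
#' `minQuantile, minQuantile + step, ..., 1`. At each threshold, observed
#' peaks are maximal runs of at least `minRun` consecutive same-chromosome
#' windows at or above the threshold; the null peak count is the mean over
#' `iterations` random permutations of the ratio values across windows
#' (destroying autocorrelation while preserving the marginal distribution —
#' a deliberately simple null). `FDR(t) = min(1, null / observed)` (0/0 is
#' 1). Each observed run is reported at the smallest threshold where
#' `FDR < fdrThr`; overlapping reported runs are merged, keeping the best
#' (lowest) FDR.
#'
#' @param track A [GatcWindowTrack-class] with `log2Ratio`.
#' @param minQuantile Lowest quantile level scanned (default 0.75).
#' @param step Quantile step (default 0.0005).
#' @param iterations Number of permutations (default 15).
#' @param fdrThr Peak FDR threshold (default 0.05).
#' @param minRun Minimum run length in windows (default 5: at least five
#'   consecutive windows, about 2.5 kb, must exceed the threshold; this
#'   sets the permutation-null run rate and hence the sensitivity floor).
#' @param seed Integer seed for the permutations.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, merged peak extents), `threshold` and `fdr`; zero rows when
#'   nothing passes.
#' @export
callPeaks <- function(track, minQuantile = 0.75, step = 5e-4,
                      iterations = 15L, fdrThr = 0.05, minRun = 5L,
                      seed = 1L) {
  stopifnot(is(track, "GatcWindowTrack"))
  if (minQuantile >= 1) stop("'minQuantile' must be < 1")
  if (step <= 0) stop("'step' must be positive")
  vals <- track@log2Ratio
  if (!length(vals)) stop("log2 ratios not computed")
  if (length(vals) < 10L) stop("need at least 10 windows")
  w <- track@windows
  chrom <- as.character(GenomicRanges::seqnames(w))
  chromId <- as.integer(factor(chrom, levels = unique(chrom)))
  levels <- seq(minQuantile, 1, by = step)
  thresholds <- unname(quantile(vals, levels))
  perms <- withSeed(seed, replicate(iterations, sample(vals),
                                    simplify = FALSE))
  hits <- NULL
  for (t in thresholds) {
    obs <- .runsAtThreshold(vals, chromId, t, minRun)
    nObs <- nrow(obs)
    if (nObs == 0L) next
    nNull <- mean(vapply(perms, function(pv)
      nrow(.runsAtThreshold(pv, chromId, t, minRun)), numeric(1)))
    fdr <- min(1, nNull / nObs)
    if (fdr < fdrThr) {
      hits <- rbind(hits, data.frame(i1 = obs[, 1], i2 = obs[, 2],
                                     threshold = t, fdr = fdr))
    }
  }
  if (is.null(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), threshold = numeric(),
                      fdr = numeric()))
  # smallest passing threshold first (thresholds scanned ascending), so the
  # first record of a merged group carries the reported threshold/FDR pair;
  # keep the lowest FDR among merged runs
  gr <- GenomicRanges::GRanges(
    chrom[hits$i1],
    IRanges::IRanges(GenomicRanges::start(w)[hits$i1],
                     GenomicRanges::end(w)[hits$i2]),
    threshold = hits$threshold, fdr = hits$fdr)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  rm <- S4Vectors::mcols(red)$revmap
  bestFdr <- vapply(rm, function(ix) min(gr$fdr[ix]), numeric(1))
  bestThr <- vapply(rm, function(ix)
    gr$threshold[ix][which.min(gr$fdr[ix])], numeric(1))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             threshold = bestThr, fdr = bestFdr,
             stringsAsFactors = FALSE)
}

#' Mean log2 ratio over a genomic interval
#'
#' Unweighted mean of the log2 ratios of all windows overlapping the
#' 0-based half-open query interval (the region-assay quantification used
#' e.g. for a candidate enhancer).
#'
#' @param track A [GatcWindowTrack-class] with `log2Ratio`.
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Mean log2 ratio (scalar).
#' @export
quantifyRegion <- function(track, chrom, start, end) {
  stopifnot(is(track, "GatcWindowTrack"))
  if (!length(track@log2Ratio)) stop("log2 ratios not computed")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  ov <- GenomicRanges::findOverlaps(q, track@windows)
  if (!length(ov)) stop("no window overlaps the interval")
  mean(track@log2Ratio[S4Vectors::subjectHits(ov)])
}

#' Write the log2-ratio track as bedGraph
#'
#' @param track A [GatcWindowTrack-class] with `log2Ratio`.
#' @param path Output path.
#' @export
writeBedGraph <- function(track, path) {
  w <- track@windows
  write.table(data.frame(as.character(GenomicRanges::seqnames(w)),
                         GenomicRanges::start(w) - 1L,
                         GenomicRanges::end(w),
                         track@log2Ratio),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
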