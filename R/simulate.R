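# Synthetic-data generators with recorded ground truth. Every generator is a
# pure function of its arguments (including seed): the caller's RNG state is
# saved and restored, so reruns are bit-identical and independent of ambient
# RNG use.

withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a label-free proteomics abundance matrix with known truth
#'
#' Draws per-protein baseline log2 intensities from a normal distribution
#' (log-normal on the raw scale), shifts a chosen fraction of proteins by
#' +/- `effectLog2fc` in the second group, and censors low-intensity cells
#' with an intensity-dependent (missing-not-at-random, MNAR) mechanism:
#' cells whose latent intensity falls below the column `mnarQuantile`
#' quantile are set missing with probability `mnarProb`, plus a small
#' completely-at-random (MCAR) rate elsewhere. The MNAR mechanism is a
#' probabilistic threshold rather than a hard truncation, so downstream
#' predictive-mean-matching imputation retains information to exploit.
#'
#' @param nProteins Number of proteins (rows).
#' @param nPerGroup Replicates per group (>= 2); two groups are simulated.
#' @param fracDiff Fraction of proteins given a true group effect.
#' @param effectLog2fc Absolute log2 fold change of differential proteins
#'   (sign randomised per protein).
#' @param noiseSd Replicate noise standard deviation, log2 units. The
#'   default 0.3 corresponds to a typical label-free replicate coefficient
#'   of variation around 20 percent.
#' @param mnarQuantile Column quantile below which latent intensities are
#'   censored with probability `mnarProb`.
#' @param mnarProb Missingness probability below the quantile (default 0.8).
#' @param mcarRate Completely-at-random missingness rate (default 0.02).
#' @param baselineMean,baselineSd Mean and sd of per-protein baseline log2
#'   intensity (defaults 25 and 2.5, the usual LFQ intensity scale).
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with
#'   \describe{
#'     \item{se}{[SummarizedExperiment::SummarizedExperiment] with assay
#'       `log2intensity` (NA = missing) and `colData$group` in
#'       \{"group1","group2"\}.}
#'     \item{truth}{List: `differentialIds`, `trueLog2fc` (named, zero for
#'       null proteins), `mnarMask`, `mcarMask` (disjoint logical matrices),
#'       and `latent` (the uncensored intensity matrix).}
#'   }
#' @export
simulateLfq <- function(nProteins = 2000, nPerGroup = 3, fracDiff = 0.1,
                        effectLog2fc = 2, noiseSd = 0.3,
                        mnarQuantile = 0.25, mnarProb = 0.8,
                        mcarRate = 0.02, baselineMean = 25,
                        baselineSd = 2.5, seed = 1L) {
  if (nProteins < 1L || nPerGroup < 2L) stop("non-positive dimensions")
  if (fracDiff < 0 || fracDiff > 1) stop("'fracDiff' must lie in [0, 1]")
  if (mnarQuantile < 0 || mnarQuantile >= 1)
    stop("'mnarQuantile' must lie in [0, 1)")
  withSeed(seed, {
    ids <- sprintf("P%04d", seq_len(nProteins))
    nS <- 2L * nPerGroup
    samples <- c(sprintf("g1_r%d", seq_len(nPerGroup)),
                 sprintf("g2_r%d", seq_len(nPerGroup)))
    group <- rep(c("group1", "group2"), each = nPerGroup)
    nDiff <- round(fracDiff * nProteins)
    diffIdx <- sort(sample.int(nProteins, nDiff))
    lfc <- setNames(numeric(nProteins), ids)
    if (nDiff > 0)
      lfc[diffIdx] <- effectLog2fc * sample(c(-1, 1), nDiff, replace = TRUE)
    base <- rnorm(nProteins, baselineMean, baselineSd)
    latent <- matrix(base, nProteins, nS) +
      matrix(rep(lfc, nS) * rep(group == "group2", each = nProteins),
             nProteins, nS) +
      matrix(rnorm(nProteins * nS, 0, noiseSd), nProteins, nS)
    dimnames(latent) <- list(ids, samples)
    mnarMask <- matrix(FALSE, nProteins, nS, dimnames = dimnames(latent))
    for (j in seq_len(nS)) {
      thr <- quantile(latent[, j], mnarQuantile)
      low <- latent[, j] < thr
      mnarMask[low, j] <- runif(sum(low)) < mnarProb
    }
    mcarMask <- matrix(runif(nProteins * nS) < mcarRate, nProteins, nS,
                       dimnames = dimnames(latent)) & !mnarMask
    values <- latent
    values[mnarMask | mcarMask] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2intensity = values),
      colData = S4Vectors::DataFrame(group = group, row.names = samples))
    list(se = se,
         truth = list(differentialIds = ids[diffIdx],
                      trueLog2fc = lfc, mnarMask = mnarMask,
                      mcarMask = mcarMask, latent = latent))
  })
}

#' Simulate a degree-heterogeneous interaction network with a planted module
#'
#' Grows a preferential-attachment (scale-free-like) graph and plants a
#' connected module of `moduleSize` nodes whose internal edge density is at
#' least twice the background density; the planted membership is recorded as
#' ground truth for recovery benchmarks. The graph is simple (no loops or
#' multi-edges).
#'
#' @param nNodes Number of nodes.
#' @param meanDegree Target mean degree (>= 1).
#' @param moduleSize Planted module size (<= `nNodes`).
#' @param seed Integer seed.
#' @return List with `edges` (two-column character matrix), `nodes`
#'   (character vector) and `truth` (list: `plantedMembers`,
#'   `plantedScoreBoost` = achieved internal/background density ratio).
#' @export
simulatePpiNetwork <- function(nNodes = 200, meanDegree = 4, moduleSize = 20,
                               seed = 1L) {
  if (moduleSize > nNodes) stop("'moduleSize' must not exceed 'nNodes'")
  if (meanDegree < 1) stop("'meanDegree' must be >= 1")
  withSeed(seed, {
    m <- max(1L, round(meanDegree / 2))
    g <- igraph::sample_pa(nNodes, m = m, directed = FALSE)
    g <- igraph::simplify(g)
    ids <- sprintf("n%03d", seq_len(nNodes))
    igraph::V(g)$name <- ids
    # connected planted set: BFS ball from a random root (tree edges are
    # graph edges, so the induced subgraph is connected)
    root <- sample.int(nNodes, 1L)
    ord <- igraph::bfs(g, root = root, order = TRUE)$order
    members <- sort(as.integer(ord)[seq_len(moduleSize)])
    if (moduleSize > 1L) {
      dens <- igraph::edge_density(g)
      target <- ceiling(2 * dens * choose(moduleSize, 2))
      pairs <- t(combn(members, 2L))
      have <- igraph::get_edge_ids(g, t(pairs)) > 0
      nAdd <- target - sum(have)
      if (nAdd > 0) {
        cand <- which(!have)
        add <- pairs[sample(cand, min(nAdd, length(cand))), , drop = FALSE]
        g <- igraph::add_edges(g, as.vector(t(add)))
      }
      inside <- sum(igraph::get_edge_ids(g, t(pairs)) > 0)
      boost <- (inside / choose(moduleSize, 2)) / igraph::edge_density(g)
    } else boost <- 1
    el <- igraph::as_edgelist(g, names = TRUE)
    list(edges = el, nodes = ids,
         truth = list(plantedMembers = ids[members],
                      plantedScoreBoost = boost))
  })
}

#' Simulate p-values from a beta-uniform mixture
#'
#' With probability `lam` a value is uniform(0,1) (noise); otherwise it is
#' Beta(`a`, 1) (signal, concentrated near zero for small `a`). Values are
#' clamped into (0, 1].
#'
#' @param n Number of p-values.
#' @param lam Uniform-component weight in \[0, 1\].
#' @param a Beta shape in (0, 1).
#' @param seed Integer seed.
#' @return Numeric vector of p-values in (0, 1].
#' @export
simulateBumPvalues <- function(n, lam, a, seed = 1L) {
  if (a <= 0 || a >= 1) stop("'a' must lie in (0, 1)")
  if (lam < 0 || lam > 1) stop("'lam' must lie in [0, 1]")
  withSeed(seed, {
    noise <- runif(n) < lam
    p <- ifelse(noise, runif(n), rbeta(n, a, 1))
    pmax(p, .Machine$double.xmin)
  })
}

#' Simulate a DamID experiment: genome, fusion reads and control reads
#'
#' Builds a synthetic chromosome carrying GATC motifs at near-regular
#' spacing (the background sequence is scrubbed of accidental GATCs so the
#' motif density is controlled), then samples read start positions:
#' uniformly over the chromosome for the untethered Dam control, and with
#' sampling weight multiplied by `enrichment` inside the planted
#' lamina-associated domains (LADs) for the Dam-lamin B1 fusion. Reads are
#' start positions only (0-based), matching start-position BED input.
#'
#' @param chromLen Chromosome length in bp.
#' @param gatcSpacing Approximate motif spacing in bp (>= 8).
#' @param lads Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), non-overlapping and sorted; may have zero rows.
#' @param enrichment Fold weight (>= 1) of fusion reads inside LADs.
#' @param readsPerCondition Reads sampled per condition.
#' @param seed Integer seed.
#' @param dir Optional directory: writes `genome.fa`, `fusion.bed`,
#'   `control.bed` there.
#' @return List: `genome` ([Biostrings::DNAStringSet], one chromosome
#'   "chrS"), `fusionReads`, `controlReads` (0-based integer start
#'   positions), `truth` (list: `lads`, `enrichment`), and file paths when
#'   `dir` is given.
#' @export
simulateDamid <- function(chromLen = 2e5, gatcSpacing = 200,
                          lads = data.frame(chrom = "chrS",
                                            start = c(48000, 120000),
                                            end = c(58000, 130000)),
                          enrichment = 4, readsPerCondition = 2e5,
                          seed = 1L, dir = NULL) {
  if (gatcSpacing < 8) stop("'gatcSpacing' must be >= 8")
  if (readsPerCondition <= 0) stop("'readsPerCondition' must be positive")
  if (enrichment < 1) stop("'enrichment' must be >= 1")
  if (nrow(lads)) {
    if (any(lads$start < 0) || any(lads$end > chromLen))
      stop("LAD interval outside chromosome")
    o <- order(lads$start)
    lads <- lads[o, , drop = FALSE]
    if (any(lads$start >= lads$end) ||
        (nrow(lads) > 1L && any(lads$start[-1] < lads$end[-nrow(lads)])))
      stop("LAD intervals must be non-overlapping, start < end")
  }
  withSeed(seed, {
    seq <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
    # scrub accidental GATCs so motif spacing is controlled
    repeat {
      s <- paste(seq, collapse = "")
      hits <- gregexpr("GATC", s, fixed = TRUE)[[1]]
      if (hits[1] == -1L) break
      seq[hits + 3L] <- sample(c("A", "G"), length(hits), replace = TRUE)
    }
    # plant motifs at jittered regular positions (1-based starts)
    nMotif <- floor(chromLen / gatcSpacing)
    starts <- round(seq(gatcSpacing / 2, by = gatcSpacing,
                        length.out = nMotif) +
                    runif(nMotif, -0.1, 0.1) * gatcSpacing)
    starts <- starts[starts >= 1 & starts + 3 <= chromLen]
    for (s0 in starts) seq[s0:(s0 + 3L)] <- c("G", "A", "T", "C")
    genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
    names(genome) <- "chrS"

    sampleReads <- function(n, weighted) {
      if (!weighted || !nrow(lads)) return(sample.int(chromLen, n,
                                                      replace = TRUE) - 1L)
      ladLen <- sum(lads$end - lads$start)
      wLad <- ladLen * enrichment
      wBg <- chromLen - ladLen
      inLad <- runif(n) < wLad / (wLad + wBg)
      pos <- integer(n)
      # uniform within the LAD union via cumulative lengths
      cum <- cumsum(lads$end - lads$start)
      u <- floor(runif(sum(inLad)) * ladLen)
      idx <- pmin(findInterval(u, c(0, cum)), nrow(lads))
      pos[inLad] <- as.integer(lads$start[idx] + (u - c(0, cum)[idx]))
      # background: uniform over the complement
      nBg <- sum(!inLad)
      if (nBg) {
        ub <- floor(runif(nBg) * wBg)
        gapStarts <- c(0, lads$end)
        gapEnds <- c(lads$start, chromLen)
        gl <- gapEnds - gapStarts
        cumg <- cumsum(gl)
        gi <- pmin(findInterval(ub, c(0, cumg)), length(gl))
        pos[!inLad] <- as.integer(gapStarts[gi] + (ub - c(0, cumg)[gi]))
      }
      pos
    }
    control <- sampleReads(readsPerCondition, weighted = FALSE)
    fusion <- sampleReads(readsPerCondition, weighted = TRUE)
    out <- list(genome = genome, fusionReads = fusion,
                controlReads = control,
                truth = list(lads = lads, enrichment = enrichment))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, fa, width = 60L)
      fb <- file.path(dir, "fusion.bed")
      cb <- file.path(dir, "control.bed")
      writeReadsBed(fusion, "chrS", fb)
      writeReadsBed(control, "chrS", cb)
      out$paths <- c(genome = fa, fusion = fb, control = cb)
    }
    out
  })
}

#' Simulate a pair of 3D images with controlled foreground overlap
#'
#' Two voxel images whose foreground supports share exactly
#' `round(overlapFrac * nForeground)` voxels, plus a cuboid-shell mask
#' marking a "nuclear membrane" region. Foreground voxels carry a constant
#' intensity (default 200) with optional additive Gaussian noise; background
#' is zero.
#'
#' @param shape Integer vector of 3 dimensions.
#' @param overlapFrac Fraction of image-A foreground shared with B, in
#'   \[0, 1\].
#' @param fgFrac Fraction of voxels in each foreground (default 0.05).
#' @param fgIntensity Foreground intensity (default 200).
#' @param noiseSd Additive Gaussian noise sd (default 0, exact supports).
#' @param seed Integer seed.
#' @return List: `a`, `b` (3D arrays), `mask` (logical 3D array, membrane
#'   shell), `truth` (list: `supportA`, `supportB` voxel indices,
#'   `overlap` = shared voxel count).
#' @export
simulateVoxelPair <- function(shape = c(32, 32, 16), overlapFrac = 0.5,
                              fgFrac = 0.05, fgIntensity = 200,
                              noiseSd = 0, seed = 1L) {
  if (length(shape) != 3L || any(shape < 1)) stop("empty shape")
  if (overlapFrac < 0 || overlapFrac > 1)
    stop("'overlapFrac' must lie in [0, 1]")
  withSeed(seed, {
    nv <- prod(shape)
    nA <- max(1L, round(fgFrac * nv))
    k <- round(overlapFrac * nA)
    idx <- sample.int(nv, 2L * nA - k)  # enough for A and B \ A
    supportA <- idx[seq_len(nA)]
    supportB <- c(supportA[seq_len(k)],
                  idx[seq.int(nA + 1L, length.out = nA - k)])
    mk <- function(support) {
      img <- array(0, dim = shape)
      img[support] <- fgIntensity
      if (noiseSd > 0) img <- pmax(img + array(rnorm(nv, 0, noiseSd), shape), 0)
      img
    }
    # membrane shell: voxels between 50% and 80% of the half-extent radius
    # (Chebyshev metric), a cuboid shell mimicking a nuclear rim
    ax <- lapply(shape, function(d) abs(seq_len(d) - (d + 1) / 2) / (d / 2))
    r <- array(0, dim = shape)
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      r[i, j, ] <- pmax(ax[[1]][i], ax[[2]][j], ax[[3]])
    mask <- r >= 0.5 & r < 0.8
    list(a = mk(supportA), b = mk(supportB), mask = mask,
         truth = list(supportA = sort(supportA), supportB = sort(supportB),
                      overlap = k))
  })
}
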