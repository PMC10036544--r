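test_that("GATC windows are motif-centred, 500 bp, clipped at ends", {
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("A", 300), "GATC", strrep("A", 700))))
  tr <- buildGatcMap(seqs)
  w <- gatcWindows(tr)
  expect_length(w, 1)
  expect_equal(BiocGenerics::width(w), 500)
  # centre = 0-based motif start (300) + 2 -> window [52, 552)
  expect_equal(BiocGenerics::start(w) - 1L, 52)
  expect_equal(BiocGenerics::end(w), 552)

  none <- buildGatcMap(Biostrings::DNAStringSet(c(chr1 = strrep("ACT", 100))))
  expect_length(gatcWindows(none), 0)

  # motif at 0-based position 10: clipped to [0, 262)
  early <- buildGatcMap(Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("A", 10), "GATC", strrep("A", 300)))))
  w2 <- gatcWindows(early)
  expect_equal(BiocGenerics::start(w2) - 1L, 0)
  expect_equal(BiocGenerics::end(w2), 262)

  expect_error(buildGatcMap(Biostrings::DNAStringSet()), "empty genome")
})

test_that("read counting follows start-position containment", {
  # two motifs 300 bp apart: overlapping windows
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 400), "GATC", strrep("A", 296), "GATC", strrep("A", 500))))
  tr <- buildGatcMap(seqs)
  expect_length(gatcWindows(tr), 2)

  # read at the first window's centre counts once; a read in the overlap
  # zone counts in both windows
  center1 <- 402
  overlapPos <- 600   # inside [152, 652) and [452, 952)
  tr2 <- countReads(tr, c(center1, overlapPos), "fusion")
  expect_equal(unname(readCounts(tr2)[, "fusion"]), c(2, 1))

  expect_error(countReads(tr, data.frame(chrom = "chrX", start = 5),
                          "fusion"), "unknown chromosome")
})

test_that("window counts equal a brute-force interval scan", {
  sim <- simulateDamid(chromLen = 5e4, gatcSpacing = 250,
                       lads = data.frame(chrom = "chrS", start = 1e4,
                                         end = 2e4),
                       readsPerCondition = 1e4, seed = 13)
  tr <- buildGatcMap(sim$genome)
  tr <- countReads(tr, sim$fusionReads, "fusion")
  expect_equal(unname(readCounts(tr)[, "fusion"]),
               bruteForceCount(tr, sim$fusionReads))
})

test_that("RPM normalisation is the direct formula and scale-invariant", {
  tr <- mkRatioTrack(rep(0, 12))
  cnt <- matrix(c(10, rpois(11, 5)), ncol = 1,
                dimnames = list(NULL, "fusion"))
  tr@counts <- cnt
  n1 <- rpmValues(normalizeRpm(tr, c(fusion = 1e6)))
  expect_equal(unname(n1[1, "fusion"]), 10)
  expect_equal(unname(n1[, "fusion"]), unname(cnt[, 1] * 1e6 / 1e6))
  n2 <- rpmValues(normalizeRpm(tr, c(fusion = 2e6)))
  tr2 <- tr; tr2@counts <- cnt * 2
  n3 <- rpmValues(normalizeRpm(tr2, c(fusion = 4e6)))
  expect_equal(unname(n2[, "fusion"]), unname(n3[, "fusion"]))
  expect_error(normalizeRpm(tr, c(fusion = 0)), "zero total")
})

test_that("log ratios handle zeros and are antisymmetric", {
  tr <- mkRatioTrack(rep(0, 10))
  tr@rpm <- cbind(fusion = c(4, 40, 0, rpois(7, 20)),
                  control = c(4, 20, 0, rpois(7, 20)))
  lr <- log2Ratios(logRatio(tr))
  expect_equal(lr[1], 0)
  expect_equal(lr[2], 1, tolerance = 0.05)
  expect_equal(lr[3], 0)
  swapped <- logRatio(tr, fusion = "control", control = "fusion")
  expect_equal(log2Ratios(swapped), -lr)
})

test_that("peak calling finds a planted block and ignores flat tracks", {
  flat <- mkRatioTrack(rep(1.3, 50))
  expect_equal(nrow(callPeaks(flat, seed = 1)), 0)

  set.seed(11)
  ratios <- rnorm(500, 0, 0.3)
  ratios[241:260] <- ratios[241:260] + 2   # 20-window planted LAD
  tr <- mkRatioTrack(ratios)
  peaks <- callPeaks(tr, seed = 11)
  expect_equal(nrow(peaks), 1)
  plantedLo <- 240L * 500L; plantedHi <- 260L * 500L
  inter <- max(0, min(peaks$end[1], plantedHi) -
                 max(peaks$start[1], plantedLo))
  union <- (peaks$end[1] - peaks$start[1]) + (plantedHi - plantedLo) - inter
  expect_gte(inter / union, 0.8)
  expect_lt(peaks$fdr[1], 0.05)
})

test_that("region quantification averages overlapping windows", {
  tr <- mkRatioTrack(c(1, 3, 5, 7))
  # windows: [0,500), [500,1000), [1000,1500), [1500,2000) in 0-based bp
  expect_equal(quantifyRegion(tr, "chrS", 0, 500), 1)
  expect_equal(quantifyRegion(tr, "chrS", 400, 600), 2)   # windows 1 and 2
  expect_error(quantifyRegion(tr, "chrS", 5000, 6000), "no window")
  # random intervals match a brute-force overlap scan
  set.seed(14)
  for (k in 1:20) {
    lo <- sample(0:1800, 1); hi <- lo + sample(50:600, 1)
    ov <- which(pmin(hi, seq(500, 2000, 500)) >
                  pmax(lo, seq(0, 1500, 500)))
    if (!length(ov)) next
    expect_equal(quantifyRegion(tr, "chrS", lo, hi),
                 mean(c(1, 3, 5, 7)[ov]))
  }
})

test_that("bedGraph and BED writers emit 0-based half-open intervals", {
  tr <- mkRatioTrack(c(0.5, -0.5))
  path <- tempfile(fileext = ".bedgraph")
  writeBedGraph(tr, path)
  bg <- read.delim(path, header = FALSE)
  expect_equal(bg[[2]], c(0, 500))
  expect_equal(bg[[3]], c(500, 1000))

  bed <- tempfile(fileext = ".bed")
  writeReadsBed(c(0L, 99L), "chrS", bed)
  df <- read.delim(bed, header = FALSE)
  expect_equal(df[[2]], c(0, 99))
  expect_equal(df[[3]], c(1, 100))
})
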