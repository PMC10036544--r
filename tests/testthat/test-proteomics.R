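mkSe <- function(m, group = rep(c("A", "B"), each = 3)) {
  dimnames(m) <- list(sprintf("P%03d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  abundanceExperiment(m, group)
}

test_that("replication filter keeps rows observed >= 2x in some group", {
  m <- rbind(c(20, 21, NA, NA, NA, NA),    # 2-of-3 in A, 0 in B -> kept
             c(20, NA, NA, 21, NA, NA),    # 1 and 1 -> dropped
             c(NA, NA, NA, 20, 21, 22))    # 0 and 3 -> kept
  f <- filterReplication(mkSe(m))
  expect_identical(rownames(f), c("P001", "P003"))
  expect_error(filterReplication(mkSe(m), minPresent = 4), "exceeds")
})

test_that("replication filter agrees with a brute-force row census", {
  set.seed(20)
  m <- matrix(rnorm(1000 * 6, 25), 1000, 6)
  m[runif(length(m)) < 0.45] <- NA
  se <- mkSe(m)
  kept <- rownames(filterReplication(se))
  expected <- rownames(se)[vapply(seq_len(nrow(m)), function(i) {
    sum(!is.na(m[i, 1:3])) >= 2 || sum(!is.na(m[i, 4:6])) >= 2
  }, logical(1))]
  expect_identical(kept, expected)
})

test_that("robust normalisation removes shifts and resists outliers", {
  set.seed(30)
  base <- rnorm(300, 25, 2)
  m <- cbind(base, base, base, base)
  se0 <- mkSe(m, group = rep(c("A", "B"), each = 2))
  expect_equal(SummarizedExperiment::assay(rlrNormalize(se0)),
               SummarizedExperiment::assay(se0), tolerance = 1e-8)

  m2 <- m; m2[, 3] <- base + 0.7
  n2 <- SummarizedExperiment::assay(rlrNormalize(mkSe(m2, rep(c("A", "B"),
                                                              each = 2))))
  expect_lt(max(abs(n2[, 3] - base)), 1e-6)

  # 10% wild outliers: Huber fit stays centred, OLS does not
  m3 <- m
  m3[, 4] <- base + 0.5
  out <- sample(300, 30)
  m3[out, 4] <- m3[out, 4] + 8
  ref <- apply(m3, 1, median)
  n3 <- SummarizedExperiment::assay(rlrNormalize(mkSe(m3, rep(c("A", "B"),
                                                              each = 2))))
  rlrOffset <- abs(median(n3[-out, 4] - base[-out]))
  olsFit <- stats::lm(m3[, 4] ~ ref)
  olsNorm <- m3[, 4] - (stats::fitted(olsFit) - ref)
  olsOffset <- abs(median(olsNorm[-out] - base[-out]))
  expect_lt(rlrOffset, 0.02)
  expect_gt(olsOffset, 5 * rlrOffset)
})

test_that("normalisation preserves the median profile under pure shifts", {
  set.seed(31)
  base <- rnorm(200, 24, 2)
  m <- cbind(base + 0.3, base - 0.2, base, base + 0.5, base - 0.4, base)
  se <- mkSe(m)
  refBefore <- apply(SummarizedExperiment::assay(se), 1, median)
  refAfter <- apply(SummarizedExperiment::assay(rlrNormalize(se)), 1,
                    median)
  expect_lt(max(abs(refBefore - refAfter)), 1e-6)
})

test_that("pass-1 imputation touches only group-wise all-missing rows", {
  m <- rbind(c(NA, NA, NA, 24, 25, 26),   # all-missing in A -> imputed in A
             c(20, NA, 22, NA, 24, NA),   # partial in both -> untouched
             c(18, 19, 20, 21, 22, 23))
  se <- mkSe(m)
  imp <- SummarizedExperiment::assay(imputeMnarMin(se))
  expect_equal(imp[1, 1:3], c(s1 = 18, s2 = 19, s3 = 20))  # column minima
  expect_identical(unname(is.na(imp[2, ])), is.na(m[2, ]))
  expect_identical(unname(imp[3, ]), m[3, ])
})

test_that("pass-1 imputed cell set equals the brute-force predicate", {
  set.seed(40)
  m <- matrix(rnorm(400 * 6, 25), 400, 6)
  m[runif(length(m)) < 0.3] <- NA
  keepObs <- colSums(!is.na(m)) > 0
  se <- mkSe(m)
  imp <- SummarizedExperiment::assay(imputeMnarMin(se))
  changed <- which(is.na(m) & !is.na(imp), arr.ind = TRUE)
  g <- rep(c("A", "B"), each = 3)
  predicate <- which(vapply(seq_len(nrow(m)), function(i) {
    allA <- all(is.na(m[i, 1:3])); allB <- all(is.na(m[i, 4:6]))
    allA || allB
  }, logical(1)))
  expect_setequal(unique(changed[, "row"]), intersect(predicate,
                                                      unique(changed[, "row"])))
  # every changed cell lies in an all-missing group of its row
  for (k in seq_len(nrow(changed))) {
    i <- changed[k, "row"]; j <- changed[k, "col"]
    grpCols <- if (j <= 3) 1:3 else 4:6
    expect_true(all(is.na(m[i, grpCols])))
  }
})

test_that("PMM imputation copies observed donors and beats mean imputation", {
  set.seed(50)
  m <- matrix(rnorm(300 * 6, 25, 2), 300, 6)
  se <- mkSe(m)
  expect_identical(imputePmm(se, seed = 1), se)  # no missing: identity

  # column 2 = column 1 + noise; 20% MAR missing in column 2
  n <- 400
  c1 <- rnorm(n, 25, 2)
  m2 <- cbind(c1, c1 + rnorm(n, 0, 0.1), rnorm(n, 25, 2),
              rnorm(n, 25, 2), rnorm(n, 25, 2), rnorm(n, 25, 2))
  hide <- sample(n, 80)
  truthVals <- m2[hide, 2]
  m2miss <- m2; m2miss[hide, 2] <- NA
  se2 <- mkSe(m2miss)
  imp <- SummarizedExperiment::assay(imputePmm(se2, seed = 7))
  expect_false(any(is.na(imp)))
  # donor-copy property: every imputed value is observed in its column
  expect_true(all(imp[hide, 2] %in% m2miss[-hide, 2]))
  rmsePmm <- sqrt(mean((imp[hide, 2] - truthVals)^2))
  rmseMean <- sqrt(mean((mean(m2miss[, 2], na.rm = TRUE) - truthVals)^2))
  expect_lt(rmsePmm, rmseMean)
})

test_that("differential calling applies both the q and fold gates", {
  set.seed(60)
  m <- matrix(rnorm(50 * 6, 25, 0.2), 50, 6)
  se <- mkSe(m)
  res0 <- differentialAbundance(se)
  expect_equal(sum(res0$significant), 0)

  # a strong but sub-two-fold effect must not be called
  m2 <- m
  m2[1, ] <- c(25, 25.01, 24.99, 25.5, 25.51, 25.49)  # lfc 0.5, q tiny
  res <- differentialAbundance(mkSe(m2))
  expect_lt(res$q[1], 0.05)
  expect_false(res$significant[1])
  expect_equal(res$log2fc[1], 0.5, tolerance = 1e-6)

  m3 <- m
  m3[2, ] <- c(25, 25.01, 24.99, 28, 28.01, 27.99)    # lfc 3
  res3 <- differentialAbundance(mkSe(m3))
  expect_true(res3$significant[2])
  expect_equal(res3$log2fc[2], 3, tolerance = 1e-6)
})

test_that("estimated effects of planted proteins are nearly unbiased", {
  sim <- simulateLfq(nProteins = 2000, effectLog2fc = 2,
                     mnarQuantile = 0.25, seed = 17)
  se <- filterReplication(sim$se)
  se <- rlrNormalize(se)
  se1 <- imputeMnarMin(se)
  se2 <- imputePmm(se1, seed = 17)
  res <- differentialAbundance(se2)
  truth <- sim$truth$trueLog2fc[res$id]
  planted <- res$id %in% sim$truth$differentialIds
  # rows censored below detection in a whole group are min-imputed and
  # report detection-floor-limited (deliberately exaggerated) fold changes;
  # the bias guarantee applies to effects quantified in both groups
  m0 <- SummarizedExperiment::assay(se)
  m1 <- SummarizedExperiment::assay(se1)
  minImputed <- rownames(m0)[rowSums(is.na(m0) & !is.na(m1)) > 0]
  measurable <- planted & !(res$id %in% minImputed)
  bias <- mean(res$log2fc[measurable] - truth[measurable])
  expect_gt(sum(measurable), 100)
  expect_lt(abs(bias), 0.2)
  # min-imputed planted rows mostly keep the effect direction; sign noise
  # remains possible when both groups sit near the detection floor
  dirOk <- sign(res$log2fc) == sign(truth)
  expect_gt(mean(dirOk[planted & res$id %in% minImputed]), 0.75)
})
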