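# Label-free proteome preprocessing. Pipeline order is fixed:
# filter -> (log2 if linear input) -> normalise -> pass-1 minimum imputation
# -> pass-2 predictive mean matching -> differential test. Row order is
# preserved at every stage.

.assayMat <- function(se) {
  m <- SummarizedExperiment::assay(se, 1L)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundance matrix must have row and column names")
  m
}

.groups <- function(se) {
  g <- SummarizedExperiment::colData(se)$group
  if (is.null(g)) stop("colData must carry a 'group' column")
  as.character(g)
}

.replaceAssay <- function(se, m) {
  SummarizedExperiment::assay(se, 1L) <- m
  se
}

#' Construct an abundance experiment from a matrix
#'
#' Convenience constructor wrapping a proteins x samples log2-intensity
#' matrix (NA = missing) and a per-sample group label into a
#' [SummarizedExperiment::SummarizedExperiment].
#'
#' @param values Numeric matrix, rownames = protein ids, colnames = sample
#'   ids; NA marks missing.
#' @param group Character/factor of group labels, one per column.
#' @return A SummarizedExperiment with assay `log2intensity`.
#' @export
abundanceExperiment <- function(values, group) {
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate protein or sample identifiers")
  if (length(group) != ncol(values))
    stop("one group label per sample required")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = values),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(values)))
}

#' Replication filter
#'
#' Keeps proteins quantified in at least `minPresent` replicates of at least
#' one experimental group (default 2, i.e. "two out of three"), preserving
#' row order.
#'
#' @param se Abundance SummarizedExperiment (see [abundanceExperiment()]).
#' @param minPresent Minimum observed values required in some group.
#' @return Filtered SummarizedExperiment.
#' @export
filterReplication <- function(se, minPresent = 2L) {
  m <- .assayMat(se); g <- .groups(se)
  if (any(table(g) < minPresent))
    stop("'minPresent' exceeds the size of a group")
  keep <- rep(FALSE, nrow(m))
  for (gr in unique(g)) {
    keep <- keep | rowSums(!is.na(m[, g == gr, drop = FALSE])) >= minPresent
  }
  se[keep, ]
}

#' Global normalisation by robust linear regression
#'
#' Each sample is regressed (Huber-weighted iteratively reweighted least
#' squares, tuning constant 1.345, up to 50 iterations) against the
#' row-wise median reference profile on their co-observed proteins, and the
#' fitted systematic deviation is subtracted:
#' `normalised = raw - (fitted - reference)`. Missing cells stay missing.
#'
#' @param se Abundance SummarizedExperiment.
#' @param minShared Minimum co-observed proteins required per sample
#'   (default 10).
#' @return Normalised SummarizedExperiment.
#' @export
rlrNormalize <- function(se, minShared = 10L) {
  m <- .assayMat(se)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  ref <- apply(m, 1L, median, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j]) & !is.na(ref)
    if (sum(ok) < minShared)
      stop(sprintf("sample '%s' shares fewer than %d observed proteins %s",
                   colnames(m)[j], minShared, "with the reference"))
    if (sd(ref[ok]) == 0) next  # degenerate reference: nothing to fit
    fit <- suppressWarnings(
      MASS::rlm(m[ok, j] ~ ref[ok], psi = MASS::psi.huber, k = 1.345,
                maxit = 50, acc = 1e-8))
    fitted <- cbind(1, ref[ok]) %*% fit$coefficients
    out[ok, j] <- m[ok, j] - (fitted - ref[ok])
  }
  .replaceAssay(se, out)
}

.groupAllMissingMask <- function(m, g) {
  # TRUE for cells eligible for pass-1 imputation: cells belonging to an
  # experimental group in which their row has no observed value at all;
  # partially missing groups are left for pass 2
  mask <- matrix(FALSE, nrow(m), ncol(m))
  for (gr in unique(g)) {
    cols <- g == gr
    allMissing <- rowSums(!is.na(m[, cols, drop = FALSE])) == 0L
    mask[allMissing, cols] <- TRUE
  }
  mask & is.na(m)
}

#' First-pass minimum-value imputation of MNAR cells
#'
#' Proteins missing in all replicates of an experimental group are taken to
#' be censored below detection (missing not at random); for those rows only,
#' every missing cell is set to the minimum observed value of its own sample
#' column. All other missing cells are left for the second pass.
#'
#' @param se Abundance SummarizedExperiment (normalised).
#' @return SummarizedExperiment with group-wise all-missing rows imputed.
#' @export
imputeMnarMin <- function(se) {
  m <- .assayMat(se); g <- .groups(se)
  if (any(colSums(!is.na(m)) == 0L))
    stop("a sample column has no observed values")
  mask <- .groupAllMissingMask(m, g)
  colMin <- apply(m, 2L, min, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[mask[, j], j] <- colMin[j]
  .replaceAssay(se, m)
}

.pmmDraw <- function(y, X) {
  # stochastic OLS parameter draw (Bayesian linear regression with the
  # noninformative prior): sigma^2* ~ SSE/chi^2_df, beta* ~ N(betahat,
  # sigma^2* (X'X)^-1); returns predictions for all rows of Xall
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # drop collinear columns
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
    attr(X, "keep") <- keep
  }
  betaHat <- qr.coef(qrX, y)
  res <- y - X %*% betaHat
  df <- max(1L, nrow(X) - ncol(X))
  sigma2 <- sum(res^2) / rchisq(1L, df)
  XtXinv <- chol2inv(qr.R(qrX))
  betaStar <- betaHat + drop(chol(XtXinv) %*% rnorm(ncol(X))) * sqrt(sigma2)
  list(beta = betaStar, keep = attr(X, "keep"))
}

#' Second-pass predictive mean matching imputation
#'
#' Chained-equation predictive mean matching (PMM) over sample columns: for
#' each column with missing cells, the column is regressed on all other
#' columns using its observed rows (with a stochastic parameter draw),
#' predictions are computed for every row, and each missing cell copies the
#' observed value of one of the `donors` rows with nearest prediction
#' (chosen uniformly). Sweeps repeat `iters` times; a single completed
#' matrix is returned. Every imputed value is an observed value somewhere in
#' its column.
#'
#' @param se Abundance SummarizedExperiment after [imputeMnarMin()].
#' @param donors Donor pool size (default 5).
#' @param iters Chained-equation sweeps (default 10).
#' @param seed Integer seed.
#' @return Fully imputed SummarizedExperiment.
#' @export
imputePmm <- function(se, donors = 5L, iters = 10L, seed = 1L) {
  m0 <- .assayMat(se)
  miss <- is.na(m0)
  if (!any(miss)) return(se)
  if (any(colSums(!miss) < donors + 1L))
    stop("too few observed values in a column for PMM")
  withSeed(seed, {
    m <- m0
    # initialise missing cells with random observed draws from their column
    for (j in which(colSums(miss) > 0L)) {
      obs <- m0[!miss[, j], j]
      m[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    for (it in seq_len(iters)) {
      for (j in which(colSums(miss) > 0L)) {
        obsRows <- which(!miss[, j]); misRows <- which(miss[, j])
        X <- cbind(1, m[, -j, drop = FALSE])
        draw <- .pmmDraw(m0[obsRows, j], X[obsRows, , drop = FALSE])
        Xu <- if (is.null(draw$keep)) X else X[, draw$keep, drop = FALSE]
        pred <- drop(Xu %*% draw$beta)
        # nearest-prediction donor pool via a sorted scan: O(log n + donors)
        # per missing cell instead of a full distance sort
        ord <- order(pred[obsRows], obsRows)
        po <- pred[obsRows][ord]
        rowsSorted <- obsRows[ord]
        nObs <- length(po)
        for (i in misRows) {
          at <- findInterval(pred[i], po)
          lo <- max(1L, at - donors); hi <- min(nObs, at + donors)
          cand <- lo:hi
          pool <- rowsSorted[cand[order(abs(po[cand] - pred[i]),
                                        cand)[seq_len(donors)]]]
          m[i, j] <- m0[sample(pool, 1L), j]
        }
      }
    }
    .replaceAssay(se, m)
  })
}

#' Differential abundance calling
#'
#' Per-protein variance-gated t-test ([varianceGatedT()]) between the two
#' groups, Benjamini-Hochberg correction across all proteins, and the
#' paper's dual gate: a protein is significant iff `q < qThr` and
#' `|log2fc| >= log2(fold)` (two-fold by default). `log2fc` is
#' mean(group2) - mean(group1).
#'
#' @param se Fully imputed abundance SummarizedExperiment with two groups.
#' @param fold Fold-change gate on the linear scale (default 2).
#' @param qThr q-value gate (default 0.05).
#' @param alphaF Variance-gate F-test level (default 0.05).
#' @return A data.frame with columns `id`, `log2fc`, `t`, `df`, `variant`,
#'   `p`, `q`, `significant`.
#' @export
differentialAbundance <- function(se, fold = 2, qThr = 0.05, alphaF = 0.05) {
  m <- .assayMat(se); g <- .groups(se)
  if (any(is.na(m))) stop("matrix must be fully imputed")
  gl <- sort(unique(g))
  if (length(gl) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("fewer than 2 samples in a group")
  i1 <- g == gl[1]; i2 <- g == gl[2]
  res <- lapply(seq_len(nrow(m)), function(i)
    varianceGatedT(m[i, i1], m[i, i2], alphaF = alphaF))
  lfc <- rowMeans(m[, i2, drop = FALSE]) - rowMeans(m[, i1, drop = FALSE])
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- bhAdjust(p)
  out <- data.frame(
    id = rownames(m),
    log2fc = unname(lfc),
    t = -vapply(res, `[[`, numeric(1), "statistic"),  # sign: group2 - group1
    df = vapply(res, `[[`, numeric(1), "df"),
    variant = vapply(res, `[[`, character(1), "variant"),
    p = p, q = q,
    significant = q < qThr & abs(lfc) >= log2(fold),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
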