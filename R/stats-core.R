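#' Variance-gated two-sample t-test
#'
#' Two-sided t-test whose flavour is chosen by a two-sided F-test on the
#' variance ratio: if the F-test rejects at \code{alphaF}, Welch's t-test
#' (Satterthwaite degrees of freedom) is used, otherwise Student's pooled
#' t-test. This is the differential-abundance test applied per protein.
#'
#' @param x,y Numeric sample vectors (each of length >= 2, finite).
#' @param alphaF Significance level of the variance-gate F-test (default
#'   0.05).
#' @return A list with \code{statistic}, \code{df}, \code{p} (two-sided) and
#'   \code{variant} ("student" or "welch").
#'
#' Degenerate inputs: if both samples have zero variance, p = 1 when the
#' means agree; when they differ, the separation is infinitely many standard
#' errors, reported as p equal to the smallest positive double.
#' @export
#' @examples
#' varianceGatedT(c(1, 2, 3, 4), c(2, 3, 4, 5))
varianceGatedT <- function(x, y, alphaF = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p = 1, variant = "student"))
    return(list(statistic = Inf, df = length(x) + length(y) - 2,
                p = .Machine$double.xmin, variant = "student"))
  }
  # two-sided F gate; guard the one-sided-zero-variance case (F p-value 0)
  pF <- if (vx == 0 || vy == 0) 0 else {
    f <- vx / vy
    2 * min(pf(f, length(x) - 1, length(y) - 1),
            pf(f, length(x) - 1, length(y) - 1, lower.tail = FALSE))
  }
  welch <- pF < alphaF
  tt <- stats::t.test(x, y, var.equal = !welch)
  p <- max(tt$p.value, .Machine$double.xmin)  # keep p in (0, 1]
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = p, variant = if (welch) "welch" else "student")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()] kept as the single adjustment route for the whole
#' pipeline.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value P(X >= x) for an overlap of \code{x}
#' between a query of size \code{n} and an annotated set of size \code{K}
#' within a universe of size \code{N}, with the enrichment ratio
#' (x/n)/(K/N). The tail is computed by [stats::phyper()], which works in
#' log space and is stable for genome-scale universes.
#'
#' @param x Overlap count.
#' @param K Annotated-set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return List with \code{p} and \code{enrichmentRatio}.
#' @export
#' @examples
#' hypergeomORA(3, 4, 5, 10)  # p = 66/252
hypergeomORA <- function(x, K, n, N) {
  if (x > n || n > N || x > K || K > N || min(x, K, n, N) < 0)
    stop("inconsistent counts: need x <= min(K, n) and K, n <= N")
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  ratio <- if (K > 0 && n > 0) (x / n) / (K / N) else NA_real_
  list(p = p, enrichmentRatio = ratio)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of tie-averaged ranks. Returns \code{NA} (with no
#' warning) when either vector is constant, where the coefficient is
#' undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or NA for a constant input.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(rank(x), rank(y), method = "pearson")
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR fold change 2^(-ddCt) with
#' ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator), the reference gene being e.g.
#' GAPDH.
#'
#' @param ctTargetSample,ctRefSample Target/reference-gene Ct in the sample.
#' @param ctTargetCalib,ctRefCalib Target/reference-gene Ct in the
#'   calibrator condition.
#' @return Fold change (positive real).
#' @export
ddctFoldChange <- function(ctTargetSample, ctRefSample,
                           ctTargetCalib, ctRefCalib) {
  cts <- c(ctTargetSample, ctRefSample, ctTargetCalib, ctRefCalib)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ctTargetSample - ctRefSample) - (ctTargetCalib - ctRefCalib)
  2^(-ddct)
}
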