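# Quantitative imaging metrics: per-channel linear intensity normalisation
# and masked Manders co-occurrence with automatic (maximum between-class
# variance) thresholding.

#' Linear intensity normalisation of a channel
#'
#' Maps intensities onto \[0, `top`\] by the linear transform
#' `I_N = (I - I_min) * top / (I_max - I_min)` (default top = 1500, the
#' convention used for STED xz-section channel comparison). The output
#' minimum is exactly 0 and the maximum exactly `top`; the map is
#' idempotent on an already-normalised image.
#'
#' @param img Numeric array (any dimension) of finite intensities.
#' @param top Upper bound of the normalised range (default 1500).
#' @return Array of the same shape.
#' @export
linearNormalize <- function(img, top = 1500) {
  if (!all(is.finite(img))) stop("intensities must be finite")
  rng <- range(img)
  if (rng[2] <= rng[1]) stop("constant image: zero dynamic range")
  out <- (img - rng[1]) * top / (rng[2] - rng[1])
  # pin the endpoints exactly: the map is defined to hit 0 and `top`
  out[img == rng[1]] <- 0
  out[img == rng[2]] <- top
  out
}

#' Automatic intensity threshold (maximum between-class variance)
#'
#' Otsu's criterion over a 256-bin histogram of the observed intensity
#' range: the returned threshold is the bin boundary maximising the
#' between-class variance of the two-class split; voxels strictly above the
#' threshold form the foreground class.
#'
#' @param img Numeric array of finite intensities (non-constant).
#' @param nBins Histogram bins (default 256).
#' @return Threshold intensity (scalar).
#' @export
autoThreshold <- function(img, nBins = 256L) {
  v <- as.vector(img)
  if (!all(is.finite(v))) stop("intensities must be finite")
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("constant image")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), nBins),
                nBins)
  mids <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  wTot <- sum(h); muTot <- sum(h * mids) / wTot
  cumW <- cumsum(h); cumMu <- cumsum(h * mids)
  w0 <- cumW[-nBins] / wTot
  mu0 <- cumMu[-nBins] / pmax(cumW[-nBins], 1)
  valid <- cumW[-nBins] > 0 & cumW[-nBins] < wTot
  sigmaB <- rep(-Inf, nBins - 1L)
  sigmaB[valid] <- (w0[valid] * (1 - w0[valid]) *
                    (mu0[valid] - (cumMu[nBins] - cumMu[-nBins][valid]) /
                       (wTot - cumW[-nBins][valid]))^2)
  breaks[which.max(sigmaB) + 1L]
}

#' Manders co-occurrence coefficients with optional region masking
#'
#' Intensity-weighted co-occurrence of two channels:
#' `M_a = sum(a_i * [b_i > t_b]) / sum(a_i)` and symmetrically `M_b`, with
#' thresholds `t_a`, `t_b` from [autoThreshold()] applied to the masked
#' images. When `regionMask` is given, voxels outside it (or inside it when
#' `invertMask = TRUE`) are zeroed in both channels before thresholding —
#' the "nuclear membrane" region is the mask itself, the "cytoplasm" its
#' complement. Both coefficients lie in \[0, 1\] and are invariant under
#' positive rescaling of either channel; an all-zero channel after masking
#' yields NA.
#'
#' @param a,b Numeric arrays of identical shape (non-negative intensities).
#' @param regionMask Optional logical array of the same shape.
#' @param invertMask Use the mask complement (default FALSE).
#' @return Named numeric vector `c(Ma = ..., Mb = ...)`.
#' @export
mandersCooccurrence <- function(a, b, regionMask = NULL,
                                invertMask = FALSE) {
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  if (!is.null(regionMask)) {
    if (!identical(dim(regionMask), dim(a)))
      stop("mask shape differs from channels")
    keep <- if (invertMask) !regionMask else regionMask
    a <- a * keep
    b <- b * keep
  }
  if (sum(a) == 0 || sum(b) == 0)
    return(c(Ma = NA_real_, Mb = NA_real_))
  ta <- autoThreshold(a)
  tb <- autoThreshold(b)
  c(Ma = sum(a * (b > tb)) / sum(a),
    Mb = sum(b * (a > ta)) / sum(b))
}
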