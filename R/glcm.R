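#' Fixed-bin-width intensity quantization
#'
#' Gray level = floor((v - min) / binSize) + 1 with the minimum taken over
#' the masked pixels (fixed-bin-width convention anchored at the masked
#' minimum; no image normalization). Levels are contiguous from 1. Pixels
#' outside the mask are set to NA.
#'
#' @param image numeric matrix (pSUV units).
#' @param mask logical matrix; must be non-empty.
#' @param binSize bin width in intensity units (default 0.5 pSUV).
#' @return integer matrix of gray levels with attribute \code{nLevels}.
#' @export
quantizeConstantBin <- function(image, mask = NULL, binSize = 0.5) {
  if (binSize <= 0) stop("binSize must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("empty mask")
  lo <- min(image[mask])
  lv <- matrix(NA_integer_, nrow(image), ncol(image))
  lv[mask] <- as.integer(floor((image[mask] - lo) / binSize)) + 1L
  attr(lv, "nLevels") <- max(lv, na.rm = TRUE)
  lv
}

#' Direction-merged gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of gray-level pairs at the given pixel
#' distance over the four 2D directions (0, 45, 90, 135 degrees), counting
#' only pairs with both pixels inside the mask, symmetrized, pooled across
#' directions before a single normalization (the 2.5D direction-merged
#' protocol collapsed to 2D for single-slice images).
#'
#' @param labels integer matrix of gray levels with NA outside the mask
#'   (from \code{\link{quantizeConstantBin}}).
#' @param distance offset in pixels (default 1).
#' @param nLevels matrix size; defaults to the maximum label.
#' @return a \code{GLCM}.
#' @export
glcmMerged <- function(labels, distance = 1L, nLevels = NULL) {
  if (is.null(nLevels)) nLevels <- max(labels, na.rm = TRUE)
  d <- as.integer(distance)
  nr <- nrow(labels); nc <- ncol(labels)
  counts <- matrix(0, nLevels, nLevels)
  offs <- list(c(0L, d), c(d, d), c(d, 0L), c(d, -d))
  for (o in offs) {
    ri <- seq_len(nr - max(0L, o[1])) + 0L
    if (o[1] > 0L) ri <- seq_len(nr - o[1])
    ci <- if (o[2] >= 0L) seq_len(nc - o[2]) else seq(1L - o[2], nc)
    a <- labels[ri, ci, drop = FALSE]
    b <- labels[ri + o[1], ci + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- matrix(table(factor(a[ok], levels = seq_len(nLevels)),
                        factor(b[ok], levels = seq_len(nLevels))),
                  nLevels, nLevels)
    counts <- counts + tab + t(tab)  # symmetric accumulation
  }
  tot <- sum(counts)
  if (tot == 0) stop("no valid in-mask pixel pairs at this distance")
  new("GLCM", matrix = unname(counts / tot), nLevels = as.integer(nLevels),
      distance = distance, merged = TRUE)
}

#' Names of the 22 Haralick GLCM features
#' @return character vector of stable column names.
#' @export
haralickFeatureNames <- function() c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "imc1", "imc2", "inverse_difference_moment",
  "inverse_difference_moment_normalized", "inverse_difference",
  "inverse_difference_normalized", "inverse_variance",
  "maximum_probability", "sum_entropy", "sum_of_squares")

#' The 22 Haralick texture features of a GLCM
#'
#' IBSI-consistent definitions computed from the normalized symmetric GLCM
#' and its marginal, sum and difference distributions. Logarithms are base
#' 2 with the convention 0 log 0 = 0. For a degenerate single-level GLCM,
#' entropy-type features are 0, joint energy and maximum probability are 1,
#' and correlation/IMC1/IMC2 are returned as 0 by convention (flagged via
#' attribute \code{degenerate}).
#'
#' @param glcm a \code{GLCM} (or normalized symmetric matrix).
#' @return named numeric vector of length 22
#'   (\code{\link{haralickFeatureNames}}).
#' @export
haralickFeatures <- function(glcm) {
  p <- if (is(glcm, "GLCM")) glcm@matrix else glcm
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                       # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # sum and difference distributions
  ps <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  ks <- 2:(2 * ng)
  pd <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kd <- 0:(ng - 1)
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  HXY  <- -sum(xlogx(p))
  HX   <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  HXY1 <- -sum(ifelse(p > 0 & pxpy > 0, p * log2(pxpy), 0))
  HXY2 <- -sum(xlogx(pxpy))
  da <- sum(kd * pd)
  degenerate <- sig2 <= .Machine$double.eps
  out <- c(
    autocorrelation   = sum(i * j * p),
    joint_average     = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade     = sum((i + j - 2 * mu)^3 * p),
    cluster_tendency  = sum((i + j - 2 * mu)^2 * p),
    contrast          = sum((i - j)^2 * p),
    correlation       = if (degenerate) 0 else (sum(i * j * p) - mu^2) / sig2,
    difference_average = da,
    difference_entropy = -sum(xlogx(pd)),
    difference_variance = sum((kd - da)^2 * pd),
    joint_energy      = sum(p^2),
    joint_entropy     = HXY,
    imc1              = if (HX <= 0) 0 else (HXY - HXY1) / HX,
    imc2              = if (degenerate) 0 else sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_normalized = sum(p / (1 + ((i - j) / ng)^2)),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_normalized = sum(p / (1 + abs(i - j) / ng)),
    inverse_variance  = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    maximum_probability = max(p),
    sum_entropy       = -sum(xlogx(ps)),
    sum_of_squares    = sig2
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' GLCM feature table over a growth run
#'
#' For every stored snapshot and requested noise level: the agent map is
#' converted to pSUV, a PET image is simulated (one fresh Poisson
#' realization per repeat for noisy levels), the ground-truth lesion mask is
#' built, and the 22 Haralick features are extracted under the fixed
#' protocol (bin size 0.5 pSUV, distance 1, direction-merged, mask
#' restricted, no resampling). Snapshots with an empty lesion mask are
#' skipped with a message.
#'
#' @param run a \code{GrowthRun}.
#' @param noiseLevels NSTD fractions; 0 is noise-free. Named list of
#'   calibrated settings may be supplied instead via \code{acqByNoise}.
#' @param nRepeats noise realizations per snapshot and level.
#' @param acq base acquisition settings (geometry, PSF).
#' @param acqByNoise optional list of pre-calibrated settings keyed by
#'   noise level (as character); levels missing from it are calibrated on
#'   the fly.
#' @param binSize quantization bin width, pSUV.
#' @return data.frame with snapshot time, diameter, noise, repeat index and
#'   the 22 feature columns.
#' @export
featureTimeSeries <- function(run, noiseLevels = c(0, 0.05, 0.10, 0.15),
                              nRepeats = 1L, acq = acquisitionSettings(),
                              acqByNoise = NULL, binSize = 0.5) {
  settings <- lapply(noiseLevels, function(nl) {
    keyed <- acqByNoise[[as.character(nl)]]
    if (!is.null(keyed)) keyed
    else if (nl == 0) { a <- acq; a$noiseFree <- TRUE; a }
    else calibrateNoise(nl, acq = acq)
  })
  rows <- list()
  for (si in seq_along(run@snapshots)) {
    grid <- run@snapshots[[si]]
    mask <- lesionMaskFromTruth(grid, acq)
    if (!any(mask)) {
      message(sprintf("snapshot t = %g h: empty lesion mask, skipped",
                      run@snapshotTimes[si]))
      next
    }
    psuv <- agentToPsuv(grid)
    for (ni in seq_along(noiseLevels)) {
      a <- settings[[ni]]
      reps <- if (noiseLevels[ni] == 0) 1L else nRepeats
      for (r in seq_len(reps)) {
        rec <- simulatePet(psuv, a)
        lv <- quantizeConstantBin(rec@values, mask, binSize)
        fv <- haralickFeatures(glcmMerged(lv))
        rows[[length(rows) + 1L]] <- data.frame(
          time = run@snapshotTimes[si],
          diameter = tumorDiameter(grid),
          noise = noiseLevels[ni], rep = r, t(fv))
      }
    }
  }
  do.call(rbind, rows)
}
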