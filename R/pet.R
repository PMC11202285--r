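#' Convert an agent map to a cell-scale pseudo-SUV image
#'
#' Tracer uptake is assigned per cell class: necrotic 0, normal 1, normoxic
#' tumor 8 (8x normal uptake), hypoxic tumor 12 (1.5x the normoxic uptake).
#' Vessel pixels map to 1 (blood pool at background level; the four-class
#' mapping leaves them unassigned).
#'
#' @param grid an \code{AgentGrid}.
#' @return a \code{PSUVImage} at the agent pixel pitch.
#' @export
agentToPsuv <- function(grid) {
  lut <- c(1, 1, 8, 12, 0)  # VESSEL, NORMAL, NORMOXIC, HYPOXIC, NECROTIC
  st <- grid@states
  if (any(!(st %in% agentStates))) stop("unknown agent code in grid")
  v <- matrix(lut[st], nrow(st), ncol(st))
  new("PSUVImage", values = v, pixelSize = grid@pixelSize / 1e3)
}

#' Acquisition and reconstruction settings
#'
#' The tomographic setup used by \code{\link{simulatePet}}: a parallel-beam
#' projector with \code{nAngles} views over 180 degrees and detector bins
#' equal to the reconstruction pixel size, OSEM with \code{subsets} ordered
#' subsets and \code{iterations} full iterations, a global pSUV-to-counts
#' scale (the acquisition-time surrogate set by \code{\link{calibrateNoise}})
#' and the Gaussian resolution model: \code{preFwhm} applied in image space
#' before projection plus \code{postFwhm} after reconstruction, tuned so the
#' end-to-end point-source resolution is \code{fwhm} = 2.35 mm.
#'
#' @param nPix reconstructed image dimension (68).
#' @param pixelMm reconstruction pixel size, mm (0.58).
#' @param fwhm nominal end-to-end resolution, mm.
#' @param nAngles projection angles over 180 degrees.
#' @param subsets,iterations OSEM settings.
#' @param countScale expected sinogram counts per unit pSUV-projection.
#' @param noiseFree skip Poisson sampling.
#' @param preFwhm,postFwhm Gaussian resolution components, mm.
#' @param padValue pSUV used to pad worlds smaller than the field of view
#'   (1 = normal tissue background).
#' @return a list of class settings used by the PET pipeline.
#' @export
acquisitionSettings <- function(nPix = 68L, pixelMm = 0.58, fwhm = 2.35,
                                nAngles = 180L, subsets = 8L, iterations = 4L,
                                countScale = 1, noiseFree = TRUE,
                                preFwhm = 2.0, postFwhm = 1.22,
                                padValue = 1) {
  list(nPix = as.integer(nPix), pixelMm = pixelMm, fwhm = fwhm,
       nAngles = as.integer(nAngles), subsets = as.integer(subsets),
       iterations = as.integer(iterations), countScale = countScale,
       noiseFree = noiseFree, preFwhm = preFwhm, postFwhm = postFwhm,
       padValue = padValue)
}

# sparse pixel-driven parallel-beam system matrix, cached per geometry;
# rows ordered angle-major (angle 1 bins, angle 2 bins, ...)
petSystemMatrix <- function(acq) {
  key <- sprintf("A_%d_%g_%d", acq$nPix, acq$pixelMm, acq$nAngles)
  cached <- get0(key, envir = .phenopetCache)
  if (!is.null(cached)) return(cached)
  n <- acq$nPix
  nbin <- 2L * ceiling(n * sqrt(2) / 2) + 1L
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr)  # pixel units; bin width = pixel width
  px <- rep(xy, times = n)  # row coordinate
  py <- rep(xy, each = n)   # column coordinate
  th <- (seq_len(acq$nAngles) - 1) * pi / acq$nAngles
  ii <- jj <- vv <- vector("list", acq$nAngles)
  for (k in seq_len(acq$nAngles)) {
    s <- px * cos(th[k]) + py * sin(th[k])
    u <- s + (nbin + 1) / 2
    u0 <- floor(u)
    w1 <- u - u0
    rowBase <- (k - 1L) * nbin
    ii[[k]] <- c(rowBase + u0, rowBase + u0 + 1L)
    jj[[k]] <- c(seq_len(n * n), seq_len(n * n))
    vv[[k]] <- c(1 - w1, w1)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(acq$nAngles * nbin, n * n))
  obj <- list(A = A, nbin = nbin,
              subsetRows = lapply(seq_len(acq$subsets), function(s) {
                ang <- seq(s, acq$nAngles, by = acq$subsets)
                as.vector(outer(seq_len(nbin), (ang - 1L) * nbin, `+`))
              }))
  obj$subsetSens <- lapply(obj$subsetRows, function(r)
    as.numeric(Matrix::crossprod(A[r, , drop = FALSE],
                                 rep(1, length(r)))))
  assign(key, obj, envir = .phenopetCache)
  obj
}

# separable Gaussian blur with replicate edge padding; fwhm in pixels
gaussianBlurPx <- function(m, fwhmPx) {
  if (fwhmPx <= 0) return(m)
  sigma <- fwhmPx / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(x) x[c(rep(1, r), seq_len(nrow(x)), rep(nrow(x), r)), , drop = FALSE]
  conv1 <- function(x) {  # convolve columns
    xp <- pad(x)
    out <- matrix(0, nrow(x), ncol(x))
    for (d in seq_along(k)) out <- out + k[d] * xp[(d - 1) + seq_len(nrow(x)), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

# crop or pad a cell-scale image to the reconstruction field of view and
# block-average down to the reconstruction grid
resampleToRecon <- function(values, cellMm, acq, padValue = acq$padValue) {
  f <- acq$pixelMm / cellMm
  if (abs(f - round(f)) > 1e-9)
    stop("reconstruction pixel size must be an integer multiple of the cell pixel size")
  f <- as.integer(round(f))
  target <- acq$nPix * f
  d <- dim(values)
  out <- matrix(padValue, target, target)
  # center alignment; crop when the world exceeds the FOV, pad when smaller
  copyLen <- pmin(d, target)
  srcOff <- pmax(0L, (d - target) %/% 2L)
  dstOff <- pmax(0L, (target - d) %/% 2L)
  out[dstOff[1] + seq_len(copyLen[1]), dstOff[2] + seq_len(copyLen[2])] <-
    values[srcOff[1] + seq_len(copyLen[1]), srcOff[2] + seq_len(copyLen[2])]
  # block mean over f x f tiles
  m1 <- colMeans(matrix(out, f, length(out) / f))
  m1 <- matrix(m1, target / f, target)  # rows reduced
  m2 <- colMeans(matrix(t(m1), f, length(m1) / f))
  t(matrix(m2, target / f, target / f))
}

#' Simulate PET acquisition and OSEM reconstruction
#'
#' Pipeline: the cell-scale pSUV image is center-cropped/padded to the
#' 68 x 0.58 mm field of view and block-averaged to the reconstruction
#' grid; an image-space Gaussian point-spread function is applied; the image
#' is forward-projected into a parallel-beam sinogram, scaled to expected
#' counts, Poisson-sampled (unless noise-free) and reconstructed with OSEM;
#' the result is rescaled to pSUV units and finished with the small
#' post-reconstruction Gaussian that realizes the end-to-end 2.35 mm FWHM.
#'
#' @param psuv a \code{PSUVImage} (or bare matrix at \code{cellMm} pitch).
#' @param acq settings from \code{\link{acquisitionSettings}}.
#' @param cellMm cell pixel size when \code{psuv} is a bare matrix.
#' @return a \code{ReconImage}.
#' @export
simulatePet <- function(psuv, acq = acquisitionSettings(), cellMm = NULL) {
  if (is(psuv, "PSUVImage")) {
    values <- psuv@values; cellMm <- psuv@pixelSize
  } else values <- psuv
  x <- if (nrow(values) == acq$nPix && ncol(values) == acq$nPix &&
           abs(cellMm - acq$pixelMm) < 1e-9) values
       else resampleToRecon(values, cellMm, acq)
  x <- gaussianBlurPx(x, acq$preFwhm / acq$pixelMm)
  sys <- petSystemMatrix(acq)
  y <- as.numeric(sys$A %*% as.numeric(x)) * acq$countScale
  if (!acq$noiseFree) y <- stats::rpois(length(y), y)
  rec <- osem(y, sys, acq) / acq$countScale
  rec <- gaussianBlurPx(matrix(rec, acq$nPix, acq$nPix),
                        acq$postFwhm / acq$pixelMm)
  rec[rec < 0] <- 0
  new("ReconImage", values = rec, pixelSize = acq$pixelMm, fwhm = acq$fwhm,
      noiseNstd = if (acq$noiseFree) 0 else NA_real_,
      lesionMask = matrix(FALSE, acq$nPix, acq$nPix))
}

# ordered-subset EM; y is the (noisy) sinogram in counts
osem <- function(y, sys, acq) {
  n2 <- acq$nPix^2
  x <- rep(max(mean(y), 1e-12), n2)
  eps <- 1e-12
  for (it in seq_len(acq$iterations)) {
    for (s in seq_len(acq$subsets)) {
      rows <- sys$subsetRows[[s]]
      As <- sys$A[rows, , drop = FALSE]
      q <- as.numeric(As %*% x)
      ratio <- ifelse(q > eps, y[rows] / q, 0)
      upd <- as.numeric(Matrix::crossprod(As, ratio))
      sens <- sys$subsetSens[[s]]
      x <- x * ifelse(sens > eps, upd / sens, 0)
    }
  }
  x
}

#' Normalized standard deviation over a uniform region
#'
#' std/mean of the reconstructed values over a region of interest; the image
#' noise metric. The default ROI is the central 40\% x 40\% of the field of
#' view, avoiding edge artifacts.
#'
#' @param recon a \code{ReconImage} (or matrix).
#' @param roi logical matrix; default central box.
#' @return NSTD as a fraction.
#' @export
measureNstd <- function(recon, roi = NULL) {
  v <- if (is(recon, "ReconImage")) recon@values else recon
  if (is.null(roi)) {
    n <- nrow(v)
    w <- round(0.4 * n)
    i0 <- floor((n - w) / 2)
    roi <- matrix(FALSE, n, ncol(v))
    roi[i0 + seq_len(w), i0 + seq_len(w)] <- TRUE
  }
  if (!any(roi)) stop("empty ROI")
  stats::sd(v[roi]) / mean(v[roi])
}

#' Calibrate the count scale to a target noise level
#'
#' Adjusts the global pSUV-to-counts scale (the acquisition-time surrogate)
#' until the uniform reference phantom (pSUV 2.37, modeling average liver
#' uptake) reconstructs with the target NSTD, averaged over \code{nReal}
#' noise realizations, to within 2\% relative. Uses the Poisson scaling law
#' NSTD ~ 1/sqrt(scale) as the update, with a secant fallback.
#'
#' @param targetNstd target noise as a fraction in (0, 0.5]; 0 returns
#'   noise-free settings.
#' @param phantomPsuv uniform phantom value (2.37).
#' @param acq starting settings.
#' @param nReal phantom realizations per measurement (>= 10).
#' @param maxRounds search cap.
#' @return calibrated settings (class list) with \code{countScale} set,
#'   \code{noiseFree = FALSE} and attribute \code{measuredNstd}.
#' @export
calibrateNoise <- function(targetNstd, phantomPsuv = 2.37,
                           acq = acquisitionSettings(), nReal = 10L,
                           maxRounds = 12L) {
  if (targetNstd == 0) { acq$noiseFree <- TRUE; return(acq) }
  if (targetNstd < 0 || targetNstd > 0.5)
    stop("target NSTD must lie in (0, 0.5]")
  acq$noiseFree <- FALSE
  phantom <- matrix(phantomPsuv, acq$nPix, acq$nPix)
  measure <- function(scale) {
    acq$countScale <- scale
    mean(vapply(seq_len(nReal), function(k)
      measureNstd(simulatePet(phantom, acq, cellMm = acq$pixelMm)),
      numeric(1)))
  }
  scale <- acq$countScale
  converged <- FALSE
  for (round in seq_len(maxRounds)) {
    m <- measure(scale)
    if (abs(m - targetNstd) / targetNstd < 0.02) { converged <- TRUE; break }
    scale <- scale * (m / targetNstd)^2
  }
  if (!converged)
    stop("noise calibration did not converge to the target NSTD")
  acq$countScale <- scale
  attr(acq, "measuredNstd") <- m
  acq
}

#' Lesion mask from the ground-truth agent map
#'
#' The tumor support (all tumor states) is resampled to the reconstruction
#' grid; a reconstruction pixel enters the mask iff its tumor-area fraction
#' is at least 0.5.
#'
#' @param grid an \code{AgentGrid}.
#' @param acq reconstruction geometry settings.
#' @return logical matrix at the reconstruction grid.
#' @export
lesionMaskFromTruth <- function(grid, acq = acquisitionSettings()) {
  tm <- matrix(as.numeric(tumorMask(grid)), nrow(grid@states))
  frac <- resampleToRecon(tm, grid@pixelSize / 1e3, acq, padValue = 0)
  frac >= 0.5
}

#' Measure the point-source FWHM of a reconstructed image
#'
#' Interpolated full width at half maximum of the central row and column
#' profiles through the image maximum, averaged.
#'
#' @param recon a \code{ReconImage} or matrix.
#' @param pixelMm pixel size when a matrix is given.
#' @return FWHM in mm.
#' @export
measureFwhm <- function(recon, pixelMm = NULL) {
  v <- if (is(recon, "ReconImage")) recon@values else recon
  if (is.null(pixelMm)) pixelMm <- if (is(recon, "ReconImage")) recon@pixelSize else stop("pixelMm required")
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  width <- function(p) {
    p <- p - min(p)
    half <- max(p) / 2
    i0 <- which.max(p)
    left <- right <- NA_real_
    for (i in seq(i0, 2)) if (p[i - 1] < half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break }
    for (i in seq(i0, length(p) - 1)) if (p[i + 1] < half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1]); break }
    right - left
  }
  mean(c(width(v[pk[1], ]), width(v[, pk[2]]))) * pixelMm
}
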