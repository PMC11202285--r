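#' Pairwise t-scores for phenotype discrimination
#'
#' For each feature and each requested phenotype pair, the magnitude of the
#' two-sample t statistic between the two groups of feature values (Welch
#' unequal-variance by default; a pooled-variance option is available), with
#' a significance flag at p < 0.01. Zero variance in both groups yields
#' t = 0 for equal means and Inf (flagged) otherwise.
#'
#' @param featuresByPhenotype named list of data.frames/matrices of feature
#'   columns, one element per phenotype (rows = samples).
#' @param pairs list of length-2 character vectors, or NULL for all pairs.
#' @param features feature columns to use; default
#'   \code{\link{haralickFeatureNames}} intersected with the data.
#' @param pooled use the pooled-variance t statistic instead of Welch.
#' @param alpha significance level for the flag (default 0.01).
#' @return data.frame with feature, pair, tScore, pValue, significant;
#'   attribute \code{method} records the variance treatment.
#' @export
pairwiseTscores <- function(featuresByPhenotype, pairs = NULL,
                            features = NULL, pooled = FALSE, alpha = 0.01) {
  phen <- names(featuresByPhenotype)
  if (is.null(pairs))
    pairs <- utils::combn(phen, 2, simplify = FALSE)
  if (is.null(features)) {
    features <- intersect(haralickFeatureNames(),
                          colnames(featuresByPhenotype[[1]]))
    if (!length(features)) features <- colnames(featuresByPhenotype[[1]])
  }
  rows <- list()
  for (pr in pairs) {
    g1 <- as.data.frame(featuresByPhenotype[[pr[1]]])
    g2 <- as.data.frame(featuresByPhenotype[[pr[2]]])
    if (nrow(g1) < 2 || nrow(g2) < 2) stop("need >= 2 samples per group")
    for (f in features) {
      x <- g1[[f]]; y <- g2[[f]]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        tv <- if (isTRUE(all.equal(mean(x), mean(y)))) 0 else Inf
        pv <- if (is.finite(tv)) 1 else 0
      } else {
        tt <- stats::t.test(x, y, var.equal = pooled)
        tv <- abs(unname(tt$statistic)); pv <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, pair = paste(pr, collapse = " vs "),
        tScore = tv, pValue = pv, significant = pv < alpha)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- if (pooled) "pooled" else "welch"
  out
}

#' Cluster separation in feature space
#'
#' The silhouette score (mean over points of (b - a)/max(a, b), via the
#' cluster package) and the Calinski-Harabasz criterion (between-cluster
#' variance over within-cluster variance, scaled by degrees of freedom).
#' Higher values indicate better-formed clusters.
#'
#' @param points numeric matrix (rows = samples) or data.frame.
#' @param labels cluster labels, length nrow(points).
#' @return named numeric: \code{silhouette}, \code{calinskiHarabasz}.
#' @export
clusterSeparation <- function(points, labels) {
  x <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2) stop("need at least 2 clusters")
  if (any(table(labels) < 2)) stop("every cluster needs >= 2 points")
  sil <- cluster::silhouette(labels, stats::dist(x))
  ss <- mean(sil[, "sil_width"])
  n <- nrow(x)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * sum((cg - grand)^2)
    ssw <- ssw + sum(sweep(xg, 2, cg)^2)
  }
  chc <- (ssb / (k - 1)) / (ssw / (n - k))
  c(silhouette = ss, calinskiHarabasz = chc)
}

#' Longitudinal feature curves with dispersion
#'
#' Mean and standard deviation of each feature versus tumor diameter for
#' each phenotype, with a monotonicity flag: a curve is non-monotone when
#' successive mean differences change sign by more than the local noise
#' band (one pooled standard error).
#'
#' @param featureTable data.frame from \code{\link{featureTimeSeries}} rows
#'   bound across runs, with a \code{phenotype} column (added by the caller)
#'   plus \code{diameter} and feature columns; needs >= 2 realizations or
#'   repeats per point for dispersion.
#' @param features feature columns; defaults to the Haralick set present.
#' @param diameterBin width (mm) used to pool diameters into curve points.
#' @return data.frame with phenotype, feature, diameter (bin center), mean,
#'   sd, n; attribute \code{monotone} is a data.frame flagging each
#'   phenotype x feature curve.
#' @export
longitudinalCurves <- function(featureTable, features = NULL,
                               diameterBin = 0.5) {
  ft <- featureTable
  if (is.null(ft$phenotype)) ft$phenotype <- "all"
  if (is.null(features))
    features <- intersect(haralickFeatureNames(), colnames(ft))
  ft$diamBin <- round(ft$diameter / diameterBin) * diameterBin
  rows <- list(); flags <- list()
  for (ph in unique(ft$phenotype)) {
    sub <- ft[ft$phenotype == ph, ]
    for (f in features) {
      agg <- stats::aggregate(sub[[f]], list(diameter = sub$diamBin),
                              function(v) c(mean = mean(v), sd = stats::sd(v),
                                            n = length(v)))
      m <- data.frame(phenotype = ph, feature = f,
                      diameter = agg$diameter,
                      mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                      n = agg$x[, "n"])
      m <- m[order(m$diameter), ]
      rows[[length(rows) + 1L]] <- m
      dmu <- diff(m$mean)
      se <- ifelse(is.na(m$sd), 0, m$sd) / sqrt(pmax(m$n, 1))
      band <- (se[-1] + se[-length(se)])
      signif <- dmu[abs(dmu) > band]
      nonMono <- length(signif) > 1 && any(sign(signif[-1]) != sign(signif[1]))
      flags[[length(flags) + 1L]] <- data.frame(
        phenotype = ph, feature = f, monotone = !nonMono)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "monotone") <- do.call(rbind, flags)
  out
}
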