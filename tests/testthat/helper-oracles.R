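# Independent brute-force oracles used to cross-check the optimized
# implementations. These deliberately use naive scalar loops and follow the
# textbook definitions directly, sharing no code with the package internals.

# exhaustive pair-enumeration GLCM: four 2D directions at the given
# distance, both pixel orders (symmetric), pooled, normalized
bfGlcmMerged <- function(labels, distance = 1L, nLevels = max(labels, na.rm = TRUE)) {
  nr <- nrow(labels); nc <- ncol(labels)
  counts <- matrix(0, nLevels, nLevels)
  offs <- rbind(c(0, distance), c(distance, distance),
                c(distance, 0), c(distance, -distance))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- labels[i, j]
    if (is.na(a)) next
    for (k in 1:4) {
      ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      b <- labels[ii, jj]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# Haralick features from first principles with explicit double loops
bfHaralick <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in seq_len(ng)) mu <- mu + i * px[i]
  sig2 <- 0; for (i in seq_len(ng)) sig2 <- sig2 + (i - mu)^2 * px[i]
  lg <- function(x) if (x > 0) log2(x) else 0
  ps <- numeric(2 * ng); pd <- numeric(ng)  # index k+1 for difference k
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    ps[i + j] <- ps[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  acc <- jointE <- jointH <- contrast <- idm <- idmn <- id <- idn <- 0
  invVar <- maxP <- cp <- cs <- ct <- HXY1 <- HXY2 <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    p <- P[i, j]
    acc <- acc + i * j * p
    jointE <- jointE + p^2
    jointH <- jointH - p * lg(p)
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invVar <- invVar + p / (i - j)^2
    if (p > maxP) maxP <- p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    if (p > 0 && px[i] * px[j] > 0) HXY1 <- HXY1 - p * lg(px[i] * px[j])
    if (px[i] * px[j] > 0) HXY2 <- HXY2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  HX <- 0; for (i in seq_len(ng)) HX <- HX - px[i] * lg(px[i])
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pd[k + 1]
  dent <- 0; for (k in 0:(ng - 1)) dent <- dent - pd[k + 1] * lg(pd[k + 1])
  sent <- 0; for (k in 2:(2 * ng)) sent <- sent - ps[k] * lg(ps[k])
  corr <- if (sig2 > .Machine$double.eps) (acc - mu^2) / sig2 else 0
  imc1 <- if (HX > 0) (jointH - HXY1) / HX else 0
  imc2 <- if (sig2 > .Machine$double.eps) sqrt(max(0, 1 - exp(-2 * (HXY2 - jointH)))) else 0
  c(autocorrelation = acc, joint_average = mu, cluster_prominence = cp,
    cluster_shade = cs, cluster_tendency = ct, contrast = contrast,
    correlation = corr, difference_average = da, difference_entropy = dent,
    difference_variance = dv, joint_energy = jointE, joint_entropy = jointH,
    imc1 = imc1, imc2 = imc2, inverse_difference_moment = idm,
    inverse_difference_moment_normalized = idmn, inverse_difference = id,
    inverse_difference_normalized = idn, inverse_variance = invVar,
    maximum_probability = maxP, sum_entropy = sent, sum_of_squares = sig2)
}

# run a python snippet (scikit-image / scikit-learn cross-checks); input and
# output are exchanged as JSON files
pyRun <- function(code, input) {
  inFile <- tempfile(fileext = ".json"); outFile <- tempfile(fileext = ".json")
  jsonlite::write_json(input, inFile, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(sprintf("IN = %s", deparse(inFile)),
               sprintf("OUT = %s", deparse(outFile)), code), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(outFile))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(outFile, simplifyVector = TRUE)
}
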