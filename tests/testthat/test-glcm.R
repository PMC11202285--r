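test_that("fixed-bin quantization anchors at the masked minimum", {
  img <- matrix(c(0, 0.49, 0.5, 1.2), 2, 2)
  lv <- quantizeConstantBin(img, binSize = 0.5)
  expect_equal(as.integer(lv), c(1L, 1L, 2L, 3L))
  # constant image: a single level
  lvc <- quantizeConstantBin(matrix(5, 4, 4))
  expect_true(all(lvc == 1L))
  expect_equal(attr(lvc, "nLevels"), 1L)
  # the pSUV range 0-12 at bin 0.5 fits in at most 25 levels
  img2 <- matrix(seq(0, 12, length.out = 64), 8, 8)
  expect_lte(attr(quantizeConstantBin(img2, binSize = 0.5), "nLevels"), 25L)
  # masked pixels are excluded and the anchor follows the mask
  msk <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  lvm <- quantizeConstantBin(img, msk, 0.5)
  expect_true(is.na(lvm[1, 1]))
  expect_equal(unname(lvm[2, 1]), 1L)  # anchored at 0.49 now
  expect_error(quantizeConstantBin(img, matrix(FALSE, 2, 2)), "empty mask")
  expect_error(quantizeConstantBin(img, binSize = 0), "positive")
})

test_that("merged GLCM equals exhaustive pair enumeration", {
  set.seed(17)
  for (k in 1:100) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    img <- matrix(runif(nr * nc, 0, 4), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.25, nr, nc)
    if (sum(mask) < 4) next
    lv <- quantizeConstantBin(img, mask, 0.7)
    got <- glcmMerged(lv)
    want <- bfGlcmMerged(lv)
    expect_equal(got@matrix, want, tolerance = 1e-12)
  }
})

test_that("merged GLCM is invariant to transposition and 90-degree rotation", {
  set.seed(23)
  img <- matrix(runif(100, 0, 3), 10, 10)
  lv <- quantizeConstantBin(img, binSize = 0.5)
  g0 <- glcmMerged(lv)@matrix
  gT <- glcmMerged(t(lv))@matrix
  rot90 <- t(lv)[, rev(seq_len(nrow(lv)))]
  gR <- glcmMerged(rot90)@matrix
  expect_equal(gT, g0, tolerance = 1e-12)
  expect_equal(gR, g0, tolerance = 1e-12)
})

test_that("a 2x2 single-level mask gives the degenerate GLCM", {
  lv <- matrix(1L, 2, 2)
  g <- glcmMerged(lv, nLevels = 1L)
  expect_equal(g@matrix, matrix(1, 1, 1))
  expect_error(glcmMerged(matrix(c(1L, rep(NA_integer_, 3)), 2, 2),
                          nLevels = 1L), "pairs")
})

test_that("all 22 features match the brute-force oracle on random images", {
  set.seed(29)
  for (k in 1:100) {
    img <- matrix(runif(32 * 32, 0, 6), 32, 32)
    lv <- quantizeConstantBin(img, binSize = 0.9)
    g <- glcmMerged(lv)
    got <- haralickFeatures(g)
    want <- bfHaralick(g@matrix)
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-6)
  }
})

test_that("merged GLCM agrees with the scikit-image reference implementation", {
  set.seed(37)
  cases <- lapply(1:20, function(k) {
    img <- matrix(runif(144, 0, 3), 12, 12)
    quantizeConstantBin(img, binSize = 0.6)
  })
  input <- lapply(cases, function(lv)
    list(labels = as.vector(t(lv)), nr = nrow(lv), nc = ncol(lv),
         levels = attr(lv, "nLevels")))
  out <- pyRun('
import json, numpy as np
from skimage.feature import graycomatrix
with open(IN) as f: cases = json.load(f)
res = []
for c in cases:
    a = np.array(c["labels"], dtype=np.uint8).reshape(int(c["nr"][0]), int(c["nc"][0])) - 1
    lv = int(c["levels"][0])
    m = graycomatrix(a, [1], [0, np.pi/4, np.pi/2, 3*np.pi/4],
                     levels=lv, symmetric=True, normed=False)
    merged = m[:, :, 0, :].sum(axis=2).astype(float)
    merged /= merged.sum()
    res.append(merged.flatten().tolist())
with open(OUT, "w") as f: json.dump(res, f)
', input)
  for (k in seq_along(cases)) {
    got <- glcmMerged(cases[[k]])@matrix
    v <- if (is.matrix(out)) out[k, ] else unlist(out[[k]])
    expect_equal(got, matrix(as.numeric(v), nrow(got), byrow = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("features of a constant image take their degenerate values", {
  lv <- quantizeConstantBin(matrix(4.2, 6, 6))
  f <- haralickFeatures(glcmMerged(lv, nLevels = 1L))
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["joint_energy"]), 1)
  expect_equal(unname(f["joint_entropy"]), 0)
  expect_equal(unname(f["cluster_shade"]), 0)
  expect_equal(unname(f["correlation"]), 0)  # convention, flagged
  expect_true(attr(f, "degenerate"))
})

test_that("checkerboard contrast equals the hand-enumerated value", {
  lv <- matrix(rep(c(1L, 2L), 18), 6, 6)  # columns alternate 1/2 by row
  # brute-force enumeration fixes the expected GLCM exactly
  P <- bfGlcmMerged(lv, nLevels = 2L)
  fv <- haralickFeatures(glcmMerged(lv))
  expect_equal(unname(fv["contrast"]),
               sum(outer(1:2, 1:2, function(i, j) (i - j)^2) * P))
  expect_equal(unname(fv["maximum_probability"]), max(P))
})

test_that("feature names and vector shape are stable", {
  expect_length(haralickFeatureNames(), 22L)
  lv <- quantizeConstantBin(matrix(runif(64), 8, 8), binSize = 0.2)
  f <- haralickFeatures(glcmMerged(lv))
  expect_named(f, haralickFeatureNames())
  expect_true(f[["joint_energy"]] > 0 && f[["joint_energy"]] <= 1)
  expect_gte(f[["joint_entropy"]], 0)
  expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
})

test_that("feature time series tabulates snapshots x noise x realization", {
  run <- scaledRuns()[["A"]]
  keep <- run@snapshots[c(length(run@snapshots) - 1, length(run@snapshots))]
  runSmall <- run
  runSmall@snapshots <- keep
  runSmall@snapshotTimes <- utils::tail(run@snapshotTimes, 2)
  acq10 <- get0("acq10_cache", envir = .runCache)
  if (is.null(acq10)) {
    set.seed(55); acq10 <- calibrateNoise(0.10, nReal = 10L)
    assign("acq10_cache", acq10, envir = .runCache)
  }
  set.seed(56)
  ft <- featureTimeSeries(runSmall, noiseLevels = c(0, 0.10), nRepeats = 2L,
                          acqByNoise = list(`0.1` = acq10))
  expect_equal(nrow(ft), 2 * (1 + 2))  # per snapshot: 1 noise-free + 2 noisy
  expect_true(all(haralickFeatureNames() %in% colnames(ft)))
  # noise-free rows of the same snapshot are deterministic
  expect_equal(ft$diameter[ft$noise == 0][1], tumorDiameter(keep[[1]]))
})
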