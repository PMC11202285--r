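test_that("pairwise t-scores match the closed-form Welch statistic", {
  # textbook case: means 1 vs 2, sd 1, n = 5 per group
  set.seed(3)
  x <- c(0.5, 1.2, 0.8, 1.4, 1.1)
  y <- c(2.1, 1.8, 2.4, 1.6, 2.1)
  tWelch <- abs(mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  tab <- pairwiseTscores(list(P = data.frame(f = x), Q = data.frame(f = y)),
                         features = "f")
  expect_equal(tab$tScore, tWelch, tolerance = 1e-12)
  expect_equal(attr(tab, "method"), "welch")
  # identical groups: t = 0, not significant
  tab0 <- pairwiseTscores(list(P = data.frame(f = x), Q = data.frame(f = x)),
                          features = "f")
  expect_equal(tab0$tScore, 0)
  expect_false(tab0$significant)
  # near-degenerate separation: huge significant t
  g1 <- data.frame(f = rep(0, 5) + rnorm(5, sd = 1e-6))
  g2 <- data.frame(f = rep(1, 5) + rnorm(5, sd = 1e-6))
  tb <- pairwiseTscores(list(A = g1, B = g2), features = "f")
  expect_gt(tb$tScore, 1e4)
  expect_true(tb$significant)
  # zero variance in both groups with unequal means is flagged infinite
  tinf <- pairwiseTscores(list(A = data.frame(f = rep(0, 3)),
                               B = data.frame(f = rep(1, 3))), features = "f")
  expect_true(is.infinite(tinf$tScore))
})

test_that("t-score magnitude is symmetric under group swap", {
  set.seed(5)
  a <- data.frame(f = rnorm(8), g = rnorm(8))
  b <- data.frame(f = rnorm(8, 1), g = rnorm(8, 2))
  t1 <- pairwiseTscores(list(A = a, B = b), features = c("f", "g"))
  t2 <- pairwiseTscores(list(B = b, A = a), features = c("f", "g"))
  expect_equal(sort(t1$tScore), sort(t2$tScore), tolerance = 1e-12)
})

test_that("cluster separation matches the scikit-learn reference", {
  set.seed(7)
  pts <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
               cbind(rnorm(30, 4), rnorm(30, 4)),
               cbind(rnorm(30, 0), rnorm(30, 8)))
  lab <- rep(1:3, each = 30)
  got <- clusterSeparation(pts, lab)
  out <- pyRun('
import json, numpy as np
from sklearn.metrics import silhouette_score, calinski_harabasz_score
with open(IN) as f: d = json.load(f)
X = np.array(d["x"]); y = np.array(d["y"])
res = {"ss": float(silhouette_score(X, y)),
       "chc": float(calinski_harabasz_score(X, y))}
with open(OUT, "w") as f: json.dump(res, f)
', list(x = pts, y = lab))
  expect_equal(unname(got["silhouette"]), out$ss, tolerance = 1e-8)
  expect_equal(unname(got["calinskiHarabasz"]), out$chc, tolerance = 1e-8)
})

test_that("cluster separation limits behave as expected", {
  # two tight, far-separated clusters: silhouette near 1
  pts <- rbind(matrix(rnorm(40, 0, 0.01), ncol = 2),
               matrix(rnorm(40, 100, 0.01), ncol = 2))
  lab <- rep(1:2, each = 20)
  s <- clusterSeparation(pts, lab)
  expect_gt(s["silhouette"], 0.99)
  # one cluster split arbitrarily into two labels: silhouette near 0
  set.seed(9)
  one <- matrix(rnorm(80), ncol = 2)
  s0 <- clusterSeparation(one, rep(1:2, each = 20))
  expect_lt(abs(s0["silhouette"]), 0.2)
  expect_error(clusterSeparation(one, rep(1, 40)), "2 clusters")
})

test_that("both separation metrics decay as image-like noise grows", {
  set.seed(11)
  base <- rbind(cbind(rnorm(30, 0, 0.2), rnorm(30, 0, 0.2)),
                cbind(rnorm(30, 3, 0.2), rnorm(30, 3, 0.2)),
                cbind(rnorm(30, 3, 0.2), rnorm(30, -3, 0.2)))
  lab <- rep(1:3, each = 30)
  ss <- chc <- numeric(0)
  for (noise in c(0, 0.5, 1.5)) {
    pts <- base + matrix(rnorm(length(base), 0, noise), nrow(base))
    m <- clusterSeparation(pts, lab)
    ss <- c(ss, m["silhouette"]); chc <- c(chc, m["calinskiHarabasz"])
  }
  expect_true(all(diff(ss) < 0))
  expect_true(all(diff(chc) < 0))
})

test_that("longitudinal curves flag monotone and N-shaped trajectories", {
  d <- rep(seq(1, 8, by = 0.5), each = 4)
  mono <- data.frame(phenotype = "P", diameter = d,
                     contrast = d * 2 + rnorm(length(d), 0, 1e-3))
  nshape <- data.frame(phenotype = "P", diameter = d,
                       contrast = sin(d) * 10 + rnorm(length(d), 0, 1e-3))
  cm <- longitudinalCurves(mono, features = "contrast")
  cn <- longitudinalCurves(nshape, features = "contrast")
  expect_true(attr(cm, "monotone")$monotone)
  expect_false(attr(cn, "monotone")$monotone)
  # dispersion of a constant feature is zero
  const <- data.frame(phenotype = "P", diameter = d, contrast = 5)
  cc <- longitudinalCurves(const, features = "contrast")
  expect_true(all(cc$sd == 0))
})
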