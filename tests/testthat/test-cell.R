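test_that("ATP production rate combines glycolytic and aerobic yields", {
  # hand arithmetic: 2*fG + (27/5)*fO
  expect_equal(atpRate(5e-14, 4e-15), 2 * 5e-14 + 5.4 * 4e-15)   # 1.216e-13
  expect_equal(atpRate(5e-14, 4e-15), 1.216e-13)
  expect_equal(atpRate(1.02e-13, 2e-15), 2.148e-13)
  expect_equal(atpRate(0, 0), 0)
  expect_error(atpRate(-1e-15, 0), ">= 0")
})

test_that("death probability follows 1 - R^x with clipping", {
  expect_equal(deathProbability(1, 1, 2), 0)       # at threshold
  expect_equal(deathProbability(2, 1, 2), 0)       # above threshold
  expect_equal(deathProbability(0, 1, 5), 1)       # fully depleted
  expect_equal(deathProbability(0.5, 1, 2), 0.75)  # R = 0.5, x = 2
  expect_equal(deathProbability(0.5, 1, 1), 0.5)
  expect_error(deathProbability(0.5, 0, 1), "positive")
  expect_error(deathProbability(0.5, 1, 0), "positive")
})

test_that("survival draws reproduce the closed-form necrosis probability", {
  bio <- bioParams()
  cfg <- phenotypeConfig(50, 0.05, "random", necrosisExponentAtp = 2)
  th <- bioThresholds(bio)
  # ATP ratio 0.5 with exponent 2: per-step necrosis probability 0.75
  set.seed(11)
  n <- 1e5
  deaths <- sum(!vapply(seq_len(n), function(k)
    survivalStep(th$o2NecrosismmHg * 2, th$atpThreshold * 0.5, cfg, bio),
    logical(1)))
  p <- deaths / n
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p - 0.75), 3 * se)
  # both criteria satisfied: always survives
  ok <- all(vapply(seq_len(1000), function(k)
    survivalStep(th$o2NecrosismmHg * 2, th$atpThreshold * 2, cfg, bio),
    logical(1)))
  expect_true(ok)
  # zero oxygen: necrotic with probability 1
  dead <- any(vapply(seq_len(100), function(k)
    survivalStep(0, th$atpThreshold * 2, cfg, bio), logical(1)))
  expect_false(dead)  # vapply returns survival; zero O2 must never survive
})

test_that("oxygenation state uses the closed 0.08-0.5% O2 band", {
  bio <- bioParams()
  expect_equal(oxygenationState(0.3 * 7.6, bio), "hypoxic")    # 0.3% O2
  expect_equal(oxygenationState(1.0 * 7.6, bio), "normoxic")   # 1% O2
  expect_equal(oxygenationState(0.5 * 7.6, bio), "hypoxic")    # closed upper end
  expect_equal(oxygenationState(0.08 * 7.6, bio), "hypoxic")   # closed lower end
  expect_equal(oxygenationState(0.5 * 7.6 + 1e-9, bio), "normoxic")
})

test_that("division probability scales linearly with oxygen and saturates", {
  bio <- bioParams()
  ref <- 0.5 * 7.6
  expect_equal(divisionProbability(50, bio), 1 / 24)       # normoxic
  expect_equal(divisionProbability(ref, bio), 1 / 24)
  expect_equal(divisionProbability(ref / 2, bio), 1 / 48)  # half the threshold
  expect_equal(divisionProbability(0, bio), 0)
})

test_that("division waiting time is geometric with mean 24 h", {
  bio <- bioParams()
  set.seed(21)
  w <- divisionWaitTimes(10000, bio = bio)
  p <- 1 / 24
  # mean of the geometric waiting time is 1/p = 24 h; SE = sqrt(1-p)/p/sqrt(n)
  se <- sqrt(1 - p) / p / sqrt(length(w))
  expect_lt(abs(mean(w) - 24), 3 * se)
  # chi-square goodness of fit against the geometric law, alpha = 0.01
  brk <- c(1:60, Inf)
  obs <- table(cut(w, c(0, brk)))
  expected <- diff(c(0, stats::pgeom(brk - 1, p))) * length(w)
  keep <- expected > 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(stats::pchisq(chi2, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("daughters take uniform NORMAL neighbors, then vessels by removal prob", {
  bio <- bioParams()
  cfg <- phenotypeConfig(50, 1, "random")  # removal prob 1
  n <- 5L
  base <- matrix(agentStates[["TUMOR_NECROTIC"]], n, n)
  base[3, 3] <- agentStates[["TUMOR_NORMOXIC"]]
  # three NORMAL neighbors: uniform choice over 1e4 trials
  st <- base
  st[2, 2] <- st[2, 3] <- st[2, 4] <- agentStates[["NORMAL"]]
  g <- new("AgentGrid", states = st, pixelSize = 20)
  set.seed(5)
  picks <- t(vapply(seq_len(10000), function(k) {
    g2 <- attemptDivision(g, 3, 3, cfg)
    d <- which(states(g2) != states(g))
    c(length(d), d[1])
  }, numeric(2)))
  expect_true(all(picks[, 1] == 1))
  tab <- table(picks[, 2])
  expect_equal(length(tab), 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)  # uniform over the three
  # all neighbors tumor: no division possible
  gFull <- new("AgentGrid", states = base, pixelSize = 20)
  gFull@states[base == agentStates[["TUMOR_NECROTIC"]]] <- agentStates[["TUMOR_HYPOXIC"]]
  expect_identical(states(attemptDivision(gFull, 3, 3, cfg)),
                   states(gFull))
  # only vessels around, removal prob 1: always replaced
  stV <- base
  stV[base == agentStates[["TUMOR_NECROTIC"]]] <- agentStates[["TUMOR_NECROTIC"]]
  stV[2:4, 2:4] <- agentStates[["VESSEL"]]
  stV[3, 3] <- agentStates[["TUMOR_NORMOXIC"]]
  gV <- new("AgentGrid", states = stV, pixelSize = 20)
  g3 <- attemptDivision(gV, 3, 3, cfg)
  expect_equal(sum(states(g3) == agentStates[["TUMOR_NORMOXIC"]]), 2)
  # removal prob 0: vessel never replaced
  cfg0 <- phenotypeConfig(50, 0, "random")
  expect_identical(states(attemptDivision(gV, 3, 3, cfg0)), states(gV))
})

test_that("hourly update is inert without tumor cells and kills depleted cells", {
  bio <- bioParams()
  cfg <- phenotypePreset("A")
  n <- 30L
  st <- matrix(agentStates[["NORMAL"]], n, n)
  g <- new("AgentGrid", states = st, pixelSize = 20)
  o2 <- nutrientField("oxygen", n, bio)
  glu <- nutrientField("glucose", n, bio)
  set.seed(1)
  expect_identical(states(updateAgents(g, o2, glu, cfg, bio)), st)
  # a viable cell with zero oxygen dies in one step (p = 1)
  g@states[15, 15] <- agentStates[["TUMOR_NORMOXIC"]]
  o2z <- nutrientField("oxygen", n, bio, init = matrix(0, n, n))
  g2 <- updateAgents(g, o2z, glu, cfg, bio)
  expect_equal(unname(states(g2)[15, 15]), unname(agentStates[["TUMOR_NECROTIC"]]))
})

test_that("necrotic count never decreases and trajectories are seed-exact", {
  bio <- bioParams()
  cfg <- phenotypePreset("A", seed = 31)
  run <- runGrowth(cfg, bio, stopDiameter = 0.6, dims = 120)
  nec <- run@log$nNecrotic
  expect_true(all(diff(nec) >= 0))
  run2 <- runGrowth(phenotypePreset("A", seed = 31), bio, stopDiameter = 0.6,
                    dims = 120)
  expect_identical(states(run@finalGrid), states(run2@finalGrid))
  expect_identical(run@log, run2@log)
})
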