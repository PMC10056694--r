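# Synthetic-data generators: scenario presets, zeroing mechanisms, baseline
# matrix and planted-cluster signal.

test_that("scenario presets load and validate against their zero targets", {
  sc <- loadScenarios()
  expect_identical(sc$n, 300L)
  expect_named(sc$bzinb, paste0("bzinb_", letters[1:4]))
  for (nm in names(sc$bzinb)) {
    b <- sc$bzinb[[nm]]
    expect_equal(sum(b$pi), 1)
    expect_equal(
      b$expectedZeros,
      c(300 * (b$pi[3] + b$pi[4]), 300 * (b$pi[2] + b$pi[4]))
    )
  }
  l <- lognormalScenario("sp_sp_a")
  expect_equal(c(l$nzero1, l$nzero2), c(60, 60))
  expect_equal(c(l$mu1, l$mu2), c(11, 11))
  expect_error(lognormalScenario("nope"), "unknown")
})

test_that("exact zeroing is exact and rank zeroing hits its expectation", {
  x <- rpois(300, 50) + 1L
  expect_identical(applyExactZeroing(x, 0, seed = 1), x)
  expect_identical(applyExactZeroing(x, 300, seed = 1), rep(0L, 300))
  z <- applyExactZeroing(x, 60, seed = 2)
  expect_equal(sum(z == 0), 60)
  expect_error(applyExactZeroing(x, 301), "0..length")
  # rank-based: E[#zeros] = sum of clamped probabilities (the formula gives
  # negative p for the largest counts at pzero = 0.1, truncated at zero);
  # the unclamped sum would be n*pzero - span/2 = 29.85
  expect_identical(applyRankZeroing(x, 0, span = 0, seed = 3), x)
  r <- rank(x, ties.method = "average")
  expAnalytic <- sum(pmax((0.5 - r / 300) * 0.3 + 0.1, 0))
  set.seed(4)
  nz <- replicate(300, sum(applyRankZeroing(x, 0.1) == 0))
  se <- sd(nz) / sqrt(length(nz))
  expect_lt(abs(mean(nz) - expAnalytic), 3 * se)
  expect_gt(expAnalytic, 29.85) # clamping only adds zeros
  expect_lt(abs(expAnalytic - 30), 1.5) # near the scenario's printed target
  expect_error(applyRankZeroing(x, 1.2), "pzero")
})

test_that("rank zeroing prefers small counts", {
  x <- 1:300
  set.seed(5)
  zeroedLow <- 0
  zeroedHigh <- 0
  for (i in 1:200) {
    z <- applyRankZeroing(x, 0.1)
    zeroedLow <- zeroedLow + sum(z[1:150] == 0)
    zeroedHigh <- zeroedHigh + sum(z[151:300] == 0)
  }
  expect_gt(zeroedLow, zeroedHigh * 1.5)
})

test_that("lognormal pairs honour the scenario zeros and correlation", {
  pair <- simulateLognormalPair("sp_sp_a", rho = 0.3, seed = 6)
  expect_equal(sum(pair[, 1] == 0), 60)
  expect_equal(sum(pair[, 2] == 0), 60)
  expect_identical(pair, simulateLognormalPair("sp_sp_a", rho = 0.3, seed = 6))
  # before zeroing, pooled log-count correlation tracks rho
  sc <- lognormalScenario("met_sp_a")
  sc$nzero1 <- 0
  sc$nzero2 <- 0
  sc$mechanism1 <- "random_exact"
  sc$mechanism2 <- "random_exact"
  set.seed(7)
  z <- replicate(60, {
    p <- simulateLognormalPair(sc, rho = 0.4)
    cor(log(p[, 1]), log(p[, 2]))
  })
  expect_lt(abs(mean(z) - 0.4), 0.02)
  # null case
  p0 <- simulateLognormalPair(sc, rho = 0, seed = 8)
  expect_lt(abs(cor(log(p0[, 1]), log(p0[, 2]))), 3 / sqrt(300))
})

test_that("BZINB presets hit the target correlation by construction", {
  for (rho in c(0.05, 0.1, 0.3, 0.5)) {
    for (kind in c("met_sp", "sp_sp")) {
      p <- bzinbPreset("bzinb_b", rho, kind = kind)
      expect_equal(rhoBnb(p), rho, tolerance = 1e-6)
    }
  }
  # Table-style masked-zero counts, unbalanced scenario: ~ (60, 225) at n=300
  set.seed(9)
  zeros <- replicate(60, colSums(simulateBzinbPair("bzinb_c",
    n = 300,
    rho = 0.3
  ) == 0))
  p <- bzinbPreset("bzinb_c", 0.3)
  nb0 <- c(
    dnbinom(0, size = 2, prob = 1 / (1 + beta1(p))),
    dnbinom(0, size = 2, prob = 1 / (1 + beta2(p)))
  )
  expMask <- c(60, 225)
  expTotal <- expMask + (300 - expMask) * nb0 # NB zeros on top of masking
  expect_lt(abs(mean(zeros[1, ]) - expTotal[1]), 3 * sd(zeros[1, ]) / sqrt(60))
  expect_lt(abs(mean(zeros[2, ]) - expTotal[2]), 3 * sd(zeros[2, ]) / sqrt(60))
})

test_that("baseline matrix has the advertised structure", {
  se <- generateBaselineMatrix(seed = 10)
  m <- SummarizedExperiment::assay(se)
  expect_identical(dim(m), c(400L, 180L))
  expect_true(all(m >= 0) && all(m == floor(m)))
  expect_lt(abs(mean(m) - 17968) / 17968, 0.1)
  zc <- rowSums(m == 0)
  lnm <- apply(m, 1, function(r) if (any(r > 0)) mean(log(r[r > 0])) else NA)
  expect_lt(cor(zc, lnm, method = "spearman", use = "complete.obs"), 0)
  expect_identical(
    SummarizedExperiment::assay(generateBaselineMatrix(seed = 10)), m
  )
})

test_that("cluster crafting preserves zeros and injects correlation", {
  se <- generateBaselineMatrix(nFeatures = 60, nSamples = 60,
    meanCount = 2000, seed = 11
  )
  m0 <- SummarizedExperiment::assay(se)
  # weight 1: unchanged
  cr1 <- craftClusterSignal(se, k = 3, clusterSize = 20, weight = 1,
    lambda = 2000, seed = 12
  )
  expect_identical(SummarizedExperiment::assay(cr1), m0)
  cr <- craftClusterSignal(se, k = 3, clusterSize = 20, weight = 0.5,
    lambda = 2000, seed = 12
  )
  m1 <- SummarizedExperiment::assay(cr)
  expect_identical(m1 == 0, m0 == 0) # zero pattern untouched
  truth <- SummarizedExperiment::rowData(cr)$trueCluster
  expect_identical(sort(unique(truth)), 1:3)
  withinCor <- function(m, lab) {
    v <- c()
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      cc <- suppressWarnings(cor(t(m[idx, ]), method = "spearman"))
      v <- c(v, cc[upper.tri(cc)])
    }
    mean(v, na.rm = TRUE)
  }
  expect_gt(withinCor(m1, truth), withinCor(m0, truth))
  expect_error(
    craftClusterSignal(se, k = 10, clusterSize = 40),
    "fewer than"
  )
})
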