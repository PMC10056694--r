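# Probability model: joint pmfs, model-based correlations, moments, sampling.

test_that("BNB joint pmf matches the closed-form MGF value at (0,0)", {
  # P(X1=0,X2=0) = (1+b1+b2)^-a0 (1+b1)^-a1 (1+b2)^-a2
  p <- BnbParams(1, 1, 1, 1, 1)
  expect_equal(dbnb(0, 0, p), 1 / 12, tolerance = 1e-10)
  p2 <- BnbParams(0.7, 1.3, 2.1, 0.5, 2)
  closed <- (1 + 0.5 + 2)^(-0.7) * (1.5)^(-1.3) * (3)^(-2.1)
  expect_equal(dbnb(0, 0, p2), closed, tolerance = 1e-10)
})

test_that("BNB pmf normalises and factorises without a shared component", {
  p <- BnbParams(1, 0.5, 0.8, 1, 1.5)
  g <- expand.grid(x1 = 0:80, x2 = 0:80)
  expect_equal(sum(dbnb(g$x1, g$x2, p)), 1, tolerance = 1e-6)
  # alpha0 -> 0: product of the two NB marginals
  p0 <- BnbParams(1e-8, 1, 1.2, 1, 2)
  joint <- dbnb(c(0, 2, 5), c(3, 1, 4), p0)
  marg <- dnbinom(c(0, 2, 5), size = 1 + 1e-8, prob = 1 / 2) *
    dnbinom(c(3, 1, 4), size = 1.2 + 1e-8, prob = 1 / 3)
  expect_equal(joint, marg, tolerance = 1e-6)
})

test_that("BZINB pmf reduces correctly at the masking extremes", {
  b <- BnbParams(1, 1, 1, 1, 1)
  g <- expand.grid(y1 = 0:10, y2 = 0:10)
  noMask <- BzinbParams(b, pi = c(1, 0, 0, 0))
  expect_equal(
    dbzinb(g$y1, g$y2, noMask), dbnb(g$y1, g$y2, b),
    tolerance = 1e-12
  )
  allMask <- BzinbParams(b, pi = c(0, 0, 0, 1))
  expect_equal(dbzinb(0, 0, allMask), 1)
  expect_equal(sum(dbzinb(g$y1, g$y2, allMask)), 1)
})

test_that("BZINB pmf has the stated ZINB marginals and masking rates", {
  b <- BnbParams(0.8, 0.6, 1.1, 1.2, 0.9)
  z <- BzinbParams(b, pi = c(0.55, 0.2, 0.15, 0.1))
  grid <- 0:120
  g <- expand.grid(y1 = grid, y2 = grid)
  pm <- matrix(dbzinb(g$y1, g$y2, z), length(grid))
  expect_equal(sum(pm), 1, tolerance = 1e-6)
  # margin of Y1: ZINB(a0+a1, 1/(b1+1), pi3+pi4)
  m1 <- rowSums(pm)
  w <- 0.15 + 0.1
  zinb1 <- (1 - w) * dnbinom(grid, size = 1.4, prob = 1 / 2.2) +
    w * (grid == 0)
  expect_equal(m1, zinb1, tolerance = 1e-8)
  m2 <- colSums(pm)
  w2 <- 0.2 + 0.1
  zinb2 <- (1 - w2) * dnbinom(grid, size = 1.9, prob = 1 / 1.9) +
    w2 * (grid == 0)
  expect_equal(m2, zinb2, tolerance = 1e-8)
})

test_that("rhoBnb formula gives known values and limits", {
  expect_equal(rhoBnb(BnbParams(1, 1e-12, 1e-12, 1, 1)), 0.5,
    tolerance = 1e-9
  )
  expect_lt(rhoBnb(BnbParams(1e-12, 1, 1, 1, 1)), 1e-9)
  # always in [0, 1)
  set.seed(7)
  for (i in 1:25) {
    p <- BnbParams(
      runif(1, 0.1, 5), runif(1, 0.1, 5), runif(1, 0.1, 5),
      runif(1, 0.2, 4), runif(1, 0.2, 4)
    )
    r <- rhoBnb(p)
    expect_gte(r, 0)
    expect_lt(r, 1)
  }
})

test_that("model correlations match empirical correlations of samples", {
  # oracle closure: formula vs generative samples, 3 MC SEs via block split
  set.seed(11)
  for (i in 1:5) {
    p <- BnbParams(
      runif(1, 0.3, 3), runif(1, 0.2, 2), runif(1, 0.2, 2),
      runif(1, 0.5, 3), runif(1, 0.5, 3)
    )
    x <- rbnb(2e5, p)
    se <- blockSE(x[, 1], x[, 2])
    expect_lt(abs(cor(x[, 1], x[, 2]) - rhoBnb(p)), 3 * se + 1e-4)
    pis <- c(runif(1, 0.4, 0.8), runif(3))
    pis <- c(pis[1], pis[2:4] / sum(pis[2:4]) * (1 - pis[1]))
    z <- BzinbParams(p, pi = pis)
    y <- rbzinb(2e5, z)
    seZ <- blockSE(y[, 1], y[, 2])
    expect_lt(
      abs(cor(y[, 1], y[, 2]) - rhoNaiveBzinb(z)),
      3 * seZ + 1e-4
    )
  }
})

test_that("masking-free BZINB collapses to BNB exactly", {
  b <- BnbParams(1.5, 0.7, 0.9, 2, 1)
  z <- BzinbParams(b, pi = c(1, 0, 0, 0))
  expect_identical(rhoBzinb(z), rhoBnb(b))
  expect_equal(rhoNaiveBzinb(z), rhoBnb(b), tolerance = 1e-12)
  m <- bzinbMoments(z)
  expect_equal(m$naiveSigma12, m$cov, tolerance = 1e-12)
  expect_equal(m$naiveSigma1Sq, m$var1, tolerance = 1e-12)
  expect_equal(m$naiveMean1, m$mean1, tolerance = 1e-12)
})

test_that("closed-form moments are correct", {
  z <- BzinbParams(BnbParams(1, 1, 1, 2, 2), pi = c(0.6, 0.2, 0.1, 0.1))
  m <- bzinbMoments(z)
  expect_equal(m$mean1, 4) # (a0+a1) b1
  expect_equal(m$var1, 12) # (a0+a1) b1 (b1+1)
  expect_equal(m$cov, 4) # a0 b1 b2
  expect_equal(m$naiveMean1, 0.8 * 4) # masking thins the mean
  # covariance vs empirical
  x <- rbnb(2e5, z, seed = 3)
  cv <- cov(x[, 1], x[, 2])
  expect_lt(abs(cv - m$cov), 4 * sd(x[, 1] * x[, 2]) / sqrt(2e5) + 0.05)
})

test_that("naive correlation signs follow the masking structure", {
  b <- BnbParams(1, 1, 1, 1, 1)
  # margins never jointly unmasked: covariance must be <= 0
  z <- BzinbParams(b, pi = c(0, 0.5, 0.4, 0.1))
  m <- bzinbMoments(z)
  expect_lte(m$naiveSigma12, 0)
  expect_lte(rhoNaiveBzinb(z), 0)
})

test_that("samplers honour the masking probabilities and the seed", {
  z <- BzinbParams(BnbParams(2, 1, 1, 1, 1), pi = c(0.1, 0.2, 0.1, 0.6))
  y <- rbzinb(1e5, z, seed = 5)
  # margin-1 masking freq ~ pi3+pi4 (NB zeros add on top, count masked only
  # through the margin zero rate lower bound)
  se <- sqrt(0.7 * 0.3 / 1e5)
  nbZero1 <- dnbinom(0, size = 3, prob = 1 / 2)
  expZeroRate1 <- 0.7 + 0.3 * nbZero1
  expect_lt(abs(mean(y[, 1] == 0) - expZeroRate1), 3 * se + 3 * sqrt(
    expZeroRate1 * (1 - expZeroRate1) / 1e5
  ))
  expect_identical(y, rbzinb(1e5, z, seed = 5))
  expect_false(identical(y, rbzinb(1e5, z, seed = 6)))
})

test_that("parameter containers validate and serialise", {
  expect_error(BnbParams(-1, 1, 1, 1, 1), "positive")
  expect_error(BzinbParams(BnbParams(1, 1, 1, 1, 1), pi = c(0.5, 0.5, 0.5, -0.5)))
  expect_error(BzinbParams(BnbParams(1, 1, 1, 1, 1), pi = c(0.3, 0.3, 0.3, 0.2)))
  z <- BzinbParams(BnbParams(1.5, 0.7, 0.9, 2, 1), pi = c(0.7, 0.1, 0.1, 0.1))
  path <- withr::local_tempfile(fileext = ".json")
  writeParams(z, path)
  z2 <- readParams(path)
  expect_equal(zeroInflation(z2), zeroInflation(z))
  expect_equal(alpha0(z2), 1.5)
  expect_equal(deltaRatio(z2), 0.5)
})
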