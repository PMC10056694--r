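# Affinity construction, spectral clustering, eigengap, matching, ARI,
# Frobenius distances, robust standardisation.

test_that("affinity construction clamps, zeroes the diagonal, symmetrises", {
  m <- matrix(c(1, -0.4, 0.2, -0.4, 1, NA, 0.2, NA, 1), 3,
    dimnames = list(letters[1:3], letters[1:3])
  )
  expect_warning(toAffinity(m), "missing")
  a <- suppressWarnings(toAffinity(m))
  expect_true(all(diag(a) == 0))
  expect_equal(a["a", "b"], 0) # negative clamped
  expect_equal(a["b", "c"], 0) # missing -> zero
  expect_equal(a["a", "c"], 0.2)
  expect_identical(unname(a), unname(t(a)))
  expect_error(toAffinity(matrix(1, 2, 3)), "square")
})

test_that("spectral clustering recovers perfect blocks exactly", {
  a <- blockAffinity(c(12, 8))
  sol <- spectralCluster(a, k = 2, seed = 1)
  expect_equal(adjustedRandIndex(clusterLabels(sol), blockLabels(c(12, 8))), 1)
  a3 <- blockAffinity(c(10, 10, 10))
  sol3 <- spectralCluster(a3, k = 3, seed = 1)
  expect_equal(
    adjustedRandIndex(clusterLabels(sol3), blockLabels(c(10, 10, 10))), 1
  )
  # deterministic under the seed
  expect_identical(
    clusterLabels(spectralCluster(a3, k = 3, seed = 7)),
    clusterLabels(spectralCluster(a3, k = 3, seed = 7))
  )
})

test_that("a flat affinity yields a valid but structureless solution", {
  a <- matrix(0.5, 20, 20)
  diag(a) <- 0
  rownames(a) <- colnames(a) <- paste0("f", 1:20)
  sol <- spectralCluster(a, k = 2, seed = 2)
  expect_identical(sort(unique(sol@labels)), 1:2)
  truth <- rep(1:2, each = 10)
  expect_lt(abs(adjustedRandIndex(clusterLabels(sol), truth)), 0.4)
})

test_that("isolated nodes are assigned and reported", {
  a <- rbind(cbind(blockAffinity(c(6, 6)), 0), 0) # disconnected 13th node
  rownames(a) <- colnames(a) <- paste0("f", 1:13)
  sol <- spectralCluster(a, k = 2, seed = 3)
  expect_identical(sol@isolated, "f13")
  expect_true(sol@labels[13] %in% 1:2)
})

test_that("eigengap selects the number of perfect blocks", {
  expect_equal(eigengapK(blockAffinity(c(8, 8)), kmax = 6), 2)
  expect_equal(eigengapK(blockAffinity(c(7, 7, 7)), kmax = 6), 3)
  # ties break toward smaller k: a constant-gap spectrum
  aff <- toAffinity(diag(0, 4) + 0.5)
  expect_lte(eigengapK(aff, kmax = 3), 3)
})

test_that("cluster matching is label-permutation invariant and optimal", {
  truth <- rep(1:3, each = 4)
  expect_equal(matchClusters(truth, truth)$accuracy, 1)
  swapped <- c(2L, 1L, 3L)[truth]
  m <- matchClusters(swapped, truth)
  expect_equal(m$accuracy, 1)
  expect_true(all(sort(m$mapping) == 1:3))
  # printed toy confusion: one element misplaced -> 11/12, equals brute force
  pred <- truth
  pred[1] <- 2L
  m2 <- matchClusters(pred, truth)
  expect_equal(m2$accuracy, 11 / 12)
  expect_equal(m2$accuracy, bruteMatchAccuracy(pred, truth, 3))
  expect_equal(m2$perCluster, c(3 / 4, 1, 1))
})

test_that("matching equals the brute-force bijection on random instances", {
  set.seed(4)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    n <- sample(20:60, 1)
    truth <- sample.int(k, n, replace = TRUE)
    pred <- truth
    flip <- runif(n) < 0.4
    pred[flip] <- sample.int(k, sum(flip), replace = TRUE)
    # ensure every label occurs
    truth[seq_len(k)] <- seq_len(k)
    pred[k + seq_len(k)] <- seq_len(k)
    expect_equal(
      matchClusters(pred, truth, k = k)$accuracy,
      bruteMatchAccuracy(pred, truth, k)
    )
  }
})

test_that("ARI matches the closed form, a reference implementation, and 0/1", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  # hand computation from the 2x3 contingency table
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(6, 2)
  hand <- (sij - expected) / ((sa + sb) / 2 - expected)
  expect_equal(adjustedRandIndex(a, b), hand)
  expect_equal(adjustedRandIndex(1:10, rep(1:5, 2) * 10), 0) # singletons vs pairs
  expect_equal(adjustedRandIndex(rep(1:4, 5), rep(1:4, 5)), 1)
  set.seed(5)
  r1 <- sample.int(5, 1000, replace = TRUE)
  r2 <- sample.int(5, 1000, replace = TRUE)
  expect_lt(abs(adjustedRandIndex(r1, r2)), 0.05)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(
      adjustedRandIndex(a, b),
      mclust::adjustedRandIndex(a, b)
    )
    expect_equal(
      adjustedRandIndex(r1, r2),
      mclust::adjustedRandIndex(r1, r2)
    )
  }
})

test_that("matching and ARI are equivariant under feature permutation", {
  set.seed(6)
  truth <- sample.int(4, 40, replace = TRUE)
  truth[1:4] <- 1:4
  pred <- truth
  pred[runif(40) < 0.3] <- sample.int(4, sum(runif(40) < 2), replace = TRUE)[1]
  perm <- sample.int(40)
  expect_equal(
    matchClusters(pred, truth, k = 4)$accuracy,
    matchClusters(pred[perm], truth[perm], k = 4)$accuracy
  )
  expect_equal(
    adjustedRandIndex(pred, truth),
    adjustedRandIndex(pred[perm], truth[perm])
  )
})

test_that("Frobenius submatrix distance matches direct computation", {
  set.seed(7)
  A <- matrix(runif(25), 5, dimnames = list(letters[1:5], letters[1:5]))
  A <- (A + t(A)) / 2
  B <- A
  expect_equal(submatrixDistance(A, B), 0)
  B["b", "d"] <- B["d", "b"] <- A["b", "d"] + 0.3
  expect_equal(submatrixDistance(A, B), sqrt(2) * 0.3)
  C <- matrix(runif(25), 5, dimnames = dimnames(A))
  expect_equal(
    submatrixDistance(A, C, c("a", "c", "e")),
    sqrt(sum((A[c(1, 3, 5), c(1, 3, 5)] - C[c(1, 3, 5), c(1, 3, 5)])^2))
  )
  expect_error(submatrixDistance(A, C, "zz"), "unknown")
})

test_that("nested distance curve orders perturbed clusters first", {
  set.seed(8)
  n <- 30
  ids <- paste0("f", 1:n)
  A <- matrix(0.2, n, n, dimnames = list(ids, ids))
  diag(A) <- 1
  B <- A
  labels <- stats::setNames(rep(1:3, each = 10), ids)
  pert <- names(labels)[labels == 2]
  B[pert, pert] <- B[pert, pert] + 0.4
  curve <- nestedDistanceCurve(A, B, labels)
  expect_equal(curve$cluster[1], 2) # perturbed cluster ranked first
  expect_true(all(diff(curve$distance) >= 0)) # monotone under nesting
  same <- nestedDistanceCurve(A, A, labels)
  expect_true(all(same$distance == 0))
})

test_that("robust standardisation centres, clips and flags", {
  set.seed(9)
  m <- rbind(
    normal = rpois(50, 20),
    outlier = c(rpois(49, 20), 5000),
    flat = rep(7, 50)
  )
  s <- standardizeCounts(m)
  expect_equal(unname(apply(s[1:2, ], 1, median)), c(0, 0))
  expect_identical(attr(s, "flagged"), "flat")
  expect_true(all(s["flat", ] == 0))
  # the outlier is clipped to exactly the 3xIQR fence before scaling
  r <- m["outlier", ]
  q <- quantile(r, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 3 * (q[2] - q[1])
  clipped <- pmin(pmax(r, q[1] - 3 * (q[2] - q[1])), fence)
  expect_equal(
    max(s["outlier", ]),
    (fence - median(clipped)) / sd(clipped)
  )
})
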