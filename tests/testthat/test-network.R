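# Thresholded network construction, merging, degrees, export round-trips.

makeBipartiteCorr <- function(nr = 16, nc = 15, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nr * nc, -1, 1), nr,
    dimnames = list(paste0("sp", 1:nr), paste0("met", 1:nc))
  )
  m
}

test_that("top-fraction thresholding keeps exactly ceil(f * pairs) edges", {
  m <- makeBipartiteCorr() # 240 eligible pairs, continuous weights: no ties
  net <- buildNetwork(m, topFraction = 0.30)
  expect_equal(nrow(edges(net)), 72) # ceiling(0.3 * 240)
  expect_equal(nrow(edges(buildNetwork(m, topFraction = 1))), 240)
  # the known top pair survives any fraction
  top <- which(m == max(m), arr.ind = TRUE)
  e <- edges(buildNetwork(m, topFraction = 0.05))
  expect_true(any(e$source == rownames(m)[top[1]] &
    e$target == colnames(m)[top[2]]))
})

test_that("ceil rule holds across sizes and fractions", {
  set.seed(2)
  for (i in 1:12) {
    nr <- sample(2:25, 1)
    nc <- sample(5:10, 1)
    m <- matrix(rnorm(nr * nc), nr,
      dimnames = list(paste0("r", 1:nr), paste0("c", 1:nc))
    )
    for (f in c(0.05, 0.3, 1.0)) {
      expect_equal(
        nrow(edges(buildNetwork(m, topFraction = f))),
        ceiling(f * nr * nc)
      )
    }
  }
})

test_that("ties at the cutoff are all included", {
  m <- matrix(c(0.9, 0.5, 0.5, 0.5, 0.2, 0.1), 2,
    dimnames = list(c("a", "b"), c("x", "y", "z"))
  )
  net <- buildNetwork(m, topFraction = 1 / 3) # ceil(2) but three tied at 0.5
  expect_equal(nrow(edges(net)), 4)
})

test_that("positive-only mode drops negatives before ranking", {
  m <- matrix(c(-0.9, -0.8, 0.3, 0.2, 0.5, -0.1), 2,
    dimnames = list(c("a", "b"), c("x", "y", "z"))
  )
  net <- buildNetwork(m, topFraction = 1, positiveOnly = TRUE)
  expect_true(all(edges(net)$weight >= 0))
  expect_equal(nrow(edges(net)), 3)
  # absolute ranking keeps the strong negative instead
  netAbs <- buildNetwork(m, topFraction = 1 / 6, absolute = TRUE)
  expect_equal(edges(netAbs)$weight, -0.9)
})

test_that("square symmetric matrices use the upper triangle only", {
  set.seed(3)
  m <- matrix(runif(36), 6)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  rownames(m) <- colnames(m) <- paste0("f", 1:6)
  net <- buildNetwork(m, topFraction = 1)
  expect_equal(nrow(edges(net)), choose(6, 2)) # no self/duplicate edges
})

test_that("group merging tags shared edges as both", {
  m <- makeBipartiteCorr(4, 4, seed = 4)
  netA <- buildNetwork(m, topFraction = 0.5, group = "groupA")
  netB <- buildNetwork(m, topFraction = 0.25, group = "groupB")
  merged <- mergeGroupNetworks(netA, netB)
  e <- edges(merged)
  expect_equal(sum(e$group == "both"), nrow(edges(netB))) # B subset of A
  # disjoint sets: no "both"
  m2 <- -m
  netC <- buildNetwork(m2, topFraction = 0.25, group = "groupB")
  merged2 <- mergeGroupNetworks(netA, netC)
  expect_equal(sum(edges(merged2)$group == "both"), 0)
  # identical inputs: all "both"
  merged3 <- mergeGroupNetworks(netA, netA)
  expect_true(all(edges(merged3)$group == "both"))
})

test_that("node degrees satisfy the handshake lemma and star geometry", {
  star <- matrix(c(0.9, 0.8, 0.7, 0.6), 1,
    dimnames = list("hub", paste0("leaf", 1:4))
  )
  net <- buildNetwork(star, topFraction = 1)
  d <- nodeDegrees(net)
  expect_equal(d$degree[d$node == "hub"], 4)
  expect_equal(sum(d$degree), 2 * nrow(edges(net)))
  empty <- buildNetwork(matrix(NA_real_, 2, 2,
    dimnames = list(c("a", "b"), c("c", "d"))
  ))
  expect_equal(nrow(edges(empty)), 0)
  expect_equal(nrow(nodeDegrees(empty)), 0)
})

test_that("export/import round-trips are lossless for every format", {
  m <- makeBipartiteCorr(5, 4, seed = 5)
  net <- buildNetwork(m,
    topFraction = 0.4, group = "groupA",
    rowLayer = "species", colLayer = "metabolite"
  )
  for (fmt in c("edge_tsv", "sif", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportNetwork(net, format = fmt, path = path)
    back <- importNetwork(path, format = fmt)
    e0 <- edges(net)[order(edges(net)$source, edges(net)$target), ]
    e1 <- edges(back)[order(edges(back)$source, edges(back)$target), ]
    expect_equal(e1$source, e0$source, info = fmt)
    expect_equal(e1$target, e0$target, info = fmt)
    expect_equal(e1$weight, e0$weight, tolerance = 1e-9, info = fmt)
    expect_equal(e1$group, e0$group, info = fmt)
    expect_setequal(nodes(back)$id, nodes(net)$id)
  }
  # SIF proper: one line per edge
  sifPath <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(net, format = "sif", path = sifPath)
  expect_length(readLines(sifPath), nrow(edges(net)))
})

test_that("a one-edge network round-trips through graphml", {
  m <- matrix(0.7, 1, 1, dimnames = list("s1", "m1"))
  net <- buildNetwork(m, topFraction = 1)
  path <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, format = "graphml", path = path)
  back <- importNetwork(path, format = "graphml")
  expect_equal(nrow(edges(back)), 1)
  expect_equal(edges(back)$weight, 0.7)
})
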