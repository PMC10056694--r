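# Module identification: correlation -> affinity -> spectral clustering,
# eigengap model selection, cluster matching accuracy, ARI, and Frobenius
# network distances.

#' Convert a square correlation matrix to a spectral-clustering affinity
#'
#' Negative entries are clamped to zero (only positive inter-dependencies
#' drive module structure; model-based correlations are non-negative
#' anyway), the diagonal is set to zero, missing entries (failed fits)
#' become zero with a warning, and any asymmetry left by per-pair fit order
#' is removed by averaging.
#'
#' @param corr a [CorrMatrix-class] or square numeric matrix.
#' @return a non-negative, zero-diagonal, symmetric numeric matrix with the
#'   source method in attribute "method".
#' @export
toAffinity <- function(corr) {
  method <- if (methods::is(corr, "CorrMatrix")) corr@method else "matrix"
  m <- if (methods::is(corr, "CorrMatrix")) corr@values else as.matrix(corr)
  if (nrow(m) != ncol(m)) {
    stop("affinity construction needs a square correlation matrix",
      call. = FALSE
    )
  }
  nMissing <- sum(!is.finite(m))
  if (nMissing > 0) {
    warning(nMissing, " missing entries set to zero affinity", call. = FALSE)
    m[!is.finite(m)] <- 0
  }
  m[m < 0] <- 0
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, method = method)
}

.laplacianEigen <- function(aff) {
  d <- rowSums(aff)
  dinv <- ifelse(d > 1e-12, 1 / sqrt(d), 0)
  M <- aff * (dinv %o% dinv)
  eg <- eigen(M, symmetric = TRUE)
  # eigen() returns descending eigenvalues of M, so 1 - values is the
  # ascending spectrum of L_sym = I - M
  list(
    values = 1 - eg$values, vectors = eg$vectors,
    mvalues = eg$values, isolated = which(d <= 1e-12)
  )
}

#' Spectral clustering of an affinity matrix
#'
#' Symmetric normalised Laplacian embedding: the affinity is degree
#' normalised, the k leading eigenvectors are taken, rows are unit
#' normalised, and k-means with a fixed seed and `nstart` restarts assigns
#' labels. Zero-degree (isolated) features have a degenerate embedding and
#' are re-assigned to the cluster whose mean affinity row is nearest; they
#' are reported in the solution.
#'
#' @param aff affinity matrix from [toAffinity()] (or a [CorrMatrix-class],
#'   converted on the fly).
#' @param k number of clusters (>= 2).
#' @param seed integer seed for k-means (default 1).
#' @param nstart k-means restarts (default 20).
#' @return a [ClusterSolution-class].
#' @export
spectralCluster <- function(aff, k, seed = 1L, nstart = 20L) {
  if (methods::is(aff, "CorrMatrix")) aff <- toAffinity(aff)
  stopifnot(k >= 2, nrow(aff) >= k)
  ids <- rownames(aff)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(aff)))
  le <- .laplacianEigen(aff)
  U <- le$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 1e-12, rn, 1)
  km <- .withSeed(seed, tryCatch(
    kmeans(U, centers = k, nstart = nstart, iter.max = 100L),
    error = function(e) {
      # Hartigan-Wong can abort on duplicate/degenerate embeddings
      kmeans(U,
        centers = k, nstart = nstart, iter.max = 100L,
        algorithm = "Lloyd"
      )
    }
  ))
  labels <- km$cluster
  if (length(le$isolated)) {
    # centroid of each cluster in raw affinity row space
    cent <- vapply(
      seq_len(k),
      function(cl) colMeans(aff[labels == cl, , drop = FALSE]),
      numeric(ncol(aff))
    )
    for (i in le$isolated) {
      d2 <- colSums((cent - aff[i, ])^2)
      labels[i] <- which.min(d2)
    }
  }
  labels <- as.integer(labels)
  names(labels) <- ids
  methods::new("ClusterSolution",
    labels = labels, k = as.integer(k),
    eigenvalues = le$values, seed = as.integer(seed),
    isolated = ids[le$isolated]
  )
}

#' @describeIn spectralCluster named integer cluster labels
#' @param object a [ClusterSolution-class]
#' @export
setMethod("clusterLabels", "ClusterSolution", function(object) {
  stats::setNames(object@labels, names(object@labels))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf(
    "ClusterSolution: %d features in %d clusters (seed %d)\n",
    length(object@labels), object@k, object@seed
  ))
  print(table(cluster = object@labels))
  if (length(object@isolated)) {
    cat("  isolated features:", length(object@isolated), "\n")
  }
})

#' Eigengap heuristic for the number of clusters
#'
#' Returns the k in 1..kmax with the largest gap between consecutive
#' ascending eigenvalues of the symmetric normalised Laplacian; ties break
#' toward smaller k. Advisory only — an explicit k can always be passed to
#' [spectralCluster()].
#'
#' @param aff affinity matrix (or [CorrMatrix-class]).
#' @param kmax largest k considered (must be < number of features).
#' @return the selected integer k.
#' @export
eigengapK <- function(aff, kmax) {
  if (methods::is(aff, "CorrMatrix")) aff <- toAffinity(aff)
  stopifnot(kmax < nrow(aff), kmax >= 1)
  lam <- .laplacianEigen(aff)$values
  gaps <- lam[2:(kmax + 1L)] - lam[1:kmax]
  which.max(gaps) # first maximum = smallest k on ties
}

# maximum-weight bijection between remaining clusters via subset DP
# (optimal linear assignment; equals exhaustive search over bijections)
.bestBijection <- function(C, freeT, freeP) {
  m <- length(freeT)
  if (m == 0) return(integer(0))
  if (m > 20) stop("too many unmatched clusters", call. = FALSE)
  full <- bitwShiftL(1L, m) - 1L
  best <- matrix(-Inf, m + 1L, full + 1L)
  choice <- matrix(NA_integer_, m + 1L, full + 1L)
  best[1L, 1L] <- 0
  for (i in seq_len(m)) {
    for (s in 0:full) {
      b <- best[i, s + 1L]
      if (!is.finite(b)) next
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) != 0L) next
        s2 <- bitwOr(s, bit)
        v <- b + C[freeT[i], freeP[j]]
        if (v > best[i + 1L, s2 + 1L]) {
          best[i + 1L, s2 + 1L] <- v
          choice[i + 1L, s2 + 1L] <- j
        }
      }
    }
  }
  assign <- integer(m)
  s <- full
  for (i in rev(seq_len(m))) {
    j <- choice[i + 1L, s + 1L]
    assign[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  assign
}

#' Match predicted clusters to reference clusters and score accuracy
#'
#' Two-stage matching: first, every mutual-mode pair is fixed (a reference
#' cluster whose most common predicted cluster has that reference cluster as
#' its own most common reference cluster; ties break toward the lower
#' cluster index). The remaining clusters are then matched by the bijection
#' maximising the overall proportion of correctly assigned features,
#' computed by exact optimal assignment (equivalent to exhaustive search
#' over bijections).
#'
#' @param pred integer predicted labels (or a [ClusterSolution-class]).
#' @param truth integer reference labels, same features.
#' @param k number of clusters; defaults to the larger label maximum.
#' @return a list with `mapping` (named integer, predicted -> reference
#'   bijection), `accuracy` (pooled proportion correct), `perCluster`
#'   (reference-side per-cluster accuracies), `perPredicted`
#'   (predicted-side), and the confusion `table`.
#' @export
matchClusters <- function(pred, truth, k = NULL) {
  if (methods::is(pred, "ClusterSolution")) pred <- clusterLabels(pred)
  if (methods::is(truth, "ClusterSolution")) truth <- clusterLabels(truth)
  stopifnot(length(pred) == length(truth))
  if (is.null(k)) k <- max(pred, truth)
  stopifnot(max(pred) <= k, max(truth) <= k)
  n <- length(pred)
  C <- matrix(0, k, k) # reference x predicted feature counts
  for (i in seq_len(n)) {
    C[truth[i], pred[i]] <- C[truth[i], pred[i]] + 1
  }
  modeT <- apply(C, 1L, which.max) # per reference cluster (ties: lower)
  modeP <- apply(C, 2L, which.max) # per predicted cluster
  mapTP <- rep(NA_integer_, k) # reference -> predicted
  for (t in seq_len(k)) {
    p <- modeT[t]
    if (modeP[p] == t && !(p %in% mapTP)) mapTP[t] <- p
  }
  freeT <- which(is.na(mapTP))
  freeP <- setdiff(seq_len(k), mapTP[!is.na(mapTP)])
  if (length(freeT)) {
    assign <- .bestBijection(C, freeT, freeP)
    mapTP[freeT] <- freeP[assign]
  }
  correct <- sum(C[cbind(seq_len(k), mapTP)])
  perCluster <- C[cbind(seq_len(k), mapTP)] / pmax(rowSums(C), 1)
  perPredicted <- C[cbind(seq_len(k), mapTP)] / pmax(colSums(C)[mapTP], 1)
  mapping <- integer(k) # predicted -> reference
  mapping[mapTP] <- seq_len(k)
  names(mapping) <- paste0("pred", seq_len(k))
  list(
    mapping = mapping, accuracy = correct / n, perCluster = perCluster,
    perPredicted = perPredicted, table = C
  )
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement under the permutation model, computed from the
#' contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\frac{1}{2}(\sum_i
#' \binom{a_i}{2} + \sum_j \binom{b_j}{2}) - E}} with
#' \eqn{E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}}.
#'
#' @param a,b label vectors of equal length (any label values).
#' @return the ARI; 1 for identical partitions, about 0 for independent
#'   ones, can be negative.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1) # both partitions trivial
  (sumij - expected) / denom
}

#' Frobenius distance between two correlation matrices on a feature subset
#'
#' The Frobenius norm of the elementwise difference restricted to the
#' subset's rows and columns; missing entries (failed fits) are treated as
#' zero in both matrices.
#'
#' @param corrA,corrB [CorrMatrix-class] objects or numeric matrices covering
#'   the subset.
#' @param features character vector of feature identifiers (default: all
#'   shared features).
#' @return non-negative distance.
#' @export
submatrixDistance <- function(corrA, corrB, features = NULL) {
  A <- if (methods::is(corrA, "CorrMatrix")) corrA@values else as.matrix(corrA)
  B <- if (methods::is(corrB, "CorrMatrix")) corrB@values else as.matrix(corrB)
  if (is.null(features)) features <- intersect(rownames(A), rownames(B))
  if (!all(features %in% rownames(A)) || !all(features %in% rownames(B))) {
    stop("unknown features in subset", call. = FALSE)
  }
  dA <- A[features, features, drop = FALSE]
  dB <- B[features, features, drop = FALSE]
  dA[!is.finite(dA)] <- 0
  dB[!is.finite(dB)] <- 0
  sqrt(sum((dA - dB)^2))
}

#' Nested-cluster distance curve between two correlation matrices
#'
#' Per-cluster Frobenius distances are computed, clusters are ordered by
#' decreasing distance, and the distance is re-evaluated on the cumulative
#' nested feature sets (largest-distance cluster first, then its union with
#' the next, and so on). The curve is non-decreasing in set size.
#'
#' @param corrA,corrB correlation matrices on the same features.
#' @param clusters a [ClusterSolution-class] (or named integer labels) on
#'   those features.
#' @return data.frame with columns `nClusters`, `cluster` (added at this
#'   step), `setSize`, `distance`.
#' @export
nestedDistanceCurve <- function(corrA, corrB, clusters) {
  labels <- if (methods::is(clusters, "ClusterSolution")) {
    clusterLabels(clusters)
  } else {
    clusters
  }
  ks <- sort(unique(labels))
  per <- vapply(ks, function(cl) {
    submatrixDistance(corrA, corrB, names(labels)[labels == cl])
  }, 0)
  ord <- ks[order(per, decreasing = TRUE)]
  acc <- character(0)
  out <- data.frame(
    nClusters = integer(0), cluster = integer(0),
    setSize = integer(0), distance = numeric(0)
  )
  for (i in seq_along(ord)) {
    acc <- c(acc, names(labels)[labels == ord[i]])
    out <- rbind(out, data.frame(
      nClusters = i, cluster = ord[i], setSize = length(acc),
      distance = submatrixDistance(corrA, corrB, acc)
    ))
  }
  out
}

#' Robust per-feature standardisation of a count matrix
#'
#' For each feature (row): outliers beyond 3 x IQR from the first or third
#' quartile are clipped to that fence, the median is subtracted, and the
#' result is divided by the standard deviation. Zero-variance features
#' yield an all-zero row and are flagged in attribute "flagged". Intended
#' for heatmap export of clustering results.
#'
#' @param x count matrix or SummarizedExperiment (features x samples).
#' @return numeric matrix of standardized values.
#' @export
standardizeCounts <- function(x) {
  m <- .countMatrix(x)
  flagged <- character(0)
  out <- t(apply(m, 1L, function(r) {
    q <- quantile(r, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    r <- pmin(pmax(r, q[1] - 3 * iqr), q[2] + 3 * iqr)
    s <- sd(r)
    if (!is.finite(s) || s == 0) {
      return(rep(NA, length(r)))
    }
    (r - median(r)) / s
  }))
  zeroVar <- apply(is.na(out), 1L, all) & !apply(is.na(m), 1L, any)
  if (any(zeroVar)) {
    flagged <- rownames(m)[zeroVar]
    out[zeroVar, ] <- 0
  }
  dimnames(out) <- dimnames(m)
  structure(out, flagged = flagged)
}
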