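# shared test fixtures, built in code

# block-diagonal affinity with `sizes` perfect blocks of given value
blockAffinity <- function(sizes, value = 0.8) {
  n <- sum(sizes)
  m <- matrix(0, n, n)
  start <- 1L
  for (s in sizes) {
    idx <- start:(start + s - 1L)
    m[idx, idx] <- value
    start <- start + s
  }
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("f", seq_len(n))
  m
}

blockLabels <- function(sizes) rep(seq_along(sizes), sizes)

# independent brute-force Spearman: explicit midranks, textbook Pearson
bruteSpearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x)
  ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force cluster matching: enumerate every bijection of the clusters
# left free after fixing mutual-mode matches, maximise pooled accuracy
bruteMatchAccuracy <- function(pred, truth, k) {
  C <- matrix(0, k, k)
  for (i in seq_along(pred)) C[truth[i], pred[i]] <- C[truth[i], pred[i]] + 1
  modeT <- apply(C, 1, which.max)
  modeP <- apply(C, 2, which.max)
  mapTP <- rep(NA_integer_, k)
  for (t in seq_len(k)) {
    p <- modeT[t]
    if (modeP[p] == t && !(p %in% mapTP)) mapTP[t] <- p
  }
  freeT <- which(is.na(mapTP))
  freeP <- setdiff(seq_len(k), mapTP[!is.na(mapTP)])
  allPerms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  perms <- if (length(freeP)) allPerms(freeP) else list(integer(0))
  for (perm in perms) {
    m <- mapTP
    m[freeT] <- perm
    best <- max(best, sum(C[cbind(seq_len(k), m)]))
  }
  best / length(pred)
}

# Monte-Carlo standard error of a correlation estimate via block splitting
blockSE <- function(x1, x2, nBlocks = 100) {
  n <- length(x1)
  idx <- rep(seq_len(nBlocks), length.out = n)
  cors <- vapply(
    seq_len(nBlocks),
    function(b) cor(x1[idx == b], x2[idx == b]),
    0
  )
  sd(cors) / sqrt(nBlocks)
}
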