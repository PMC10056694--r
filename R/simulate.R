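# Synthetic-data generators: zero-inflated bivariate lognormal pairs, BZINB
# pairs from named scenario presets, an overdispersed zero-inflated baseline
# count matrix, and the planted-cluster (semi-parametric) signal injector.

.scenarioCache <- new.env(parent = emptyenv())

#' Load and validate the shipped simulation scenario presets
#'
#' Scenario presets live in a JSON configuration shipped with the package:
#' zero-inflated lognormal designs (`met_sp_a..d`, `sp_sp_a..c`: per-margin
#' log-scale means, target zero counts and zeroing mechanisms) and BZINB
#' masking designs (`bzinb_a..d`: the four-category masking probabilities).
#' On load, each BZINB preset's expected masked-zero counts are checked
#' against `n * (pi3 + pi4)` and `n * (pi2 + pi4)`, and each lognormal
#' preset's zero targets against the vector length.
#'
#' @return a list with elements `n`, `lognormal`, `bzinb`.
#' @export
loadScenarios <- function() {
  if (!is.null(.scenarioCache$sc)) return(.scenarioCache$sc)
  path <- system.file("extdata", "scenarios.json", package = "bzinbcor")
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- sc$n
  for (nm in names(sc$bzinb)) {
    b <- sc$bzinb[[nm]]
    if (abs(sum(b$pi) - 1) > 1e-9) {
      stop("preset ", nm, ": pi must sum to 1", call. = FALSE)
    }
    expect <- c(n * (b$pi[3] + b$pi[4]), n * (b$pi[2] + b$pi[4]))
    if (any(abs(expect - b$expectedZeros) > 1e-6)) {
      stop("preset ", nm, ": expected zeros inconsistent with pi",
        call. = FALSE
      )
    }
  }
  for (nm in names(sc$lognormal)) {
    l <- sc$lognormal[[nm]]
    if (any(l$nzero >= n)) {
      stop("preset ", nm, ": zero targets must be < n", call. = FALSE)
    }
  }
  .scenarioCache$sc <- sc
  sc
}

#' Retrieve a lognormal scenario preset
#'
#' @param name preset name (`met_sp_a..d`, `sp_sp_a..c`).
#' @return a list with fields `mu1, mu2, sigma, n, nzero1, nzero2,
#'   mechanism1, mechanism2`.
#' @export
lognormalScenario <- function(name) {
  sc <- loadScenarios()
  l <- sc$lognormal[[name]]
  if (is.null(l)) {
    stop("unknown lognormal scenario: ", name, call. = FALSE)
  }
  list(
    name = name, mu1 = l$means[1], mu2 = l$means[2], sigma = 1,
    n = sc$n, nzero1 = l$nzero[1], nzero2 = l$nzero[2],
    mechanism1 = l$mechanisms[1], mechanism2 = l$mechanisms[2]
  )
}

#' Simulate a zero-inflated bivariate lognormal pair
#'
#' Draws `n` bivariate normal log-counts with the scenario's log-scale means,
#' unit log-variance and correlation `rho`, exponentiates, rounds to the
#' nearest integer, then applies the scenario's zeroing mechanism to each
#' margin: `rank_based` zeroes low counts preferentially (metabolite
#' dropout, probability decreasing in rank) with baseline proportion
#' `nzero / n`; `random_exact` sets exactly `nzero` uniformly chosen
#' positions to zero (structural species zeros).
#'
#' @param scenario a preset name or the list from [lognormalScenario()].
#' @param rho target log-scale correlation in [-1, 1].
#' @param n overrides the scenario vector length (default from the preset).
#' @param span rank-probability span for the rank-based mechanism.
#' @param seed optional integer seed.
#' @return integer matrix with columns `x1`, `x2` and the scenario attached
#'   as attribute "scenario".
#' @export
simulateLognormalPair <- function(scenario, rho, n = NULL, span = 0.3,
                                  seed = NULL) {
  if (is.character(scenario)) scenario <- lognormalScenario(scenario)
  stopifnot(rho >= -1, rho <= 1)
  if (is.null(n)) n <- scenario$n
  .withSeed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x1 <- round(exp(scenario$mu1 + scenario$sigma * z1))
    x2 <- round(exp(scenario$mu2 + scenario$sigma * z2))
    x1 <- .applyZeroing(x1, scenario$mechanism1, scenario$nzero1, span)
    x2 <- .applyZeroing(x2, scenario$mechanism2, scenario$nzero2, span)
    structure(cbind(x1 = x1, x2 = x2), scenario = scenario)
  })
}

.applyZeroing <- function(x, mechanism, nzero, span) {
  switch(mechanism,
    rank_based = applyRankZeroing(x, pzero = nzero / length(x), span = span),
    random_exact = applyExactZeroing(x, nzero = nzero),
    stop("unknown zeroing mechanism: ", mechanism, call. = FALSE)
  )
}

#' Rank-based probabilistic zeroing
#'
#' Mimics metabolite dropout due to low concentration: counts are ranked
#' ascending (midranks on ties; rank 1 = smallest) and element i is zeroed
#' independently with probability
#' `p_i = (0.5 - rank_i / n) * span + pzero`, clamped to [0, 1], so the
#' smallest counts are the likeliest to vanish. The expected number of zeros
#' is the sum of the clamped probabilities; without clamping this is
#' `n * pzero - span / 2`, and when `pzero < span / 2` the zero clamp on the
#' largest counts raises it slightly.
#'
#' @param counts non-negative integer vector.
#' @param pzero baseline zero proportion in [0, 1).
#' @param span width of the rank-probability interval (default 0.3).
#' @param seed optional integer seed.
#' @return the vector with zeroed entries.
#' @export
applyRankZeroing <- function(counts, pzero, span = 0.3, seed = NULL) {
  .assertCounts(counts)
  if (pzero < 0 || pzero >= 1) {
    stop("pzero must lie in [0, 1)", call. = FALSE)
  }
  n <- length(counts)
  r <- rank(counts, ties.method = "average")
  p <- pmin(pmax((0.5 - r / n) * span + pzero, 0), 1)
  .withSeed(seed, {
    counts[runif(n) < p] <- 0L
    counts
  })
}

#' Exact-count random zeroing
#'
#' Structural species zeros: exactly `nzero` positions chosen uniformly at
#' random (among all indices, including already-zero ones) are set to zero.
#'
#' @param counts non-negative integer vector.
#' @param nzero number of positions to zero (0..n).
#' @param seed optional integer seed.
#' @return the vector with zeroed entries.
#' @export
applyExactZeroing <- function(counts, nzero, seed = NULL) {
  .assertCounts(counts)
  n <- length(counts)
  if (nzero > n || nzero < 0) {
    stop("nzero must lie in 0..length(counts)", call. = FALSE)
  }
  .withSeed(seed, {
    if (nzero > 0) counts[sample.int(n, nzero)] <- 0L
    counts
  })
}

#' BZINB scenario preset parameters
#'
#' Combines a named Table-style masking design (`bzinb_a..d`) with shape and
#' scale parameters constructed to hit the target latent correlation exactly:
#' the scales are fixed per relationship kind (`met_sp`: beta = (4, 2);
#' `sp_sp`: beta = (3, 3)), the total shape per margin is 2, and the shared
#' shape is solved from the closed-form correlation, so
#' `rhoBnb(preset) == rho` by construction.
#'
#' @param scenario preset name (`bzinb_a..d`).
#' @param rho target latent (BNB) correlation in (0, 0.7].
#' @param kind "met_sp" (metabolite-species) or "sp_sp" (species-species).
#' @return a [BzinbParams-class] object.
#' @export
bzinbPreset <- function(scenario, rho, kind = c("met_sp", "sp_sp")) {
  kind <- match.arg(kind)
  sc <- loadScenarios()
  b <- sc$bzinb[[scenario]]
  if (is.null(b)) stop("unknown BZINB scenario: ", scenario, call. = FALSE)
  betas <- if (kind == "met_sp") c(4, 2) else c(3, 3)
  K <- 2 # total shape alpha0 + alphai per margin
  fac <- sqrt(betas[1] * betas[2] / ((betas[1] + 1) * (betas[2] + 1)))
  a0 <- rho * K / fac
  if (a0 <= 0 || a0 >= K) {
    stop("target rho out of the constructible range for this kind",
      call. = FALSE
    )
  }
  params <- BzinbParams(
    BnbParams(a0, K - a0, K - a0, betas[1], betas[2]),
    pi = b$pi
  )
  stopifnot(abs(rhoBnb(params) - rho) < 1e-6)
  params
}

#' Simulate a BZINB pair from a scenario preset or explicit parameters
#'
#' @param params a [BzinbParams-class] object, or a preset name
#'   (`bzinb_a..d`) combined with `rho` and `kind` via [bzinbPreset()].
#' @param n pair length (default 300).
#' @param seed optional integer seed.
#' @param rho,kind used when `params` is a preset name.
#' @return integer matrix with columns `x1`, `x2`.
#' @export
simulateBzinbPair <- function(params, n = 300L, seed = NULL, rho = NULL,
                              kind = "met_sp") {
  if (is.character(params)) {
    stopifnot(!is.null(rho))
    params <- bzinbPreset(params, rho, kind = kind)
  }
  rbzinb(n, params, seed = seed)
}

#' Generate an overdispersed zero-inflated baseline count matrix
#'
#' A stand-in for a healthy-group species-by-sample metagenomic count matrix:
#' per-feature negative binomial draws with structural zeros, where feature
#' abundances follow a long-tailed (log-normal-like) rank-abundance
#' distribution spanning several orders of magnitude and the zero
#' probability increases as the log-mean decreases (the decreasing
#' mean-versus-zeros trend seen in sparse count data). Feature means are
#' scaled so the overall matrix mean matches `meanCount`.
#'
#' @param nFeatures,nSamples matrix dimensions (defaults 400 x 180).
#' @param meanCount target overall mean count (default 17968).
#' @param dispersion negative binomial size parameter (default 0.5, i.e.
#'   strongly overdispersed, as species-level metagenomic counts are).
#' @param dominantFraction fraction of high-abundance "dominant" features
#'   (default 0.04); the long right tail of the rank-abundance curve that
#'   carries most of the reads, while the bulk of features sit orders of
#'   magnitude lower.
#' @param seed optional integer seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay and per-feature `mu`, `zeroProb` in the row data.
#' @export
generateBaselineMatrix <- function(nFeatures = 400L, nSamples = 180L,
                                   meanCount = 17968, dispersion = 0.5,
                                   dominantFraction = 0.04,
                                   seed = NULL) {
  stopifnot(nFeatures >= 2, nSamples >= 2)
  .withSeed(seed, {
    dom <- runif(nFeatures) < dominantFraction
    bulkMean <- log(meanCount / 100)
    logMu <- ifelse(dom,
      rnorm(nFeatures, log(meanCount * 22), 1.0),
      rnorm(nFeatures, bulkMean, 0.55)
    )
    zeroProb <- pmin(pmax(
      0.45 - 0.12 * (logMu - bulkMean) + runif(nFeatures, 0, 0.1),
      0.02
    ), 0.9)
    mu <- exp(logMu)
    mu <- mu * meanCount / mean((1 - zeroProb) * mu)
    counts <- matrix(0, nFeatures, nSamples)
    for (f in seq_len(nFeatures)) {
      present <- runif(nSamples) >= zeroProb[f]
      counts[f, present] <- rnbinom(sum(present),
        size = dispersion,
        mu = mu[f]
      )
    }
    dimnames(counts) <- list(
      sprintf("sp%03d", seq_len(nFeatures)),
      sprintf("s%03d", seq_len(nSamples))
    )
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(mu = mu, zeroProb = zeroProb)
    )
  })
}

#' Plant correlated clusters into a count matrix
#'
#' Semi-parametric cluster-signal injection: features are permuted and the
#' first `k * clusterSize` are partitioned into `k` equal clusters; for each
#' cluster one shared vector `R_k` with independent Poisson(`lambda`) entries
#' per sample is drawn, and each member feature's nonzero counts are replaced
#' by `round(weight * Y + (1 - weight) * R_k)`. Zeros are preserved exactly,
#' so zero-inflation structure is untouched; the shared vector raises
#' within-cluster correlation.
#'
#' @param x a count matrix or SummarizedExperiment.
#' @param k number of clusters (default 10).
#' @param clusterSize features per cluster (default 40).
#' @param weight weight on the original counts, in (0, 1] (default 0.9).
#' @param lambda Poisson mean of the shared vector (default 17968).
#' @param seed optional integer seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with the modified
#'   `counts` assay and the ground-truth labels in `rowData(x)$trueCluster`
#'   (NA for features outside the planted clusters).
#' @export
craftClusterSignal <- function(x, k = 10L, clusterSize = 40L, weight = 0.9,
                               lambda = 17968, seed = NULL) {
  m <- .countMatrix(x)
  if (k * clusterSize > nrow(m)) {
    stop("matrix has fewer than k * clusterSize features", call. = FALSE)
  }
  stopifnot(weight > 0, weight <= 1)
  .withSeed(seed, {
    ord <- sample.int(nrow(m))
    truth <- rep(NA_integer_, nrow(m))
    names(truth) <- rownames(m)
    for (cl in seq_len(k)) {
      members <- ord[((cl - 1L) * clusterSize + 1L):(cl * clusterSize)]
      truth[members] <- cl
      rk <- rpois(ncol(m), lambda)
      for (f in members) {
        nz <- m[f, ] > 0
        m[f, nz] <- round(weight * m[f, nz] + (1 - weight) * rk[nz])
      }
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = m),
      rowData = S4Vectors::DataFrame(trueCluster = truth)
    )
  })
}
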