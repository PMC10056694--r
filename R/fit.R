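# Fitting of BNB / BZINB models to a pair of count vectors.
#
# Two engines:
#   * "ml": direct numerical maximization of the observed-data log-likelihood
#     (Nelder-Mead on log-transformed shapes/scales and log-ratio-transformed
#     masking probabilities), method-of-moments initialization, deterministic
#     restarts. This is the default for single-pair fits.
#   * "moment": closed-form solution of the model's moment and zero-probability
#     equations; orders of magnitude faster, used for large all-pairs
#     correlation matrices.

.PARAM_FLOOR <- 1e-8

# returns NULL when the pair is fittable, else a failure description
.checkPair <- function(x1, x2, minLen = 10L) {
  .assertCounts(x1, "x1")
  .assertCounts(x2, "x2")
  if (length(x1) != length(x2)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (length(x1) < minLen) {
    stop("need at least ", minLen, " paired observations", call. = FALSE)
  }
  allZero1 <- all(x1 == 0)
  allZero2 <- all(x2 == 0)
  if (allZero1 && allZero2) return("degenerate: both margins all zero")
  if (allZero1) return("degenerate: margin 1 all zero")
  if (allZero2) return("degenerate: margin 2 all zero")
  if (var(x1) == 0) return("degenerate: margin 1 constant")
  if (var(x2) == 0) return("degenerate: margin 2 constant")
  NULL
}

.fitFailure <- function(model, status, engine = "ml") {
  methods::new("BzinbFit",
    params = NULL, logLik = NA_real_, nIter = 0L, converged = FALSE,
    rho = NA_real_, trace = numeric(0), status = status, model = model,
    engine = engine
  )
}

# collapse to unique pairs with multiplicities (likelihood cost then scales
# with the number of distinct observed pairs, not n)
.uniquePairs <- function(x1, x2) {
  key <- x1 * (max(x2) + 1) + x2
  idx <- which(!duplicated(key))
  list(
    u1 = as.integer(x1[idx]), u2 = as.integer(x2[idx]),
    w = as.numeric(tabulate(match(key, key[idx])))
  )
}

.momInitBnb <- function(x1, x2) {
  m1 <- mean(x1)
  m2 <- mean(x2)
  b1 <- max(var(x1) / m1 - 1, 0.05)
  b2 <- max(var(x2) / m2 - 1, 0.05)
  k1 <- m1 / b1
  k2 <- m2 / b2
  a0 <- min(max(stats::cov(x1, x2) / (b1 * b2), 0.01), 0.9 * min(k1, k2))
  c(a0, max(k1 - a0, 0.01), max(k2 - a0, 0.01), b1, b2)
}

# deterministic perturbations used for restarts (no RNG: per-pair results are
# then independent of execution order)
.restartOffsets <- list(
  c(0.7, -0.7, 0.7, -0.7, 0.7), c(-0.9, 0.9, -0.9, 0.9, -0.9),
  c(1.2, 1.2, -1.2, -1.2, 0)
)

.runOptim <- function(th0, nll, maxIter, tol, nRestart = 3L,
                      offsets = .restartOffsets) {
  tracer <- new.env(parent = emptyenv())
  tracer$best <- -Inf
  tracer$trace <- numeric(0)
  wrapped <- function(th) {
    v <- nll(th)
    ll <- -v
    if (is.finite(ll) && ll > tracer$best) {
      tracer$best <- ll
      tracer$trace <- c(tracer$trace, ll)
    }
    v
  }
  f0 <- wrapped(th0)
  reltol <- tol / max(1, abs(f0))
  ctl <- list(maxit = 5L * maxIter, reltol = reltol)
  res <- stats::optim(th0, wrapped, method = "Nelder-Mead", control = ctl)
  for (r in seq_len(nRestart)) {
    if (res$convergence == 0L) break
    off <- rep_len(offsets[[r]], length(th0))
    res2 <- stats::optim(res$par + off, wrapped,
      method = "Nelder-Mead", control = ctl
    )
    if (res2$value <= res$value) res <- res2
  }
  # polish: restarting the simplex at the optimum escapes premature collapse
  for (r in 1:3) {
    res2 <- stats::optim(res$par, wrapped,
      method = "Nelder-Mead",
      control = ctl
    )
    improved <- res$value - res2$value
    if (res2$value <= res$value) res <- res2
    if (improved < max(tol, 1e-8)) break
  }
  list(res = res, trace = tracer$trace, ll0 = -f0)
}

#' Fit the BNB model to a pair of count vectors
#'
#' Maximizes the BNB log-likelihood over the five parameters by Nelder-Mead
#' on the log scale, starting from a method-of-moments estimate, with
#' deterministic restarts on non-convergence. Degenerate pairs (a margin
#' all-zero or constant) return an explicit failure status rather than a
#' number.
#'
#' @param x1,x2 non-negative integer vectors of equal length (>= 10).
#' @param maxIter iteration budget passed to the optimizer (default 1000).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6),
#'   applied as the optimizer's scaled relative tolerance.
#' @return a [BzinbFit-class]; `rhoBnb()` of the estimate is in the `rho`
#'   slot.
#' @examples
#' x <- rbnb(500, BnbParams(2, 1, 1, 1, 1), seed = 1)
#' fitBnb(x[, 1], x[, 2])
#' @export
fitBnb <- function(x1, x2, maxIter = 1000L, tol = 1e-6) {
  bad <- .checkPair(x1, x2)
  if (!is.null(bad)) return(.fitFailure("bnb", bad))
  up <- .uniquePairs(x1, x2)
  nll <- function(th) {
    p <- exp(pmin(pmax(th, log(.PARAM_FLOOR)), log(1e8)))
    cpp_bnb_negloglik(up$u1, up$u2, up$w, p[1], p[2], p[3], p[4], p[5])
  }
  th0 <- log(.momInitBnb(x1, x2))
  out <- .runOptim(th0, nll, maxIter, tol)
  p <- exp(pmin(pmax(out$res$par, log(.PARAM_FLOOR)), log(1e8)))
  params <- BnbParams(p[1], p[2], p[3], p[4], p[5])
  methods::new("BzinbFit",
    params = params, logLik = -out$res$value,
    nIter = as.integer(out$res$counts[["function"]]),
    converged = out$res$convergence == 0L, rho = rhoBnb(params),
    trace = out$trace, status = "ok", model = "bnb", engine = "ml"
  )
}

#' Fit the BZINB model to a pair of count vectors
#'
#' Maximizes the nine-parameter BZINB observed-data log-likelihood
#' (`engine = "ml"`), or solves the model's closed-form moment and
#' zero-probability equations (`engine = "moment"`; no likelihood
#' evaluation, orders of magnitude faster — the engine used by default for
#' large all-pairs correlation matrices). The ML engine is initialized at the
#' moment solution.
#'
#' @param y1,y2 non-negative integer vectors of equal length (>= 10).
#' @param maxIter,tol as in [fitBnb()].
#' @param engine "ml" or "moment".
#' @return a [BzinbFit-class]; `rho` holds the model-based BZINB correlation
#'   (the BNB-component correlation of the fitted parameters).
#' @examples
#' p <- BzinbParams(BnbParams(1, 1, 1, 3, 3), pi = c(0.75, 0.15, 0.05, 0.05))
#' y <- rbzinb(500, p, seed = 1)
#' fitBzinb(y[, 1], y[, 2])
#' @export
fitBzinb <- function(y1, y2, maxIter = 1000L, tol = 1e-6,
                     engine = c("ml", "moment")) {
  engine <- match.arg(engine)
  bad <- .checkPair(y1, y2)
  if (!is.null(bad)) return(.fitFailure("bzinb", bad, engine))
  mom <- .momentEstimate(y1, y2)
  if (engine == "moment") {
    if (!mom$ok) return(.fitFailure("bzinb", mom$status, "moment"))
    params <- BzinbParams(
      BnbParams(mom$a0, mom$a1, mom$a2, mom$b1, mom$b2),
      pi = mom$pi
    )
    return(methods::new("BzinbFit",
      params = params, logLik = NA_real_, nIter = 0L, converged = TRUE,
      rho = rhoBzinb(params), trace = numeric(0), status = mom$status,
      model = "bzinb", engine = "moment"
    ))
  }
  up <- .uniquePairs(y1, y2)
  nll <- function(th) {
    p <- exp(pmin(pmax(th[1:5], log(.PARAM_FLOOR)), log(1e8)))
    e <- exp(c(0, th[6:8]) - max(0, th[6:8]))
    pi <- e / sum(e)
    cpp_bzinb_negloglik(
      up$u1, up$u2, up$w, p[1], p[2], p[3], p[4], p[5],
      pi[1], pi[2], pi[3], pi[4]
    )
  }
  th0 <- .bzinbInit(y1, y2, mom)
  out <- .runOptim(th0, nll, maxIter, tol,
    offsets = lapply(.restartOffsets, rep_len, 8L)
  )
  th <- out$res$par
  p <- exp(pmin(pmax(th[1:5], log(.PARAM_FLOOR)), log(1e8)))
  e <- exp(c(0, th[6:8]) - max(0, th[6:8]))
  pivec <- e / sum(e)
  params <- BzinbParams(BnbParams(p[1], p[2], p[3], p[4], p[5]), pi = pivec)
  methods::new("BzinbFit",
    params = params, logLik = -out$res$value,
    nIter = as.integer(out$res$counts[["function"]]),
    converged = out$res$convergence == 0L, rho = rhoBzinb(params),
    trace = out$trace, status = "ok", model = "bzinb", engine = "ml"
  )
}

.bzinbInit <- function(y1, y2, mom) {
  if (mom$ok) {
    pi <- pmax(mom$pi, 0.01)
    pi <- pi / sum(pi)
    return(c(
      log(pmax(c(mom$a0, mom$a1, mom$a2, mom$b1, mom$b2), 1e-4)),
      log(pi[2:4] / pi[1])
    ))
  }
  z1 <- mean(y1 == 0)
  z2 <- mean(y2 == 0)
  z12 <- mean(y1 == 0 & y2 == 0)
  pi4 <- 0.7 * z12
  pi3 <- 0.7 * max(z1 - z12, 0.01)
  pi2 <- 0.7 * max(z2 - z12, 0.01)
  pi <- pmax(c(1 - pi2 - pi3 - pi4, pi2, pi3, pi4), 0.02)
  pi <- pi / sum(pi)
  nz <- y1 > 0 & y2 > 0
  if (sum(nz) >= 10) {
    th5 <- log(.momInitBnb(y1[nz], y2[nz]))
  } else {
    th5 <- log(.momInitBnb(y1, y2))
  }
  c(th5, log(pi[2:4] / pi[1]))
}

# ---- moment engine ---------------------------------------------------------

# per-margin: solve for the unmasking probability a and the implied NB
# parameters (mu, beta, k) from the margin's mean, second moment and zero
# fraction: E[Y] = a*mu, E[Y^2] = a*E[X^2], P(Y=0) = a*(1+beta)^-k + (1-a)
.marginSolve <- function(y) {
  m <- mean(y)
  s2m <- mean(y^2)
  z <- mean(y == 0)
  nbOf <- function(a) {
    mu <- m / a
    v <- max(s2m / a - mu^2, mu * 1.000001)
    b <- v / mu - 1
    c(mu = mu, b = b, k = mu / b)
  }
  g <- function(a) {
    p <- nbOf(a)
    a * (1 + p[["b"]])^(-p[["k"]]) + (1 - a) - z
  }
  a <- 1
  if (z > 0 && g(1) < 0) {
    lo <- max(1 - z, 1e-6)
    a <- if (g(lo) <= 0) lo else uniroot(g, c(lo, 1), tol = 1e-10)$root
  }
  c(a = a, nbOf(a))
}

.momentEstimate <- function(y1, y2) {
  eps <- .PARAM_FLOOR
  status <- "ok"
  s1 <- .marginSolve(y1)
  s2 <- .marginSolve(y2)
  a1u <- s1[["a"]]
  a2u <- s2[["a"]]
  mu1 <- s1[["mu"]]
  mu2 <- s2[["mu"]]
  b1 <- s1[["b"]]
  b2 <- s2[["b"]]
  k1 <- s1[["k"]]
  k2 <- s2[["k"]]
  m12 <- mean(as.numeric(y1) * as.numeric(y2))
  z12 <- mean(y1 == 0 & y2 == 0)
  nb01 <- (1 + b1)^(-k1)
  nb02 <- (1 + b2)^(-k2)
  loPi <- max(0, a1u + a2u - 1)
  hiPi <- min(a1u, a2u)
  kmin <- min(k1, k2)
  pi1Of <- function(a0) {
    min(max(m12 / (mu1 * mu2 + a0 * b1 * b2), loPi), hiPi)
  }
  h <- function(a0) {
    p1 <- pi1Of(a0)
    f00 <- (1 + b1 + b2)^(-a0) * (1 + b1)^(-(k1 - a0)) *
      (1 + b2)^(-(k2 - a0))
    p1 * f00 + (a1u - p1) * nb01 + (a2u - p1) * nb02 +
      (1 - a1u - a2u + p1) - z12
  }
  grid <- kmin * seq(1e-6, 1 - 1e-6, length.out = 48)
  hv <- vapply(grid, h, 0)
  sgn <- which(hv[-1] * hv[-length(hv)] <= 0)
  if (length(sgn)) {
    a0 <- uniroot(h, grid[c(sgn[1], sgn[1] + 1)], tol = 1e-10)$root
  } else {
    a0 <- grid[which.min(abs(hv))]
    status <- "ok (joint-zero equation approximate)"
  }
  a0 <- min(max(a0, eps), kmin - eps)
  p1 <- pi1Of(a0)
  pi <- c(p1, a1u - p1, a2u - p1, 1 - a1u - a2u + p1)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  list(
    ok = TRUE, status = status,
    a0 = a0, a1 = max(k1 - a0, eps), a2 = max(k2 - a0, eps),
    b1 = b1, b2 = b2, pi = pi
  )
}

# rho-only fast path used by corrMatrix (avoids S4 construction per pair)
.rhoMoment <- function(y1, y2) {
  bad <- .checkPair(y1, y2)
  if (!is.null(bad)) return(list(rho = NA_real_, status = bad))
  mom <- .momentEstimate(y1, y2)
  rho <- .rhoBnbFormula(mom$a0, mom$a1, mom$a2, mom$b1, mom$b2)
  list(rho = min(rho, 1 - 1e-12), status = mom$status)
}

#' @describeIn fitBnb accessor for the fit status string
#' @param object a [BzinbFit-class]
#' @export
setMethod("fitStatus", "BzinbFit", function(object) object@status)

#' @export
setMethod("bnbParams", "BzinbFit", function(object) {
  if (is.null(object@params)) return(NULL)
  bnbParams(object@params)
})

setMethod("show", "BzinbFit", function(object) {
  cat(sprintf(
    "%s fit (engine %s): status %s\n", toupper(object@model),
    object@engine, object@status
  ))
  if (identical(object@status, "ok") ||
      startsWith(object@status, "ok")) {
    cat(sprintf(
      "  rho = %.4f, logLik = %.3f, converged = %s, evals = %d\n",
      object@rho, object@logLik, object@converged, object@nIter
    ))
  }
})
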