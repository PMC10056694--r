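# Marginal goodness-of-fit workflow: fit zero-inflated Poisson / negative
# binomial / lognormal to each feature (parameters from the nonzero counts,
# zero proportion empirical), simulate replicates, and KS-test the lognormal
# fit on the nonzero counts.

#' Fit a zero-inflated marginal family to one count vector
#'
#' The nonzero-part parameters are estimated by maximum likelihood on the
#' nonzero counts (not a zero-truncated likelihood — the zero mass of the
#' count family is left in place, a deliberate simplification) and the zero
#' proportion is the empirical fraction of zeros.
#'
#' @param counts non-negative integer vector.
#' @param family "zip" (Poisson: mean), "zinb" (negative binomial: size and
#'   mean) or "ziln" (lognormal: meanlog, sdlog of the nonzero counts).
#' @param featureId optional identifier carried through.
#' @return a list with `family`, `params` (named numeric), `zeroProp`, `n`,
#'   `nZero`, `featureId`, `status` ("ok" or a failure reason).
#' @export
fitMarginal <- function(counts, family = c("zip", "zinb", "ziln"),
                        featureId = NA_character_) {
  family <- match.arg(family)
  .assertCounts(counts)
  n <- length(counts)
  nz <- counts[counts > 0]
  base <- list(
    family = family, params = c(), zeroProp = mean(counts == 0),
    n = n, nZero = n - length(nz), featureId = featureId, status = "ok"
  )
  if (length(nz) < 3) {
    base$status <- "failed: fewer than 3 nonzero counts"
    return(base)
  }
  base$params <- switch(family,
    zip = c(lambda = mean(nz)),
    zinb = .fitNb(nz),
    ziln = {
      lm <- log(nz)
      c(meanlog = mean(lm), sdlog = sqrt(mean((lm - mean(lm))^2)))
    }
  )
  if (anyNA(base$params)) base$status <- "failed: estimation error"
  base
}

# ML negative binomial fit (size, mu) via optim on the log scale
.fitNb <- function(x) {
  m <- mean(x)
  v <- var(x)
  size0 <- if (v > m) m^2 / (v - m) else 100
  nll <- function(th) {
    -sum(dnbinom(x, size = exp(th[1]), mu = exp(th[2]), log = TRUE))
  }
  res <- tryCatch(
    optim(log(c(max(size0, 1e-3), m)), nll, method = "Nelder-Mead"),
    error = function(e) NULL
  )
  if (is.null(res)) return(c(size = NA_real_, mu = NA_real_))
  c(size = exp(res$par[1]), mu = exp(res$par[2]))
}

#' Simulate a replicate vector from a fitted marginal
#'
#' The number of zeros is drawn Binomial(n, zeroProp); the remaining entries
#' come from the fitted nonzero family (lognormal draws are rounded to
#' integers) and positions are shuffled.
#'
#' @param fit result of [fitMarginal()].
#' @param seed optional integer seed.
#' @return non-negative integer vector of length `fit$n`.
#' @export
simulateFromMarginal <- function(fit, seed = NULL) {
  if (!identical(fit$status, "ok")) {
    stop("cannot simulate from a failed marginal fit", call. = FALSE)
  }
  .withSeed(seed, {
    n <- fit$n
    nZero <- rbinom(1L, n, fit$zeroProp)
    nPos <- n - nZero
    draws <- switch(fit$family,
      zip = rpois(nPos, fit$params[["lambda"]]),
      zinb = rnbinom(nPos,
        size = fit$params[["size"]],
        mu = fit$params[["mu"]]
      ),
      ziln = round(rlnorm(nPos, fit$params[["meanlog"]],
        fit$params[["sdlog"]]
      ))
    )
    sample(c(rep(0L, nZero), draws))
  })
}

#' Kolmogorov-Smirnov p-value for the lognormal fit of nonzero counts
#'
#' One-sample KS test of the nonzero counts against the lognormal whose
#' parameters were fitted from those same counts. This is the plain KS test
#' with estimated parameters (no Lilliefors-style correction), which is
#' conservative; ties in the counts additionally make it approximate.
#'
#' @param counts non-negative integer vector with at least 8 nonzero values.
#' @return p-value in [0, 1]; NA with status attribute on failure.
#' @export
ksLognormalPvalue <- function(counts) {
  .assertCounts(counts)
  nz <- counts[counts > 0]
  if (length(nz) < 8) {
    return(structure(NA_real_, status = "failed: fewer than 8 nonzero"))
  }
  lm <- log(nz)
  meanlog <- mean(lm)
  sdlog <- sqrt(mean((lm - meanlog)^2))
  if (sdlog < 1e-12) return(0) # degenerate: constant nonzero counts
  suppressWarnings(
    ks.test(nz, "plnorm", meanlog = meanlog, sdlog = sdlog)$p.value
  )
}

#' Feature-wise lognormal goodness-of-fit summary
#'
#' Applies [ksLognormalPvalue()] to every feature of a count matrix.
#'
#' @param x count matrix or SummarizedExperiment (features x samples).
#' @param alpha rejection threshold for the summary fraction (default 0.05).
#' @return a list with `table` (feature, n, nZero, pValue, status) and
#'   `fractionBelow` (share of testable features with p < alpha).
#' @export
gofSummary <- function(x, alpha = 0.05) {
  m <- .countMatrix(x)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cnt <- m[i, ]
    p <- ksLognormalPvalue(cnt)
    data.frame(
      feature = rownames(m)[i], n = length(cnt),
      nZero = sum(cnt == 0), pValue = as.numeric(p),
      status = if (is.na(p)) attr(p, "status") else "ok",
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(
      feature = character(0), n = integer(0), nZero = integer(0),
      pValue = numeric(0), status = character(0)
    )
  }
  ok <- !is.na(tab$pValue)
  list(
    table = tab,
    fractionBelow = if (any(ok)) mean(tab$pValue[ok] < alpha) else NA_real_,
    nSkipped = sum(!ok)
  )
}
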