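#' Parameters of the bivariate negative binomial (BNB) model
#'
#' The BNB model is a shared-component Poisson--Gamma mixture: with
#' independent latent variables \eqn{R_0 \sim Gamma(\alpha_0, \beta_1)},
#' \eqn{R_1 \sim Gamma(\alpha_1, \beta_1)}, \eqn{R_2 \sim Gamma(\alpha_2,
#' \beta_1)} (scale parameterisation), the pair is
#' \eqn{X_1 | R \sim Pois(R_0 + R_1)} and
#' \eqn{X_2 | R \sim Pois(\delta (R_0 + R_2))} with
#' \eqn{\delta = \beta_2 / \beta_1}. Marginally
#' \eqn{X_i \sim NB(\alpha_0 + \alpha_i, 1 / (\beta_i + 1))}, and the shared
#' component \eqn{R_0} induces a non-negative correlation.
#'
#' @slot alpha0 positive shape of the shared Gamma component.
#' @slot alpha1,alpha2 positive shapes of the idiosyncratic components.
#' @slot beta1,beta2 positive scale parameters of the two margins.
#'
#' @seealso [BnbParams()], [rhoBnb()], [dbnb()], [rbnb()]
#' @export
setClass("BnbParams",
  representation(
    alpha0 = "numeric", alpha1 = "numeric", alpha2 = "numeric",
    beta1 = "numeric", beta2 = "numeric"
  )
)

setValidity("BnbParams", function(object) {
  v <- c(
    alpha0 = object@alpha0, alpha1 = object@alpha1, alpha2 = object@alpha2,
    beta1 = object@beta1, beta2 = object@beta2
  )
  if (length(v) != 5L || anyNA(v) || any(!is.finite(v))) {
    return("all five parameters must be finite scalars")
  }
  if (any(v <= 0)) {
    return("all five parameters must be strictly positive")
  }
  TRUE
})

#' Parameters of the bivariate zero-inflated negative binomial (BZINB) model
#'
#' A BNB pair overlaid with a four-category zero-masking layer: with
#' probability \eqn{\pi_1} both margins are observed, \eqn{\pi_2} only the
#' first is observed (the second is masked to zero), \eqn{\pi_3} only the
#' second, and \eqn{\pi_4} both are masked. The masking probabilities describe
#' zero inflation, not the probability of observing a zero: the latent NB
#' component produces zeros of its own.
#'
#' @slot bnb a [BnbParams-class] object, the latent BNB component.
#' @slot pi numeric vector of length 4 (\eqn{\pi_1..\pi_4}) on the simplex.
#'
#' @seealso [BzinbParams()], [rhoBzinb()], [dbzinb()], [rbzinb()]
#' @export
setClass("BzinbParams",
  representation(bnb = "BnbParams", pi = "numeric")
)

setValidity("BzinbParams", function(object) {
  p <- object@pi
  if (length(p) != 4L || anyNA(p)) {
    return("pi must be a numeric vector of length 4")
  }
  if (any(p < 0) || any(p > 1)) {
    return("each masking probability must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    return("masking probabilities must sum to 1 (tolerance 1e-9)")
  }
  TRUE
})

#' Result of fitting a BNB or BZINB model to a pair of count vectors
#'
#' @slot params the fitted [BnbParams-class] or [BzinbParams-class];
#'   may be empty when the fit failed.
#' @slot logLik maximised observed-data log-likelihood (NA for the fast
#'   moment engine, which does not evaluate the likelihood).
#' @slot nIter number of objective evaluations / iterations used.
#' @slot converged logical convergence flag.
#' @slot rho the applicable model-based correlation estimate, in [0, 1);
#'   NA when the fit failed.
#' @slot trace non-decreasing trace of accepted log-likelihood values.
#' @slot status "ok" or a human-readable failure description.
#' @slot model "bnb" or "bzinb".
#' @slot engine "ml" (numerical maximum likelihood) or "moment".
#' @export
setClass("BzinbFit",
  representation(
    params = "ANY", logLik = "numeric", nIter = "integer",
    converged = "logical", rho = "numeric", trace = "numeric",
    status = "character", model = "character", engine = "character"
  )
)

setValidity("BzinbFit", function(object) {
  if (!object@model %in% c("bnb", "bzinb")) return("model must be bnb/bzinb")
  if (identical(object@status, "ok") &&
      (is.na(object@rho) || object@rho < 0 || object@rho >= 1)) {
    return("rho must lie in [0, 1) for a successful fit")
  }
  if (length(object@trace) > 1 &&
      any(diff(object@trace) < -1e-8)) {
    return("log-likelihood trace must be non-decreasing")
  }
  TRUE
})

#' Pairwise correlation matrix with per-entry fit status
#'
#' @slot values numeric matrix of correlations; model-based entries lie in
#'   [0, 1), rank/linear correlations in [-1, 1]; failed entries are NA.
#' @slot method one of "spearman", "pearson", "bnb", "bzinb".
#' @slot status character matrix parallel to `values`; "ok" or a failure tag.
#' @export
setClass("CorrMatrix",
  representation(values = "matrix", method = "character", status = "matrix")
)

setValidity("CorrMatrix", function(object) {
  if (!all(dim(object@values) == dim(object@status))) {
    return("values and status must have identical dimensions")
  }
  bad <- !is.finite(object@values) & object@status == "ok"
  bad[row(bad) == col(bad)] <- FALSE
  if (any(bad)) {
    return("every non-finite off-diagonal entry must carry a failure flag")
  }
  TRUE
})

#' Spectral clustering solution
#'
#' @slot labels integer cluster labels in 1..k, named by feature.
#' @slot k number of clusters.
#' @slot eigenvalues ascending eigenvalues of the symmetric normalised
#'   Laplacian, kept for eigengap diagnostics.
#' @slot seed seed used for the k-means step.
#' @slot isolated features with zero affinity degree, assigned by the
#'   nearest-centroid fallback.
#' @export
setClass("ClusterSolution",
  representation(
    labels = "integer", k = "integer", eigenvalues = "numeric",
    seed = "integer", isolated = "character"
  )
)

setValidity("ClusterSolution", function(object) {
  if (anyNA(object@labels) || any(object@labels < 1L) ||
      any(object@labels > object@k)) {
    return("labels must lie in 1..k with every feature labelled")
  }
  TRUE
})

#' Weighted feature-feature edge list with node annotations
#'
#' @slot edgeTable data.frame with columns source, target, weight, method,
#'   group (one of "groupA", "groupB", "both", or NA when ungrouped).
#' @slot nodeTable data.frame with columns id, layer and optional attributes
#'   (e.g. metabolite superpathway).
#' @export
setClass("EdgeList",
  representation(edgeTable = "data.frame", nodeTable = "data.frame")
)

setValidity("EdgeList", function(object) {
  e <- object@edgeTable
  need <- c("source", "target", "weight", "method", "group")
  if (!all(need %in% names(e))) {
    return(paste("edgeTable must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(e$source == e$target)) return("self-edges are not allowed")
    key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
    if (anyDuplicated(key)) return("duplicate undirected edges")
    if (any(!is.finite(e$weight))) return("weights must be finite")
  }
  TRUE
})
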