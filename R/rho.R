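.rhoBnbFormula <- function(a0, a1, a2, b1, b2) {
  a0 * sqrt(b1 * b2) /
    sqrt((a0 + a1) * (a0 + a2) * (b1 + 1) * (b2 + 1))
}

#' Model-based correlation of the BNB model
#'
#' \deqn{\rho_{BNB} = \frac{\alpha_0 \sqrt{\beta_1 \beta_2}}
#'   {\sqrt{(\alpha_0+\alpha_1)(\alpha_0+\alpha_2)(\beta_1+1)(\beta_2+1)}}}
#' which is the Pearson correlation of the latent pair and always lies in
#' [0, 1): the shared Gamma component can only induce non-negative dependence.
#'
#' @param object a [BnbParams-class], [BzinbParams-class] (its BNB component
#'   is used) or [BzinbFit-class] object.
#' @return correlation in [0, 1).
#' @export
setMethod("rhoBnb", "BnbParams", function(object) {
  .rhoBnbFormula(
    object@alpha0, object@alpha1, object@alpha2,
    object@beta1, object@beta2
  )
})

#' @rdname rhoBnb-BnbParams-method
#' @export
setMethod("rhoBnb", "BzinbParams", function(object) rhoBnb(object@bnb))

#' Model-based correlation of a fitted BZINB model
#'
#' The headline estimator: the BNB-component correlation of the fitted BZINB
#' parameters, ignoring the masking probabilities. It estimates the
#' underlying association free of zero inflation.
#'
#' @param object a [BzinbParams-class] object or a [BzinbFit-class] from
#'   [fitBzinb()]; a failed fit propagates as NA.
#' @return correlation in [0, 1), or NA for a failed fit.
#' @export
setMethod("rhoBzinb", "BzinbParams", function(object) rhoBnb(object@bnb))

#' @rdname rhoBzinb-BzinbParams-method
#' @export
setMethod("rhoBzinb", "BzinbFit", function(object) {
  if (!startsWith(object@status, "ok")) {
    warning("fit failed (", object@status, "); rho is NA", call. = FALSE)
    return(NA_real_)
  }
  object@rho
})

#' @rdname rhoBnb-BnbParams-method
#' @export
setMethod("rhoBnb", "BzinbFit", function(object) rhoBzinb(object))

#' Naive (unconditional) correlation of the BZINB model
#'
#' The Pearson correlation of the masked pair itself, involving all nine
#' parameters:
#' \deqn{\tilde\rho_{BZINB} = \sigma_{12} / (\sigma_1 \sigma_2)} with
#' \eqn{\sigma_{12} = \{\alpha_0 + (\alpha_0+\alpha_1)(\alpha_0+\alpha_2)\}
#' \beta_1\beta_2\pi_1 - (\alpha_0+\alpha_1)(\alpha_0+\alpha_2)\beta_1\beta_2
#' (\pi_1+\pi_2)(\pi_1+\pi_3)} and
#' \eqn{\sigma_j^2 = (\alpha_0+\alpha_j)^2\beta_j^2 (\pi_1+\pi_{j+1})
#' (1-\pi_1-\pi_{j+1}) + (\alpha_0+\alpha_j)\beta_j(\beta_j+1)
#' (\pi_1+\pi_{j+1})}. Unlike the model-based correlation it can be negative
#' (masking of opposite margins induces negative dependence).
#'
#' @param object a [BzinbParams-class] object.
#' @return a signed correlation, or NA (with a warning) when a margin has
#'   zero variance.
#' @export
setMethod("rhoNaiveBzinb", "BzinbParams", function(object) {
  m <- bzinbMoments(object)
  if (m$naiveSigma1Sq <= 0 || m$naiveSigma2Sq <= 0) {
    warning("zero masked-margin variance; naive correlation undefined",
      call. = FALSE
    )
    return(NA_real_)
  }
  m$naiveSigma12 / sqrt(m$naiveSigma1Sq * m$naiveSigma2Sq)
})

#' Closed-form moments of the BNB / BZINB model
#'
#' Unmasked (BNB) moments: `mean_i = (alpha0 + alphai) betai`,
#' `var_i = (alpha0 + alphai) betai (betai + 1)`,
#' `cov = alpha0 beta1 beta2`. The `naive*` entries are the moments of the
#' masked pair and feed the naive correlation.
#'
#' @param object a [BnbParams-class] (treated as masking-free) or
#'   [BzinbParams-class] object.
#' @return a list with elements `mean1, mean2, var1, var2, cov,
#'   naiveMean1, naiveMean2, naiveSigma12, naiveSigma1Sq, naiveSigma2Sq`.
#' @export
setMethod("bzinbMoments", "BzinbParams", function(object) {
  b <- object@bnb
  p <- object@pi
  .momentsImpl(b@alpha0, b@alpha1, b@alpha2, b@beta1, b@beta2, p)
})

#' @rdname bzinbMoments-BzinbParams-method
#' @export
setMethod("bzinbMoments", "BnbParams", function(object) {
  .momentsImpl(
    object@alpha0, object@alpha1, object@alpha2,
    object@beta1, object@beta2, c(1, 0, 0, 0)
  )
})

.momentsImpl <- function(a0, a1, a2, b1, b2, p) {
  k1 <- a0 + a1
  k2 <- a0 + a2
  u1 <- p[1] + p[2] # margin 1 unmasked
  u2 <- p[1] + p[3] # margin 2 unmasked
  s12 <- (a0 + k1 * k2) * b1 * b2 * p[1] - k1 * k2 * b1 * b2 * u1 * u2
  s1 <- k1^2 * b1^2 * u1 * (1 - u1) + k1 * b1 * (b1 + 1) * u1
  s2 <- k2^2 * b2^2 * u2 * (1 - u2) + k2 * b2 * (b2 + 1) * u2
  list(
    mean1 = k1 * b1, mean2 = k2 * b2,
    var1 = k1 * b1 * (b1 + 1), var2 = k2 * b2 * (b2 + 1),
    cov = a0 * b1 * b2,
    naiveMean1 = u1 * k1 * b1, naiveMean2 = u2 * k2 * b2,
    naiveSigma12 = s12, naiveSigma1Sq = s1, naiveSigma2Sq = s2
  )
}
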