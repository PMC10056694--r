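#' Construct BNB model parameters
#'
#' @param alpha0 positive shape of the shared Gamma component; larger values
#'   relative to `alpha1`/`alpha2` give stronger correlation.
#' @param alpha1,alpha2 positive idiosyncratic shapes.
#' @param beta1,beta2 positive scales; the margin means are
#'   `(alpha0 + alphai) * betai`.
#' @return a validated [BnbParams-class] object.
#' @examples
#' p <- BnbParams(1, 1, 1, 2, 2)
#' rhoBnb(p)
#' @export
BnbParams <- function(alpha0, alpha1, alpha2, beta1, beta2) {
  methods::new("BnbParams",
    alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1),
    alpha2 = as.numeric(alpha2), beta1 = as.numeric(beta1),
    beta2 = as.numeric(beta2)
  )
}

#' Construct BZINB model parameters
#'
#' @param bnb a [BnbParams-class] object (alternatively supply the five
#'   numeric parameters via `...`).
#' @param pi numeric vector `c(pi1, pi2, pi3, pi4)` on the 4-simplex:
#'   probabilities that both margins are observed / only the first / only the
#'   second / neither.
#' @param ... `alpha0, alpha1, alpha2, beta1, beta2` when `bnb` is missing.
#' @return a validated [BzinbParams-class] object.
#' @examples
#' BzinbParams(BnbParams(1, 1, 1, 2, 2), pi = c(0.75, 0.15, 0.05, 0.05))
#' @export
BzinbParams <- function(bnb, pi, ...) {
  if (missing(bnb)) bnb <- BnbParams(...)
  methods::new("BzinbParams", bnb = bnb, pi = as.numeric(pi))
}

#' @describeIn BnbParams shape of the shared component
#' @param object a parameter object
#' @export
setMethod("alpha0", "BnbParams", function(object) object@alpha0)
#' @export
setMethod("alpha1", "BnbParams", function(object) object@alpha1)
#' @export
setMethod("alpha2", "BnbParams", function(object) object@alpha2)
#' @export
setMethod("beta1", "BnbParams", function(object) object@beta1)
#' @export
setMethod("beta2", "BnbParams", function(object) object@beta2)

#' @export
setMethod("alpha0", "BzinbParams", function(object) object@bnb@alpha0)
#' @export
setMethod("alpha1", "BzinbParams", function(object) object@bnb@alpha1)
#' @export
setMethod("alpha2", "BzinbParams", function(object) object@bnb@alpha2)
#' @export
setMethod("beta1", "BzinbParams", function(object) object@bnb@beta1)
#' @export
setMethod("beta2", "BzinbParams", function(object) object@bnb@beta2)

#' @describeIn BzinbParams the masking probability vector pi1..pi4
#' @param object a parameter object
#' @export
setMethod("zeroInflation", "BzinbParams", function(object) {
  stats::setNames(object@pi, c("pi1", "pi2", "pi3", "pi4"))
})

#' @describeIn BzinbParams the latent BNB component
#' @export
setMethod("bnbParams", "BzinbParams", function(object) object@bnb)
#' @export
setMethod("bnbParams", "BnbParams", function(object) object)

#' Scale ratio delta = beta2 / beta1
#'
#' @param object a [BnbParams-class] or [BzinbParams-class] object.
#' @return the positive scale ratio between the two margins.
#' @export
deltaRatio <- function(object) beta2(object) / beta1(object)

setMethod("show", "BnbParams", function(object) {
  cat("BNB parameters\n")
  cat(sprintf(
    "  alpha0 = %.4g, alpha1 = %.4g, alpha2 = %.4g\n",
    object@alpha0, object@alpha1, object@alpha2
  ))
  cat(sprintf(
    "  beta1 = %.4g, beta2 = %.4g (delta = %.4g)\n",
    object@beta1, object@beta2, object@beta2 / object@beta1
  ))
  cat(sprintf("  rhoBnb = %.4f\n", rhoBnb(object)))
})

setMethod("show", "BzinbParams", function(object) {
  cat("BZINB parameters\n")
  show(object@bnb)
  cat(sprintf(
    "  pi = (%.3f, %.3f, %.3f, %.3f)\n",
    object@pi[1], object@pi[2], object@pi[3], object@pi[4]
  ))
})

#' Write model parameters to a flat JSON file
#'
#' Keys are `alpha0, alpha1, alpha2, beta1, beta2` and, for BZINB,
#' `pi1..pi4`.
#'
#' @param params a [BnbParams-class] or [BzinbParams-class] object.
#' @param path output file path.
#' @export
writeParams <- function(params, path) {
  x <- list(
    alpha0 = alpha0(params), alpha1 = alpha1(params),
    alpha2 = alpha2(params), beta1 = beta1(params), beta2 = beta2(params)
  )
  if (methods::is(params, "BzinbParams")) {
    p <- zeroInflation(params)
    x <- c(x, as.list(p))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from a flat JSON file
#'
#' @param path file written by [writeParams()].
#' @return a [BzinbParams-class] object when pi keys are present, else a
#'   [BnbParams-class] object.
#' @export
readParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bnb <- BnbParams(x$alpha0, x$alpha1, x$alpha2, x$beta1, x$beta2)
  if (!is.null(x$pi1)) {
    return(BzinbParams(bnb, pi = c(x$pi1, x$pi2, x$pi3, x$pi4)))
  }
  bnb
}
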