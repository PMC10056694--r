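#' Sample pairs from the BNB model
#'
#' Latent-variable generation: per observation draw the three Gamma
#' components, then the two conditionally independent Poisson counts.
#'
#' @param n number of pairs.
#' @param params a [BnbParams-class] object.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return integer matrix with `n` rows and columns `x1`, `x2`.
#' @examples
#' x <- rbnb(1000, BnbParams(2, 1, 1, 1, 1), seed = 1)
#' cor(x[, 1], x[, 2]) # near rhoBnb of the parameters
#' @export
rbnb <- function(n, params, seed = NULL) {
  stopifnot(n >= 1)
  params <- bnbParams(params)
  .withSeed(seed, {
    b <- params@beta1
    delta <- params@beta2 / params@beta1
    r0 <- rgamma(n, shape = params@alpha0, scale = b)
    r1 <- rgamma(n, shape = params@alpha1, scale = b)
    r2 <- rgamma(n, shape = params@alpha2, scale = b)
    cbind(
      x1 = rpois(n, r0 + r1),
      x2 = rpois(n, delta * (r0 + r2))
    )
  })
}

#' Sample pairs from the BZINB model
#'
#' A BNB draw followed by a four-category masking draw: category 2 masks the
#' second margin to zero, category 3 the first, category 4 both.
#'
#' @param n number of pairs.
#' @param params a [BzinbParams-class] object.
#' @param seed optional integer seed.
#' @return integer matrix with `n` rows and columns `x1`, `x2`.
#' @export
rbzinb <- function(n, params, seed = NULL) {
  stopifnot(n >= 1, methods::is(params, "BzinbParams"))
  .withSeed(seed, {
    x <- rbnb(n, params@bnb)
    z <- sample.int(4L, n, replace = TRUE, prob = params@pi)
    x[z == 2L | z == 4L, "x2"] <- 0L
    x[z == 3L | z == 4L, "x1"] <- 0L
    x
  })
}
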