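#' Joint probability mass function of the BNB model
#'
#' Computes \eqn{P(X_1 = x_1, X_2 = x_2)} under the shared-component
#' Poisson--Gamma mixture via the finite-sum decomposition: conditioning on
#' the shared-component event counts in each margin reduces the joint mass to
#' a double convolution of a closed-form bivariate term with the two
#' idiosyncratic negative binomial pmfs. All terms are accumulated in log
#' space with log-Gamma tables.
#'
#' @param x1,x2 non-negative integer vectors (recycled to common length).
#' @param params a [BnbParams-class] or [BzinbParams-class] object (the BNB
#'   component is used).
#' @param log return log probabilities.
#' @return numeric vector of (log) probabilities.
#' @examples
#' dbnb(0, 0, BnbParams(1, 1, 1, 1, 1)) # = 1/12
#' @export
dbnb <- function(x1, x2, params, log = FALSE) {
  .assertCounts(x1)
  .assertCounts(x2)
  params <- bnbParams(params)
  n <- max(length(x1), length(x2))
  x1 <- as.integer(rep_len(x1, n))
  x2 <- as.integer(rep_len(x2, n))
  lp <- cpp_bnb_logpmf(
    x1, x2, params@alpha0, params@alpha1, params@alpha2,
    params@beta1, params@beta2
  )
  if (log) lp else exp(lp)
}

#' Joint probability mass function of the BZINB model
#'
#' \eqn{P(Y_1 = y_1, Y_2 = y_2) = \pi_1 f(y_1, y_2) + \pi_2 f_1(y_1)
#' 1\{y_2 = 0\} + \pi_3 1\{y_1 = 0\} f_2(y_2) + \pi_4 1\{y_1 = 0, y_2 = 0\}},
#' where \eqn{f} is the BNB joint pmf and \eqn{f_j} the
#' \eqn{NB(\alpha_0 + \alpha_j, 1/(\beta_j + 1))} marginal pmf.
#'
#' @param y1,y2 non-negative integer vectors (recycled to common length).
#' @param params a [BzinbParams-class] object.
#' @param log return log probabilities.
#' @return numeric vector of (log) probabilities.
#' @export
dbzinb <- function(y1, y2, params, log = FALSE) {
  .assertCounts(y1)
  .assertCounts(y2)
  stopifnot(methods::is(params, "BzinbParams"))
  n <- max(length(y1), length(y2))
  y1 <- as.integer(rep_len(y1, n))
  y2 <- as.integer(rep_len(y2, n))
  b <- params@bnb
  p <- params@pi
  lp <- cpp_bzinb_logpmf(
    y1, y2, b@alpha0, b@alpha1, b@alpha2, b@beta1, b@beta2,
    p[1], p[2], p[3], p[4]
  )
  if (log) lp else exp(lp)
}
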