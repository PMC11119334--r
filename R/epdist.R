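#' The exponential power (generalized Gaussian) distribution
#'
#' Density, log-density, random generation and variance for the symmetric
#' exponential power distribution with location 0, scale `sigma` and shape
#' `shape`, with density
#' \deqn{f(x) = \frac{p}{\Gamma(1/p)\,2^{1+1/p}\,\sigma}
#'              \exp\{-\tfrac12 |x/\sigma|^p\},}
#' where `p = shape`. The Gaussian distribution is the special case
#' `shape = 2` (with `sigma` the standard deviation) and the Laplace
#' distribution the case `shape = 1` (with scale parameter `2 * sigma`).
#' Shapes below 2 give heavier-than-Gaussian tails, which is what makes the
#' mixture-regression estimator built on this family robust to outliers.
#'
#' `repow()` draws variates via the stochastic representation
#' \eqn{X = \sigma (2G)^{1/p} S} with \eqn{G \sim \mathrm{Gamma}(1/p, 1)}
#' and \eqn{S} a random sign, which follows from the change of variables
#' \eqn{g = \tfrac12 |x/\sigma|^p}.
#'
#' @param x numeric vector of quantiles.
#' @param n number of draws.
#' @param sigma positive scale parameter.
#' @param shape positive shape parameter `p`.
#' @param log logical; if `TRUE`, return the log-density.
#' @return `depow` a numeric vector of (log-)densities; `repow` a numeric
#'   vector of draws; `epow_var` the variance
#'   \eqn{\sigma^2 2^{2/p} \Gamma(3/p)/\Gamma(1/p)}.
#' @examples
#' depow(0, sigma = 1, shape = 2)        # dnorm(0)
#' depow(1, sigma = 1, shape = 1)        # Laplace, scale 2
#' set.seed(1); var(repow(1e4, 1, 2))    # ~ 1
#' @export
depow <- function(x, sigma = 1, shape = 2, log = FALSE) {
  check_ep_params(sigma, shape)
  if (any(!is.finite(x))) stop("'x' must be finite")
  ld <- log(shape) - lgamma(1 / shape) - (1 + 1 / shape) * log(2) -
    log(sigma) - 0.5 * abs(x / sigma)^shape
  if (log) ld else exp(ld)
}

#' @rdname depow
#' @export
repow <- function(n, sigma = 1, shape = 2) {
  check_ep_params(sigma, shape)
  g <- stats::rgamma(n, shape = 1 / shape, rate = 1)
  s <- sample(c(-1, 1), n, replace = TRUE)
  sigma * (2 * g)^(1 / shape) * s
}

#' @rdname depow
#' @export
epow_var <- function(sigma = 1, shape = 2) {
  check_ep_params(sigma, shape)
  sigma^2 * 2^(2 / shape) * exp(lgamma(3 / shape) - lgamma(1 / shape))
}

check_ep_params <- function(sigma, shape) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be positive and finite")
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop("'shape' must be positive and finite")
  invisible(TRUE)
}
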