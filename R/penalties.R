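#' Penalty configuration
#'
#' Bundles the tuning constants of the doubly penalized likelihood: `lambda1`
#' scales the SCAD penalty on the regression coefficients (sparsity within
#' components), `lambda2` scales the logarithmic SCAD penalty on the mixing
#' proportions (shrinking redundant components), `a` is the SCAD concavity
#' constant, and `epsilon` is the offset inside the logarithm of the mixing
#' penalty. The mixing penalty per component is
#' \eqn{n\lambda_2[\log(\epsilon + p_{\lambda_2}(\pi_j)) - \log\epsilon]},
#' so a smaller `epsilon` makes a sharper cliff near \eqn{\pi_j = 0} and
#' therefore stronger order-selection pressure.
#'
#' @param lambda1 non-negative coefficient penalty level.
#' @param lambda2 non-negative mixing-proportion penalty level.
#' @param a SCAD constant, must exceed 2; 3.7 is the conventional choice.
#' @param epsilon small positive offset of the mixing penalty.
#' @return A list of class `"penalty_config"`.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 0, a = 3.7, epsilon = 1e-6) {
  stopifnot(is.numeric(lambda1), lambda1 >= 0,
            is.numeric(lambda2), lambda2 >= 0,
            is.numeric(epsilon), epsilon > 0)
  if (!is.numeric(a) || a <= 2) stop("SCAD constant 'a' must exceed 2")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, a = a,
                 epsilon = epsilon),
            class = "penalty_config")
}

#' SCAD penalty and its derivative
#'
#' The smoothly clipped absolute deviation penalty
#' \deqn{p_\lambda(t) = \lambda|t| \quad (|t|\le\lambda), \qquad
#'   -\frac{t^2 - 2a\lambda|t| + \lambda^2}{2(a-1)} \quad
#'   (\lambda<|t|\le a\lambda), \qquad
#'   \frac{(a+1)\lambda^2}{2} \quad (|t|>a\lambda),}
#' and its derivative on \eqn{(0,\infty)}:
#' \eqn{\lambda} on \eqn{(0,\lambda]}, \eqn{(a\lambda - t)/(a-1)} on
#' \eqn{(\lambda, a\lambda]}, and 0 beyond \eqn{a\lambda}.
#'
#' @param t numeric vector of arguments (any sign for `scad_penalty`,
#'   strictly positive for `scad_deriv`).
#' @param lambda non-negative penalty level.
#' @param a SCAD constant, > 2.
#' @return numeric vector of penalty (or derivative) values.
#' @export
scad_penalty <- function(t, lambda, a = 3.7) {
  if (a <= 2) stop("SCAD constant 'a' must exceed 2")
  stopifnot(lambda >= 0)
  at <- abs(t)
  ifelse(at <= lambda,
         lambda * at,
         ifelse(at <= a * lambda,
                -(at^2 - 2 * a * lambda * at + lambda^2) / (2 * (a - 1)),
                (a + 1) * lambda^2 / 2))
}

#' @rdname scad_penalty
#' @export
scad_deriv <- function(t, lambda, a = 3.7) {
  if (a <= 2) stop("SCAD constant 'a' must exceed 2")
  stopifnot(lambda >= 0)
  if (any(t <= 0)) stop("'t' must be strictly positive; the derivative at 0 is handled by thresholding")
  ifelse(t <= lambda,
         lambda,
         ifelse(t <= a * lambda, pmax(a * lambda - t, 0) / (a - 1), 0))
}

#' Local quadratic approximation coefficient for one regression coefficient
#'
#' Replaces the SCAD penalty near the current iterate by the quadratic
#' tangent \eqn{p_\lambda(|\beta|) \approx p_\lambda(|\hat\beta|) +
#' \frac{p'_\lambda(|\hat\beta|)}{2|\hat\beta|}(\beta^2 - \hat\beta^2)},
#' and returns the curvature \eqn{p'_\lambda(|\hat\beta|)/(2|\hat\beta|)}
#' that enters the diagonal ridge matrix of the coefficient update. When the
#' current coefficient is below `zero_threshold` (and the penalty is active)
#' the quadratic approximation degenerates; the coefficient is then locked at
#' exactly zero for the remainder of the EM run, signalled by `NA`.
#'
#' @param beta_current current value of the coefficient.
#' @param lambda,a SCAD penalty level and constant.
#' @param zero_threshold magnitude below which a coefficient is treated as
#'   zero.
#' @return A non-negative curvature, or `NA` to signal the zero-lock.
#' @export
lqa_coefficient <- function(beta_current, lambda, a = 3.7,
                            zero_threshold = 1e-3) {
  if (lambda == 0) return(0)
  ab <- abs(beta_current)
  if (ab < zero_threshold) return(NA_real_)
  scad_deriv(ab, lambda, a) / (2 * ab)
}

#' Mixing-proportion penalty and its local linear approximation slope
#'
#' The order-selection penalty on the mixing weights is
#' \deqn{P_{n2}(\pi) = n\lambda_2 \sum_j
#'   \{\log(\epsilon + p_{\lambda_2}(\pi_j)) - \log\epsilon\},}
#' with \eqn{p_{\lambda_2}} the SCAD penalty. It vanishes at
#' \eqn{\pi_j = 0} and rises steeply for small positive weights, which is the
#' mechanism that forces redundant components to zero.
#' `lla_mix_coefficient()` returns the slope of the local linear
#' approximation of the logarithmic term at the current weight,
#' \eqn{p'_{\lambda_2}(\hat\pi_j)/(\epsilon + p_{\lambda_2}(\hat\pi_j))},
#' which drives the proportion update of the EM algorithm.
#'
#' @param pi vector of mixing proportions in `[0, 1]`.
#' @param n sample size multiplying the penalty.
#' @param cfg a [penalty_config()].
#' @return `mix_penalty` a non-negative scalar; `lla_mix_coefficient` a
#'   non-negative slope per proportion.
#' @export
mix_penalty <- function(pi, n, cfg) {
  stopifnot(inherits(cfg, "penalty_config"), all(pi >= 0), all(pi <= 1))
  if (cfg$lambda2 == 0) return(0)
  n * cfg$lambda2 *
    sum(log(cfg$epsilon + scad_penalty(pi, cfg$lambda2, cfg$a)) -
          log(cfg$epsilon))
}

#' @rdname mix_penalty
#' @param pi_current a single current mixing proportion.
#' @export
lla_mix_coefficient <- function(pi_current, cfg) {
  stopifnot(inherits(cfg, "penalty_config"))
  if (cfg$lambda2 == 0) return(0 * pi_current)
  num <- ifelse(pi_current > 0,
                scad_deriv(pmax(pi_current, .Machine$double.eps),
                           cfg$lambda2, cfg$a),
                cfg$lambda2)
  num / (cfg$epsilon + scad_penalty(pi_current, cfg$lambda2, cfg$a))
}
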