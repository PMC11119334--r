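#' Mixture-of-regressions parameter state
#'
#' Container for the full parameter vector of an m-component mixture of
#' linear regressions with exponential power errors: mixing proportions
#' `pi` (on the simplex), an `m x d` coefficient matrix `beta`, per-component
#' scales `sigma` and per-component shapes `p`. The shape constraint
#' `p > 1` keeps the per-component log-likelihood concave in the residual
#' and is required by the estimator; the density itself is defined for all
#' `p > 0`.
#'
#' @param pi mixing proportions, non-negative, summing to 1.
#' @param beta numeric matrix (components in rows, covariates in columns) or
#'   a vector for a single component.
#' @param sigma positive scales, one per component.
#' @param p shapes, one per component, each greater than 1.
#' @return A list of class `"mixture_theta"` with elements `m`, `pi`,
#'   `beta`, `sigma`, `p`.
#' @export
mixture_theta <- function(pi, beta, sigma, p) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  beta <- as.matrix(beta)
  m <- length(pi)
  if (nrow(beta) != m || length(sigma) != m || length(p) != m)
    stop("'pi', rows of 'beta', 'sigma' and 'p' must have a common length")
  if (any(!is.finite(pi)) || any(pi < -1e-12) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("'pi' must be a probability vector summing to 1")
  if (any(!is.finite(beta))) stop("'beta' must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be positive")
  if (any(!is.finite(p)) || any(p <= 1))
    stop("shapes 'p' must exceed 1")
  structure(list(m = m, pi = pmax(pi, 0) / sum(pmax(pi, 0)),
                 beta = beta, sigma = as.numeric(sigma),
                 p = as.numeric(p)),
            class = "mixture_theta")
}

#' @export
print.mixture_theta <- function(x, ...) {
  cat(sprintf("Mixture of %d regression component(s), %d covariate(s)\n",
              x$m, ncol(x$beta)))
  tab <- cbind(pi = x$pi, sigma = x$sigma, p = x$p, x$beta)
  colnames(tab)[-(1:3)] <- paste0("beta", seq_len(ncol(x$beta)))
  rownames(tab) <- paste0("comp", seq_len(x$m))
  print(round(tab, 4))
  invisible(x)
}

# n x m matrix of per-component log pi_j + log f_{p_j}(y - x'beta_j; sigma_j)
component_logdens <- function(x, y, theta) {
  x <- as.matrix(x)
  n <- length(y)
  out <- matrix(NA_real_, n, theta$m)
  for (j in seq_len(theta$m)) {
    r <- y - drop(x %*% theta$beta[j, ])
    out[, j] <- log(theta$pi[j] + 1e-300) +
      depow(r, theta$sigma[j], theta$p[j], log = TRUE)
  }
  out
}

log_sum_exp_rows <- function(l) {
  mx <- apply(l, 1, max)
  mx + log(rowSums(exp(l - mx)))
}

#' Mixture conditional density and log-likelihood
#'
#' `conditional_density()` evaluates the conditional density of the response
#' given the covariates,
#' \eqn{f(y \mid x) = \sum_j \pi_j f_{p_j}(y - x^\top \beta_j; 0, \sigma_j)},
#' for each observation. `mixture_loglik()` sums its logarithm over the
#' sample, using the log-sum-exp device so that extreme residuals do not
#' underflow. Densities are floored at `1e-300` before taking logs so the
#' objective stays finite during line searches through degenerate parameter
#' regions.
#'
#' @param x numeric design matrix (observations in rows).
#' @param y numeric response vector.
#' @param theta a [mixture_theta()].
#' @return `conditional_density` a vector of positive densities;
#'   `mixture_loglik` a scalar log-likelihood.
#' @export
conditional_density <- function(x, y, theta) {
  stopifnot(inherits(theta, "mixture_theta"))
  pmax(exp(log_sum_exp_rows(component_logdens(x, y, theta))), 1e-300)
}

#' @rdname conditional_density
#' @export
mixture_loglik <- function(x, y, theta) {
  stopifnot(inherits(theta, "mixture_theta"))
  sum(pmax(log_sum_exp_rows(component_logdens(x, y, theta)), log(1e-300)))
}

#' Doubly penalized log-likelihood
#'
#' The objective maximized by the estimator:
#' \deqn{\tilde Q_n(\theta) = Q_n(\theta) - P_{n1}(\theta) - P_{n2}(\theta),}
#' where \eqn{Q_n} is the mixture log-likelihood, \eqn{P_{n1}(\theta) =
#' n \sum_j \sum_t p_{\lambda_1}(|\beta_{jt}|)} is the SCAD coefficient
#' penalty and \eqn{P_{n2}} is the logarithmic mixing penalty of
#' [mix_penalty()]. With both penalty levels zero this reduces to the
#' log-likelihood.
#'
#' @inheritParams conditional_density
#' @param cfg a [penalty_config()].
#' @param penalize_cols columns of `beta` included in the coefficient
#'   penalty (default all); an intercept column can be exempted here.
#' @return scalar value of the penalized objective.
#' @export
penalized_objective <- function(x, y, theta, cfg,
                                penalize_cols = seq_len(ncol(theta$beta))) {
  n <- length(y)
  pn1 <- if (cfg$lambda1 > 0)
    n * sum(scad_penalty(abs(theta$beta[, penalize_cols, drop = FALSE]),
                         cfg$lambda1, cfg$a))
  else 0
  mixture_loglik(x, y, theta) - pn1 - mix_penalty(theta$pi, n, cfg)
}
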