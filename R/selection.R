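#' Count coefficients estimated as nonzero
#'
#' A coefficient counts as nonzero when its magnitude strictly exceeds
#' `threshold` (default `1e-3`), the same notion of "zero" used by the
#' zero-locking of the EM algorithm and by the simulation metrics.
#'
#' @param theta a [mixture_theta()].
#' @param threshold strict magnitude threshold.
#' @return integer count.
#' @export
count_nonzero_beta <- function(theta, threshold = 1e-3) {
  sum(abs(theta$beta) > threshold)
}

#' Modified BIC of a fitted mixture
#'
#' \deqn{\mathrm{MBIC} = -2\,Q_n(\hat\theta) + \log(n)\,\mathrm{df}, \qquad
#'   \mathrm{df} = 3\hat m - 1 + \hat M_\beta,}
#' where \eqn{Q_n} is the unpenalized mixture log-likelihood of the fitted
#' state, \eqn{\hat m} the number of surviving components and
#' \eqn{\hat M_\beta} the number of nonzero coefficients
#' ([count_nonzero_beta()]). The degrees of freedom count one proportion
#' fewer than components (the simplex constraint), one scale and one shape
#' per component, and the active coefficients. When the shapes were frozen
#' (`fixed_p` mode) they are not estimated, so df drops to
#' \eqn{2\hat m - 1 + \hat M_\beta}.
#'
#' @inheritParams conditional_density
#' @param fit an [epmix_fit()] result.
#' @param threshold nonzero-count threshold.
#' @return scalar MBIC value (smaller is better).
#' @export
mbic <- function(x, y, fit, threshold = 1e-3) {
  stopifnot(inherits(fit, "epmix_fit"))
  n <- length(y)
  per_comp <- if (is.null(fit$control$fixed_p)) 3 else 2
  df <- per_comp * fit$m_hat - 1 + count_nonzero_beta(fit$theta, threshold)
  -2 * mixture_loglik(x, y, fit$theta) + log(n) * df
}

#' Tuning grid for the two penalty levels
#'
#' The default grid reflects the consistency conditions of the estimator,
#' which require both penalty levels to dominate the \eqn{n^{-1/2}}
#' parametric rate while still vanishing asymptotically. At the sample
#' sizes the package targets (a few hundred to a few thousand) this puts
#' the useful mixing-penalty levels `lambda2` in a narrow band around
#' \eqn{n^{-1/2}}: well below it a spurious component retaining a handful
#' of observations survives the penalty; well above it (once
#' `a * lambda2` approaches a genuine mixing weight) true components are
#' threatened. The coefficient-penalty levels `lambda1` span the range in
#' which a SCAD penalty thresholds noise coefficients without biasing
#' signals of magnitude near one (`a * lambda1 < 1`).
#'
#' @param lambda1_values,lambda2_values ascending non-negative vectors.
#' @return list of class `"tuning_grid"`.
#' @export
tuning_grid <- function(lambda1_values = c(0.05, 0.1, 0.15, 0.22),
                        lambda2_values = c(0.02, 0.03, 0.045, 0.06)) {
  stopifnot(length(lambda1_values) >= 1, length(lambda2_values) >= 1,
            all(lambda1_values >= 0), all(lambda2_values >= 0),
            !is.unsorted(lambda1_values), !is.unsorted(lambda2_values))
  structure(list(lambda1_values = lambda1_values,
                 lambda2_values = lambda2_values),
            class = "tuning_grid")
}

#' Joint order and variable selection over a tuning grid
#'
#' Builds a small set of shared starting states with `m_max` components,
#' runs the penalized EM at every grid point `(lambda1, lambda2)` from each
#' of them (keeping, per cell, the restart with the smallest modified BIC),
#' and returns the fit minimizing the MBIC over the grid. Ties are resolved
#' toward the larger penalties (the sparser model): the grid is scanned in
#' ascending order and a later cell replaces the incumbent when its MBIC is
#' no worse.
#'
#' @inheritParams epmix_fit
#' @param m_max number of components to start every fit from.
#' @param grid a [tuning_grid()].
#' @param a,epsilon SCAD constant and mixing-penalty offset shared by all
#'   cells.
#' @param n_starts number of distinct starting states tried per grid cell.
#' @return An object of class `"epmix_select"`: list with `best_fit`,
#'   `best_lambda`, `mbic_surface` (matrix, `lambda1` in rows), `df`, and
#'   `m_hat`.
#' @export
epmix_select <- function(x, y, m_max = 5, grid = tuning_grid(),
                         control = em_control(), a = 3.7, epsilon = 1e-6,
                         penalize_cols = seq_len(ncol(as.matrix(x))),
                         n_starts = 1, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  inits <- epmix_init(x, y, m_max, control, n_candidates = n_starts)
  if (inherits(inits, "mixture_theta")) inits <- list(inits)
  surface <- matrix(NA_real_,
                    length(grid$lambda1_values), length(grid$lambda2_values),
                    dimnames = list(lambda1 = grid$lambda1_values,
                                    lambda2 = grid$lambda2_values))
  best <- NULL
  best_mbic <- Inf
  best_lambda <- c(NA_real_, NA_real_)
  failures <- character()
  for (i2 in seq_along(grid$lambda2_values)) {
    for (i1 in seq_along(grid$lambda1_values)) {
      cfg <- penalty_config(grid$lambda1_values[i1],
                            grid$lambda2_values[i2], a = a,
                            epsilon = epsilon)
      fit <- NULL
      val <- Inf
      for (init in inits) {
        f <- tryCatch(
          epmix_fit(x, y, init$m, cfg, control, init = init,
                    penalize_cols = penalize_cols),
          error = function(e) e)
        if (inherits(f, "error")) {
          failures <- c(failures, sprintf(
            "lambda1=%g lambda2=%g: %s", grid$lambda1_values[i1],
            grid$lambda2_values[i2], conditionMessage(f)))
          next
        }
        v <- mbic(x, y, f, control$zero_threshold)
        if (v < val) { val <- v; fit <- f }
      }
      if (is.null(fit)) next
      surface[i1, i2] <- val
      if (val <= best_mbic) {
        best_mbic <- val
        best <- fit
        best_lambda <- c(lambda1 = grid$lambda1_values[i1],
                         lambda2 = grid$lambda2_values[i2])
      }
    }
  }
  if (is.null(best))
    stop("every grid cell failed:\n", paste(failures, collapse = "\n"))
  per_comp <- if (is.null(control$fixed_p)) 3 else 2
  structure(list(best_fit = best, best_lambda = best_lambda,
                 mbic = best_mbic, mbic_surface = surface,
                 m_hat = best$m_hat,
                 df = per_comp * best$m_hat - 1 +
                   count_nonzero_beta(best$theta, control$zero_threshold),
                 failures = failures),
            class = "epmix_select")
}

#' @export
print.epmix_select <- function(x, ...) {
  cat(sprintf(
    "MBIC-tuned EP mixture regression: m_hat = %d, MBIC = %.2f, df = %d\n",
    x$m_hat, x$mbic, x$df))
  cat(sprintf("  selected lambda1 = %g, lambda2 = %g\n",
              x$best_lambda[1], x$best_lambda[2]))
  print(x$best_fit$theta)
  invisible(x)
}
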