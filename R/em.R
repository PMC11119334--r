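#' Control parameters of the modified EM algorithm
#'
#' @param max_iter maximum number of EM sweeps.
#' @param tol convergence tolerance on the relative change of the penalized
#'   objective between sweeps.
#' @param prune_threshold mixing proportions below this value flag their
#'   component for removal.
#' @param residual_floor floor applied to `|residual|` inside the
#'   majorization weights, preventing the slope of the tangent majorizer of
#'   `u^(p/2)` from blowing up at exact zeros when `p < 2`.
#' @param zero_threshold magnitude below which a penalized coefficient is
#'   locked at exactly zero (also the nonzero-count threshold of the
#'   modified BIC).
#' @param p_min,p_max box for the shape parameters; `p_min` must exceed 1
#'   so the per-component log-likelihood stays concave.
#' @param sigma_min,sigma_max absolute box for the scale parameters,
#'   keeping the parameter space compact.
#' @param sigma_rel_box length-2 multipliers bounding every component
#'   scale relative to the median component scale, enforced after each
#'   sweep (set `NULL` to disable). Under heavy-tailed errors an
#'   effectively unbounded scale lets a spurious diffuse component cover
#'   the extreme residuals of every other component; because such a
#'   component dominates any likelihood-based model comparison, the
#'   compactness constraint on the scales has to bind relative to the bulk
#'   noise scale for order selection to remain meaningful.
#' @param fixed_p if non-`NULL`, all shapes are frozen at this value
#'   (e.g. 2 for a Gaussian-error baseline) instead of being estimated.
#' @param restarts number of random clustering restarts tried at
#'   initialization, in addition to the model-based clustering candidate.
#' @param refine run the backward-elimination refinement at convergence:
#'   trial-remove each low-weight component, re-run a short EM, and keep
#'   the reduced model when the modified BIC improves.
#' @return A list of class `"em_control"`.
#' @export
em_control <- function(max_iter = 500, tol = 1e-6, prune_threshold = 1e-3,
                       residual_floor = 1e-6, zero_threshold = 1e-3,
                       p_min = 1.01, p_max = 10,
                       sigma_min = 1e-3, sigma_max = 1e3,
                       sigma_rel_box = NULL,
                       fixed_p = NULL, restarts = 5, refine = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, prune_threshold > 0, prune_threshold < 1,
            residual_floor > 0, zero_threshold > 0,
            p_min > 1, p_max > p_min, sigma_min > 0, sigma_max > sigma_min,
            is.null(sigma_rel_box) ||
              (length(sigma_rel_box) == 2 && all(sigma_rel_box > 0) &&
                 sigma_rel_box[1] < sigma_rel_box[2]))
  if (!is.null(fixed_p) && (fixed_p <= 1 || fixed_p > p_max))
    stop("'fixed_p' must lie in (1, p_max]")
  structure(list(max_iter = max_iter, tol = tol,
                 prune_threshold = prune_threshold,
                 residual_floor = residual_floor,
                 zero_threshold = zero_threshold,
                 p_min = p_min, p_max = p_max,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 sigma_rel_box = sigma_rel_box,
                 fixed_p = fixed_p, restarts = restarts,
                 refine = isTRUE(refine)),
            class = "em_control")
}

#' E-step: posterior component responsibilities
#'
#' Computes in log space the posterior probability that each observation
#' arises from each component,
#' \eqn{\hat p_{ij} \propto \pi_j f_{p_j}(y_i - x_i^\top\beta_j; 0, \sigma_j)},
#' with rows normalized to sum to one.
#'
#' @inheritParams conditional_density
#' @return an `n x m` row-stochastic matrix.
#' @export
e_step <- function(x, y, theta) {
  stopifnot(inherits(theta, "mixture_theta"))
  l <- component_logdens(x, y, theta)
  l <- l - apply(l, 1, max)
  g <- exp(l)
  g / rowSums(g)
}

#' M-step update of the mixing proportions
#'
#' Maximizes the local linear approximation of the penalized proportion
#' surrogate
#' \eqn{\sum_j n_j \log\pi_j - n\lambda_2 \sum_j c_j \pi_j} over the simplex,
#' where \eqn{n_j = \sum_i \hat p_{ij}} and \eqn{c_j} is the LLA slope
#' [lla_mix_coefficient()] evaluated at the current proportions. The exact
#' maximizer is \eqn{\pi_j = n_j / (\delta + n\lambda_2 c_j)} with the
#' Lagrange multiplier \eqn{\delta} solved so that the proportions sum to
#' one. With `lambda2 = 0` this is the classical EM weight update
#' \eqn{n_j / n}. Proportions driven toward zero are handled afterwards by
#' [prune_components()].
#'
#' @param posteriors row-stochastic responsibility matrix from [e_step()].
#' @param pi_current current mixing proportions (LLA expansion point).
#' @param cfg a [penalty_config()].
#' @return updated mixing proportions on the simplex.
#' @export
m_step_pi <- function(posteriors, pi_current, cfg) {
  nj <- colSums(posteriors)
  n <- nrow(posteriors)
  if (cfg$lambda2 == 0) return(nj / n)
  a <- n * cfg$lambda2 * lla_mix_coefficient(pi_current, cfg)
  pos <- nj > 0
  f <- function(delta) sum(nj[pos] / (delta + a[pos])) - 1
  lo <- -min(a[pos]) + 1e-12
  hi <- n + max(a)
  while (f(hi) > 0) hi <- hi * 2
  if (f(lo) < 0) return(nj / n)  # defensive; surrogate degenerate
  delta <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  pi_new <- ifelse(pos, nj / (delta + a), 0)
  pi_new <- pmin(pmax(pi_new, 0), 1)
  pi_new / sum(pi_new)
}

#' M-step update of one component scale
#'
#' The responsibility-weighted maximizer of
#' \eqn{\sum_i \gamma_i \{-\log\sigma - \tfrac12 |r_i/\sigma|^{p}\}} has the
#' closed form
#' \deqn{\hat\sigma = \Big[\tfrac{p}{2}\,
#'   \frac{\sum_i \gamma_i |r_i|^{p}}{\sum_i \gamma_i}\Big]^{1/p},}
#' which solves the first-order condition exactly; the result is clipped to
#' the scale box. An effectively empty component (negligible total
#' responsibility) returns `NA` to flag the component for pruning.
#'
#' @param weights responsibilities \eqn{\gamma_i} of this component.
#' @param residuals current residuals \eqn{r_i} of this component.
#' @param p shape exponent in force for this update.
#' @param control an [em_control()] (for the scale box).
#' @return updated scale, or `NA` for an empty component.
#' @export
m_step_sigma <- function(weights, residuals, p, control = em_control()) {
  sw <- sum(weights)
  if (!is.finite(sw) || sw < 1e-8) return(NA_real_)
  s <- ((p / 2) * sum(weights * abs(residuals)^p) / sw)^(1 / p)
  min(max(s, control$sigma_min), control$sigma_max)
}

#' M-step update of one component shape
#'
#' Maximizes the responsibility-weighted exponential power log-likelihood in
#' the shape,
#' \eqn{\sum_i \gamma_i \{\log p - \log\Gamma(1/p) - (1 + 1/p)\log 2
#'  - \tfrac12 |r_i/\sigma|^{p}\}},
#' over the box `[p_min, p_max]` by one-dimensional bounded search
#' ([stats::optimize()]), comparing the interior optimum against both box
#' endpoints. With `control$fixed_p` set the frozen value is returned.
#'
#' @inheritParams m_step_sigma
#' @param sigma the already-updated scale of this component.
#' @return updated shape within the box.
#' @export
m_step_p <- function(weights, residuals, sigma, control = em_control()) {
  if (!is.null(control$fixed_p)) return(control$fixed_p)
  z <- abs(residuals / sigma)
  obj <- function(p)
    sum(weights * (log(p) - lgamma(1 / p) - (1 + 1 / p) * log(2) -
                     0.5 * z^p))
  opt <- tryCatch(stats::optimize(obj, c(control$p_min, control$p_max),
                                  maximum = TRUE, tol = 1e-8),
                  error = function(e) NULL)
  cand <- c(control$p_min, control$p_max, if (!is.null(opt)) opt$maximum)
  vals <- vapply(cand, obj, numeric(1))
  if (all(!is.finite(vals))) return(control$p_min)
  cand[which.max(vals)]
}

#' Majorization weight for the L_p regression loss
#'
#' Slope of the tangent majorizer of \eqn{u \mapsto u^{p/2}} at
#' \eqn{u_0 = r^2}: \eqn{w = \tfrac{p}{2}(r^2)^{p/2 - 1}}. Substituting the
#' majorizer turns the \eqn{|r|^p} loss into a weighted least-squares
#' problem. For `p < 2` the slope diverges at `r = 0`, so `r^2` is floored
#' at `floor^2`.
#'
#' @param residual numeric vector of residuals.
#' @param p shape exponent.
#' @param floor positive floor on `|residual|`.
#' @return positive weights.
#' @export
mm_weight <- function(residual, p, floor = 1e-6) {
  (p / 2) * pmax(residual^2, floor^2)^(p / 2 - 1)
}

#' M-step update of one component coefficient vector
#'
#' Minimizes the majorized, locally quadratic surrogate of the penalized
#' component loss: a ridge-type system
#' \deqn{\hat\beta = (X^\top B X + A)^{-1} X^\top B y,}
#' with \eqn{B_{ii} = \gamma_i w_i / (2\sigma^{p})} combining the
#' responsibilities with the majorization weights [mm_weight()] evaluated at
#' the incoming coefficients, and \eqn{A = n\,\mathrm{diag}\{
#' p'_{\lambda_1}(|\beta_t|)/(2|\beta_t|)\}} from [lqa_coefficient()].
#' Coefficients whose magnitude falls below the zero threshold are locked at
#' exactly zero (excluded from the solve) for the rest of the run.
#'
#' @inheritParams conditional_density
#' @param weights responsibilities of this component.
#' @param beta_current incoming coefficient vector (majorization point).
#' @param sigma,p current scale and shape of this component.
#' @param cfg a [penalty_config()].
#' @param control an [em_control()].
#' @param locked logical vector marking coefficients already locked at zero.
#' @param penalize logical vector marking which coefficients are penalized
#'   (an intercept can be exempted).
#' @return list with elements `beta` (updated vector, exact zeros at locked
#'   positions) and `locked` (updated lock state).
#' @export
m_step_beta <- function(x, y, weights, beta_current, sigma, p, cfg,
                        control = em_control(),
                        locked = rep(FALSE, length(beta_current)),
                        penalize = rep(TRUE, length(beta_current))) {
  x <- as.matrix(x)
  d <- ncol(x)
  r_old <- y - drop(x %*% ifelse(locked, 0, beta_current))
  w <- mm_weight(r_old, p, control$residual_floor)
  b <- weights * w / (2 * sigma^p)

  acoef <- numeric(d)
  for (t in seq_len(d)) {
    if (locked[t]) next
    if (!penalize[t]) next
    ct <- lqa_coefficient(beta_current[t], cfg$lambda1, cfg$a,
                          control$zero_threshold)
    if (is.na(ct)) locked[t] <- TRUE else acoef[t] <- ct
  }
  active <- !locked
  beta_new <- numeric(d)
  if (any(active)) {
    xa <- x[, active, drop = FALSE]
    xtb <- t(xa * b)
    lhs <- xtb %*% xa
    diag(lhs) <- diag(lhs) + length(y) * acoef[active]
    rhs <- xtb %*% y
    ridge <- 1e-8 * (mean(diag(lhs)) + 1)
    sol <- tryCatch(solve(lhs, rhs), error = function(e)
      tryCatch(solve(lhs + diag(ridge, nrow(lhs)), rhs),
               error = function(e2)
                 MASS::ginv(lhs) %*% rhs))
    beta_new[active] <- drop(sol)
  }
  list(beta = beta_new, locked = locked)
}

#' Remove components with negligible mixing proportion
#'
#' Drops components whose proportion falls below `threshold` (never the last
#' one), renormalizes the proportions, and renormalizes the posterior rows
#' over the surviving components.
#'
#' @param theta a [mixture_theta()].
#' @param posteriors responsibility matrix aligned with `theta`.
#' @param threshold pruning threshold on the proportions.
#' @return list with pruned `theta`, `posteriors` and the logical `kept`
#'   index.
#' @export
prune_components <- function(theta, posteriors, threshold = 1e-3) {
  keep <- theta$pi >= threshold
  if (!any(keep)) keep[which.max(theta$pi)] <- TRUE
  if (all(keep))
    return(list(theta = theta, posteriors = posteriors, kept = keep))
  pi_new <- theta$pi[keep] / sum(theta$pi[keep])
  theta_new <- mixture_theta(pi_new, theta$beta[keep, , drop = FALSE],
                             theta$sigma[keep], theta$p[keep])
  post <- posteriors[, keep, drop = FALSE]
  post <- post / rowSums(post)
  list(theta = theta_new, posteriors = post, kept = keep)
}

#' Fit a penalized exponential power mixture of regressions
#'
#' Runs the modified EM algorithm from a given (or automatically
#' constructed) starting state: E-step responsibilities, penalized
#' proportion update, closed-form scale update, one-dimensional shape
#' update, majorized and locally quadratic coefficient update, then pruning
#' of vanishing components, iterated until the relative change of the
#' penalized objective falls below `control$tol`.
#'
#' @inheritParams conditional_density
#' @param m number of components to start from.
#' @param cfg a [penalty_config()].
#' @param control an [em_control()].
#' @param init optional [mixture_theta()] starting state; by default
#'   [epmix_init()] builds one from clustering candidates.
#' @param penalize_cols columns of the design matrix whose coefficients are
#'   penalized (default all).
#' @param seed optional integer seed applied before the (randomized)
#'   initialization.
#' @return An object of class `"epmix_fit"`: a list with the fitted `theta`
#'   (components sorted by decreasing proportion), `posteriors`,
#'   `objective_trace`, `m_hat`, `loglik`, `converged`, `n_iter`, and the
#'   `cfg`/`control` used.
#' @export
epmix_fit <- function(x, y, m, cfg = penalty_config(),
                      control = em_control(), init = NULL,
                      penalize_cols = seq_len(ncol(as.matrix(x))),
                      seed = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  d <- ncol(x)
  stopifnot(nrow(x) == n, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- if (is.null(init)) epmix_init(x, y, m, control) else init
  stopifnot(inherits(theta, "mixture_theta"))
  penalize <- seq_len(d) %in% penalize_cols

  locked <- matrix(FALSE, theta$m, d)
  trace <- penalized_objective(x, y, theta, cfg,
                               penalize_cols = which(penalize))
  converged <- FALSE
  iter <- 0
  post <- e_step(x, y, theta)

  while (iter < control$max_iter) {
    iter <- iter + 1
    post <- e_step(x, y, theta)
    pi_new <- m_step_pi(post, theta$pi, cfg)

    beta_new <- theta$beta
    sigma_new <- theta$sigma
    p_new <- theta$p
    empty <- rep(FALSE, theta$m)
    for (j in seq_len(theta$m)) {
      g <- post[, j]
      r <- y - drop(x %*% theta$beta[j, ])
      s <- m_step_sigma(g, r, theta$p[j], control)
      if (is.na(s)) { empty[j] <- TRUE; next }
      sigma_new[j] <- s
      p_new[j] <- m_step_p(g, r, sigma_new[j], control)
      upd <- m_step_beta(x, y, g, theta$beta[j, ], sigma_new[j], p_new[j],
                         cfg, control, locked[j, ], penalize)
      beta_new[j, ] <- upd$beta
      locked[j, ] <- upd$locked
    }
    pi_new[empty] <- 0
    if (sum(pi_new) == 0) pi_new <- theta$pi  # all empty: keep state
    pi_new <- pi_new / sum(pi_new)
    if (!is.null(control$sigma_rel_box) && theta$m > 1) {
      s0 <- stats::median(sigma_new)
      sigma_new <- pmin(pmax(sigma_new, control$sigma_rel_box[1] * s0),
                        control$sigma_rel_box[2] * s0)
    }
    theta <- mixture_theta(pi_new, beta_new, sigma_new,
                           pmax(p_new, control$p_min))

    # Mid-run, a component is removed only when it is BOTH negligible in
    # weight and essentially unoccupied (its points are explained by other
    # components): discarding a down-weighted component that still owns
    # observations is not an ascent step and destabilizes the scale
    # updates of whichever component inherits the points. Down-weighted
    # but occupied components persist at the small weight floor induced by
    # the epsilon offset of the mixing penalty and are dropped only in the
    # final report.
    occupancy <- colSums(post)
    drop_now <- theta$pi < control$prune_threshold & occupancy < 1
    if (any(drop_now) && !all(drop_now)) {
      keep <- !drop_now
      locked <- locked[keep, , drop = FALSE]
      theta <- mixture_theta(theta$pi[keep] / sum(theta$pi[keep]),
                             theta$beta[keep, , drop = FALSE],
                             theta$sigma[keep], theta$p[keep])
      post <- post[, keep, drop = FALSE]
      post <- post / rowSums(post)
    }

    obj <- penalized_objective(x, y, theta, cfg,
                               penalize_cols = which(penalize))
    if (!is.finite(obj))
      stop("penalized objective became non-finite at iteration ", iter)
    trace <- c(trace, obj)
    rel <- abs(obj - trace[iter]) / (abs(trace[iter]) + 1)
    if (rel < control$tol) { converged <- TRUE; break }
  }

  # Backward-elimination refinement. A spurious low-weight component can
  # sit in a local maximum the coordinate updates cannot escape (the local
  # linear approximation of the mixing penalty is nearly flat away from
  # zero). Trial-removing each low-weight component, re-running a short EM,
  # and keeping the reduced model when the modified BIC improves lets the
  # information criterion arbitrate directly between the fit with and
  # without the questionable component.
  if (isTRUE(control$refine) && theta$m > 1) {
    repeat {
      if (theta$m == 1) break
      n <- length(y)
      per_comp <- if (is.null(control$fixed_p)) 3 else 2
      mb <- function(th) {
        th_p <- prune_components(th, e_step(x, y, th),
                                 control$prune_threshold)$theta
        df <- per_comp * th_p$m - 1 +
          sum(abs(th_p$beta) > control$zero_threshold)
        -2 * mixture_loglik(x, y, th_p) + log(n) * df
      }
      cur <- mb(theta)
      cand <- which(theta$pi < 0.18)
      best_alt <- NULL
      best_val <- cur - 1e-6
      sub_control <- control
      sub_control$max_iter <- min(control$max_iter, 40)
      sub_control$refine <- FALSE
      for (j in cand) {
        keep <- setdiff(seq_len(theta$m), j)
        theta_j <- mixture_theta(theta$pi[keep] / sum(theta$pi[keep]),
                                 theta$beta[keep, , drop = FALSE],
                                 theta$sigma[keep], theta$p[keep])
        alt <- tryCatch(
          epmix_fit(x, y, theta_j$m, cfg, sub_control, init = theta_j,
                    penalize_cols = penalize_cols),
          error = function(e) NULL)
        if (is.null(alt)) next
        # a removal whose re-run collapses further has destabilized the
        # fit (the dropped component's observations overwhelmed another
        # component's scale); such trials are rejected outright
        if (alt$theta$m != theta$m - 1) next
        alt_val <- mb(alt$theta)
        if (alt_val < best_val) { best_val <- alt_val; best_alt <- alt }
      }
      if (is.null(best_alt)) break
      theta <- best_alt$theta
      trace <- c(trace, penalized_objective(x, y, theta, cfg,
                                            penalize_cols = which(penalize)))
    }
  }

  # Final report: components whose weight fell below the threshold are
  # dropped (this is where the selected order m_hat is determined), and the
  # survivors are sorted by decreasing weight.
  pr <- prune_components(theta, e_step(x, y, theta),
                         control$prune_threshold)
  theta <- pr$theta
  post <- e_step(x, y, theta)
  ord <- order(theta$pi, decreasing = TRUE)
  theta <- mixture_theta(theta$pi[ord], theta$beta[ord, , drop = FALSE],
                         theta$sigma[ord], theta$p[ord])
  post <- post[, ord, drop = FALSE]
  trace[length(trace)] <- penalized_objective(x, y, theta, cfg,
                                              penalize_cols = which(penalize))
  structure(list(theta = theta, posteriors = post,
                 objective_trace = trace, m_hat = theta$m,
                 loglik = mixture_loglik(x, y, theta),
                 converged = converged, n_iter = iter,
                 cfg = cfg, control = control),
            class = "epmix_fit")
}

#' @export
print.epmix_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized EP mixture regression fit: m_hat = %d, loglik = %.3f\n",
    x$m_hat, x$loglik))
  cat(sprintf("  %d EM iteration(s), converged: %s\n",
              x$n_iter, x$converged))
  print(x$theta)
  invisible(x)
}

#' Initial parameter state for the EM algorithm
#'
#' `method = "cluster"` (default) builds candidate hard partitions of the
#' joint `(x, y)` space — one from Gaussian model-based clustering with
#' unconstrained covariances, plus `control$restarts` randomly started
#' k-means partitions — converts each partition to a parameter state through
#' per-cluster robust regressions, scores every candidate with a short
#' Gaussian EM run, and returns the state with the best log-likelihood.
#' Model-based clustering on the joint space works here because each
#' regression component induces a Gaussian-like joint cluster with a
#' distinctive covariance structure even though all clusters share the same
#' mean.
#'
#' `method = "ols_jitter"` reproduces a simpler scheme useful for real-data
#' fits: a pooled least-squares coefficient vector perturbed by standard
#' normal jitter per component, with user-specified starting proportions,
#' scales, and shapes (clamped to the boxes).
#'
#' @inheritParams epmix_fit
#' @param method initialization strategy.
#' @param pi0,sigma0,p0 starting values for `method = "ols_jitter"`.
#' @param n_candidates number of distinct starting states to return.
#' @return a [mixture_theta()] with (at most) `m` components, or a list of
#'   up to `n_candidates` of them (best-scored first) when
#'   `n_candidates > 1`.
#' @export
epmix_init <- function(x, y, m, control = em_control(),
                       method = c("cluster", "ols_jitter"),
                       pi0 = NULL, sigma0 = NULL, p0 = NULL,
                       n_candidates = 1) {
  x <- as.matrix(x)
  method <- match.arg(method)
  n <- length(y)
  d <- ncol(x)

  if (method == "ols_jitter") {
    bols <- stats::lm.fit(x, y)$coefficients
    bols[is.na(bols)] <- 0
    beta <- t(vapply(seq_len(m), function(j) bols + stats::rnorm(d),
                     numeric(d)))
    if (is.null(pi0)) pi0 <- rep(1 / m, m)
    if (is.null(sigma0)) sigma0 <- rep(stats::sd(y), m)
    if (is.null(p0)) p0 <- rep(2, m)
    return(mixture_theta(pi0 / sum(pi0),
                         beta,
                         pmin(pmax(sigma0, control$sigma_min),
                              control$sigma_max),
                         pmin(pmax(p0, control$p_min), control$p_max)))
  }

  if (m == 1) {
    bols <- stats::lm.fit(x, y)$coefficients
    bols[is.na(bols)] <- 0
    s <- sqrt(mean((y - drop(x %*% bols))^2))
    return(mixture_theta(1, matrix(bols, 1), max(s, control$sigma_min), 2))
  }

  # Partition candidates are built on a winsorized view of the joint space:
  # gross response outliers must not seed components of their own, or the
  # EM inherits a dedicated outlier-absorbing component that distorts order
  # selection under heavy-tailed errors.
  yw <- winsorize(y)
  z <- scale(cbind(x, yw))
  min_size <- max(d + 2, ceiling(0.04 * n))
  partitions <- list()
  mc <- tryCatch(
    suppressWarnings(Mclust(cbind(x, yw), G = m,
                                    modelNames = "VVV",
                                    verbose = FALSE)$classification),
    error = function(e) NULL)
  if (!is.null(mc) && length(unique(mc)) > 1)
    partitions <- list(mc)
  for (r in seq_len(control$restarts)) {
    km <- tryCatch(stats::kmeans(z, centers = m, nstart = 1,
                                 iter.max = 20)$cluster,
                   error = function(e) NULL)
    if (!is.null(km)) partitions <- c(partitions, list(km))
  }
  if (!length(partitions))
    partitions <- list(sample(rep_len(seq_len(m), n)))
  partitions <- lapply(partitions, function(cl) {
    cl <- clean_partition(z, cl, m, min_size)
    cl <- refine_partition(x, y, cl, min_size)
    cl <- dissolve_wide_clusters(x, y, cl, min_size)
    clean_partition(z, cl, m, min_size)
  })

  # Candidates are compared by a trimmed mixture log-likelihood of the
  # state itself (worst 5% of per-point contributions dropped). No warm-up
  # EM is run — iterating a Gaussian EM here rewards degenerate likelihood
  # spikes — and the trimming keeps the comparison focused on how well the
  # bulk of the data is partitioned rather than on whether some diffuse
  # cluster happens to cover the outliers.
  partitions <- unique(partitions)
  cand <- list()
  score <- numeric()
  for (cl in partitions) {
    theta0 <- tryCatch(partition_to_theta(x, y, cl, m, control),
                       error = function(e) NULL)
    if (is.null(theta0)) next
    li <- log(conditional_density(x, y, theta0))
    keep_n <- max(1, ceiling(0.95 * length(li)))
    cand[[length(cand) + 1L]] <- theta0
    score <- c(score, sum(sort(li, decreasing = TRUE)[seq_len(keep_n)]))
  }
  if (!length(cand)) stop("initialization failed for every candidate")
  cand <- cand[order(score, decreasing = TRUE)]
  if (n_candidates == 1) cand[[1]] else cand[seq_len(min(n_candidates,
                                                         length(cand)))]
}

winsorize <- function(y, k = 6) {
  md <- stats::median(y)
  s <- stats::mad(y)
  if (s == 0) s <- stats::sd(y) + .Machine$double.eps
  pmin(pmax(y, md - k * s), md + k * s)
}

# Reabsorb clusters below min_size into their nearest large cluster, then
# pad back to m clusters by randomly splitting the largest ones, so every
# candidate has exactly m sizeable regression-like clusters.
clean_partition <- function(z, cl, m, min_size) {
  cl <- as.integer(factor(cl))
  repeat {
    sizes <- tabulate(cl)
    small <- which(sizes > 0 & sizes < min_size)
    big <- which(sizes >= min_size)
    if (!length(small) || !length(big)) break
    centers <- t(vapply(big, function(g)
      colMeans(z[cl == g, , drop = FALSE]), numeric(ncol(z))))
    for (g in small) {
      for (i in which(cl == g)) {
        dist <- rowSums((centers - matrix(z[i, ], nrow(centers),
                                          ncol(z), byrow = TRUE))^2)
        cl[i] <- big[which.min(dist)]
      }
    }
    cl <- as.integer(factor(cl))
  }
  while (length(unique(cl)) < m) {
    sizes <- tabulate(cl)
    g <- which.max(sizes)
    idx <- which(cl == g)
    take <- sample(idx, floor(length(idx) / 2))
    cl[take] <- max(cl) + 1L
    cl <- as.integer(factor(cl))
  }
  cl
}

# Classification-EM refinement of a hard partition: repeatedly fit a robust
# regression per cluster and reassign every point to the cluster whose
# regression explains it best (Laplace score with robust scale). Joint-space
# clusters are heterogeneous mixtures of the regression populations; a few
# reassignment rounds align them with the regression structure, which is
# what the EM needs as a starting point.
refine_partition <- function(x, y, cl, min_size, rounds = 4) {
  d <- ncol(x)
  n <- length(y)
  scale_floor <- max(0.05 * stats::mad(y), 1e-8)
  for (it in seq_len(rounds)) {
    labs <- sort(unique(cl))
    score <- matrix(-Inf, n, length(labs))
    for (k in seq_along(labs)) {
      idx <- which(cl == labs[k])
      if (length(idx) < max(d + 2, min_size %/% 2)) next
      fit <- tryCatch(
        suppressWarnings(MASS::rlm(x[idx, , drop = FALSE], y[idx],
                                   maxit = 20)),
        error = function(e) NULL)
      bg <- if (!is.null(fit)) stats::coef(fit)
            else stats::lm.fit(x[idx, , drop = FALSE], y[idx])$coefficients
      bg[is.na(bg)] <- 0
      sg <- max(stats::mad(y[idx] - drop(x[idx, , drop = FALSE] %*% bg)),
                scale_floor)
      r_all <- y - drop(x %*% bg)
      score[, k] <- log(length(idx) / n) - log(sg) - abs(r_all) / sg
    }
    if (all(!is.finite(score))) break
    cl_new <- labs[max.col(score, ties.method = "first")]
    if (all(cl_new == cl)) break
    cl <- cl_new
  }
  as.integer(factor(cl))
}

# Under heavy-tailed errors the refinement can park the worst-explained tail
# points of every population in a spare cluster, producing a diffuse
# pseudo-component whose scale dwarfs the others. Such clusters are not
# regression populations; dissolve them into the best-fitting regular
# cluster so every starting component is regression-like.
dissolve_wide_clusters <- function(x, y, cl, min_size, factor = 2.5) {
  d <- ncol(x)
  labs <- sort(unique(cl))
  fits <- list()
  scales <- rep(NA_real_, length(labs))
  for (k in seq_along(labs)) {
    idx <- which(cl == labs[k])
    if (length(idx) < d + 2) next
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(x[idx, , drop = FALSE], y[idx],
                                 maxit = 20)),
      error = function(e) NULL)
    bg <- if (!is.null(fit)) stats::coef(fit)
          else stats::lm.fit(x[idx, , drop = FALSE], y[idx])$coefficients
    bg[is.na(bg)] <- 0
    fits[[k]] <- bg
    scales[k] <- stats::mad(y[idx] - drop(x[idx, , drop = FALSE] %*% bg))
  }
  med <- stats::median(scales, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) return(cl)
  bad <- which(is.na(scales) | scales > factor * med)
  good <- setdiff(seq_along(labs), bad)
  if (!length(bad) || !length(good)) return(cl)
  score <- vapply(good, function(k) {
    r <- y - drop(x %*% fits[[k]])
    -abs(r) / max(scales[k], 1e-8) - log(max(scales[k], 1e-8))
  }, numeric(length(y)))
  reassign <- cl %in% labs[bad]
  cl[reassign] <- labs[good][max.col(rbind(score)[reassign, , drop = FALSE],
                                     ties.method = "first")]
  as.integer(factor(cl))
}

# Hard partition -> parameter state via per-cluster robust regressions.
partition_to_theta <- function(x, y, cl, m, control) {
  d <- ncol(x)
  labs <- sort(unique(cl))
  sigma_floor <- max(0.05 * stats::mad(y), control$sigma_min)
  beta <- NULL; sigma <- NULL; pi <- NULL
  for (g in labs) {
    idx <- which(cl == g)
    if (length(idx) < d + 2) next
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(x[idx, , drop = FALSE], y[idx],
                                 maxit = 20)),
      error = function(e) NULL)
    bg <- if (!is.null(fit)) stats::coef(fit)
          else stats::lm.fit(x[idx, , drop = FALSE], y[idx])$coefficients
    bg[is.na(bg)] <- 0
    r <- y[idx] - drop(x[idx, , drop = FALSE] %*% bg)
    sg <- max(stats::mad(r), sigma_floor)
    beta <- rbind(beta, bg)
    sigma <- c(sigma, min(sg, control$sigma_max))
    pi <- c(pi, length(idx))
  }
  if (is.null(beta)) stop("no usable cluster in partition")
  pi <- pmax(pi / sum(pi), 0.02)
  mixture_theta(pi / sum(pi), beta, sigma, rep(2, nrow(beta)))
}
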