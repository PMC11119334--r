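# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of closed forms, generic
# optimizers instead of analytic updates, coordinate descent instead of the
# ridge-type solve.

# EP density evaluated from its unnormalized kernel + numeric normalization.
ep_pdf_quadrature <- function(x, sigma, p) {
  kernel <- function(t) exp(-0.5 * abs(t / sigma)^p)
  z <- integrate(kernel, -Inf, Inf, rel.tol = 1e-12)$value
  kernel(x) / z
}

# EP cdf as a vectorized function, built by trapezoidal quadrature of the
# kernel on a fine grid (fast enough to feed ks.test).
ep_cdf_fun <- function(sigma, p, span = 40, len = 20001) {
  kernel <- function(t) exp(-0.5 * abs(t / sigma)^p)
  xs <- seq(-span * sigma, span * sigma, length.out = len)
  dens <- kernel(xs)
  step <- diff(xs[1:2])
  cdf <- cumsum((dens + c(0, dens[-len])) / 2) * step
  cdf <- cdf / cdf[len]
  approxfun(xs, cdf, yleft = 0, yright = 1)
}

# Coordinate-descent minimizer of the exact SCAD-penalized weighted
# least-squares objective sum_i b_i (y_i - x_i'beta)^2 + n sum_t p_l1(|b_t|).
cd_scad_wls <- function(x, y, b, lambda, a, beta0, n_pen = length(y),
                        max_sweeps = 500, tol = 1e-10) {
  d <- ncol(x)
  beta <- beta0
  obj1 <- function(bt, t, beta) {
    beta[t] <- bt
    r <- y - drop(x %*% beta)
    sum(b * r^2) + n_pen * sum(scad_penalty(abs(beta), lambda, a))
  }
  for (s in seq_len(max_sweeps)) {
    beta_old <- beta
    for (t in seq_len(d)) {
      opt <- optimize(obj1, c(-20, 20), t = t, beta = beta, tol = 1e-12)
      cand <- c(opt$minimum, 0)
      vals <- vapply(cand, obj1, numeric(1), t = t, beta = beta)
      beta[t] <- cand[which.min(vals)]
    }
    if (max(abs(beta - beta_old)) < tol) break
  }
  beta
}

# Small well-separated two-component regression mixture for EM smoke tests.
make_toy_mixture <- function(n = 80, seed = 1, sd = 0.4) {
  set.seed(seed)
  x <- cbind(1, rnorm(n))
  lab <- sample(1:2, n, replace = TRUE, prob = c(0.55, 0.45))
  beta <- rbind(c(2, 1), c(-2, -1.5))
  y <- rowSums(x * beta[lab, ]) + rnorm(n, sd = sd)
  list(x = x, y = y, labels = lab, beta = beta)
}

# Iterate the LQA/MM coefficient update to its fixed point (m = 1, fixed
# weights), mimicking how the EM applies it across sweeps.
iterate_beta_update <- function(x, y, gamma, sigma, p, cfg, control,
                                beta0, max_sweeps = 200) {
  beta <- beta0
  locked <- rep(FALSE, length(beta0))
  for (s in seq_len(max_sweeps)) {
    upd <- m_step_beta(x, y, gamma, beta, sigma, p, cfg, control, locked)
    if (max(abs(upd$beta - beta)) < 1e-12) {
      beta <- upd$beta; locked <- upd$locked; break
    }
    beta <- upd$beta
    locked <- upd$locked
  }
  beta
}
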