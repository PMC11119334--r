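test_that("E-step recovers Bayes-rule responsibilities", {
  x <- rbind(c(1, 0.5), c(1, -2), c(1, 1.5))
  y <- c(2.2, -0.5, 4)
  th <- mixture_theta(c(0.4, 0.6), rbind(c(2, 1), c(0, -1)),
                      c(0.8, 1.1), c(2, 2))
  post <- e_step(x, y, th)
  # direct Bayes rule with normal densities
  d1 <- 0.4 * dnorm(y, drop(x %*% c(2, 1)), 0.8)
  d2 <- 0.6 * dnorm(y, drop(x %*% c(0, -1)), 1.1)
  expect_equal(post, cbind(d1, d2) / (d1 + d2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-12)

  # single component and exact symmetry
  th1 <- mixture_theta(1, matrix(c(2, 1), 1), 0.8, 2)
  expect_equal(e_step(x, y, th1), matrix(1, 3, 1), ignore_attr = TRUE)
  thd <- mixture_theta(c(0.5, 0.5), rbind(c(2, 1), c(2, 1)),
                       c(0.8, 0.8), c(2, 2))
  expect_equal(e_step(x, y, thd), matrix(0.5, 3, 2), ignore_attr = TRUE)
})

test_that("proportion update matches the constrained surrogate maximizer", {
  cfg0 <- penalty_config(0, 0)
  post <- matrix(c(0.9, 0.2, 0.7, 0.1, 0.8, 0.3), 3, 2)
  post <- post / rowSums(post)
  # classical EM update when the penalty is off
  expect_equal(m_step_pi(post, c(0.5, 0.5), cfg0), colSums(post) / 3)
  expect_equal(m_step_pi(matrix(1, 5, 1), 1, cfg0), 1)

  # independent 1-D oracle: maximize the LLA surrogate over the simplex
  set.seed(9)
  for (rep in 1:20) {
    n <- 100
    g <- matrix(rexp(n * 2), n, 2)
    g <- g / rowSums(g)
    pi_cur <- runif(1, 0.02, 0.98)
    pi_cur <- c(pi_cur, 1 - pi_cur)
    cfg <- penalty_config(0, lambda2 = runif(1, 0.005, 0.08))
    nj <- colSums(g)
    cc <- lla_mix_coefficient(pi_cur, cfg)
    surrogate <- function(t)
      nj[1] * log(t) + nj[2] * log(1 - t) -
        n * cfg$lambda2 * (cc[1] * t + cc[2] * (1 - t))
    oracle_t <- optimize(surrogate, c(1e-9, 1 - 1e-9),
                         maximum = TRUE, tol = 1e-12)$maximum
    got <- m_step_pi(g, pi_cur, cfg)
    expect_equal(got[1], oracle_t, tolerance = 1e-6)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }

  # the printed-formula scenario: flat-tail proportions feel no pressure
  cfg <- penalty_config(0, 0.1, 3.7, 1e-6)
  g <- rbind(matrix(rep(c(1, 0), 60), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 40), ncol = 2, byrow = TRUE))
  expect_equal(m_step_pi(g, c(0.5, 0.5), cfg), c(0.6, 0.4),
               tolerance = 1e-9)
})

test_that("scale update solves the weighted first-order condition", {
  ctrl <- em_control()
  set.seed(5)
  # closed form vs generic 1-D optimizer on random weighted problems
  for (rep in 1:20) {
    nn <- 50
    w <- runif(nn)
    r <- rnorm(nn, sd = runif(1, 0.3, 3))
    p <- runif(1, 1.05, 4)
    got <- m_step_sigma(w, r, p, ctrl)
    obj <- function(s) sum(w * (-log(s) - 0.5 * abs(r / s)^p))
    oracle <- optimize(obj, c(1e-3, 1e3), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(got, oracle, tolerance = 1e-5)
  }
  # Gaussian case: root mean square residual
  r <- rnorm(200)
  expect_equal(m_step_sigma(rep(1, 200), r, 2, ctrl), sqrt(mean(r^2)),
               tolerance = 1e-12)
  # constant residuals: sigma = c * (p/2)^(1/p)
  expect_equal(m_step_sigma(rep(1, 10), rep(1.4, 10), 1.3, ctrl),
               1.4 * (1.3 / 2)^(1 / 1.3), tolerance = 1e-12)
  # empty component is flagged
  expect_true(is.na(m_step_sigma(rep(0, 5), rnorm(5), 2, ctrl)))
})

test_that("shape update is consistent and respects its box", {
  ctrl <- em_control()
  set.seed(6)
  r <- rnorm(1e4)
  s <- m_step_sigma(rep(1, 1e4), r, 2, ctrl)
  p_hat <- m_step_p(rep(1, 1e4), r, s, ctrl)
  expect_equal(p_hat, 2, tolerance = 0.15)
  # grid-search cross-check
  grid <- seq(1.01, 10, by = 0.005)
  obj <- vapply(grid, function(p)
    sum(log(p) - lgamma(1 / p) - (1 + 1 / p) * log(2) -
          0.5 * abs(r / s)^p), numeric(1))
  expect_equal(p_hat, grid[which.max(obj)], tolerance = 0.02)

  # Laplace residuals: true shape 1 lies outside the box, estimate near floor
  set.seed(7)
  rl <- repow(1e4, sigma = 1, shape = 1)
  sl <- m_step_sigma(rep(1, 1e4), rl, 1.05, ctrl)
  pl <- m_step_p(rep(1, 1e4), rl, sl, ctrl)
  expect_lt(pl, 1.2)

  ctrl_fixed <- em_control(fixed_p = 2)
  expect_identical(m_step_p(rep(1, 10), rnorm(10), 1, ctrl_fixed), 2)
})

test_that("majorization weights evaluate correctly and bound the loss", {
  expect_equal(mm_weight(c(-3, 0.1, 7), 2), c(1, 1, 1))
  expect_equal(mm_weight(2, 1.5), 0.75 * 4^(-0.25), tolerance = 1e-12)
  fl <- 1e-6
  expect_equal(mm_weight(1e-12, 1.2, fl), 0.6 * (fl^2)^(-0.4),
               tolerance = 1e-10)

  # tangent-majorization inequality on 1e4 random triples (concave regime)
  set.seed(8)
  r0 <- runif(1e4, 1e-3, 5) * sample(c(-1, 1), 1e4, replace = TRUE)
  r <- rnorm(1e4, sd = 2)
  p <- runif(1e4, 1.01, 2)
  w <- mm_weight(r0, p)
  lhs <- (r^2)^(p / 2)
  rhs <- (r0^2)^(p / 2) + w * (r^2 - r0^2)
  expect_true(all(lhs <= rhs + 1e-10))
})

test_that("coefficient update solves the penalized weighted system", {
  set.seed(10)
  n <- 40; d <- 3
  x <- matrix(rnorm(n * d), n, d)
  beta_true <- c(2, 0, 0.8)
  y <- drop(x %*% beta_true) + rnorm(n, sd = 0.5)
  ctrl <- em_control()

  # no penalty, Gaussian shape, unit responsibilities: exactly OLS
  upd <- m_step_beta(x, y, rep(1, n), beta_current = rep(0.5, d),
                     sigma = 1, p = 2, cfg = penalty_config(0, 0),
                     control = ctrl)
  expect_equal(upd$beta, unname(lm.fit(x, y)$coefficients),
               tolerance = 1e-10)

  # enormous penalty: everything zero-locks within a few sweeps
  beta <- rep(1, d); locked <- rep(FALSE, d)
  cfg_huge <- penalty_config(lambda1 = 50, lambda2 = 0)
  for (k in 1:10) {
    u <- m_step_beta(x, y, rep(1, n), beta, 1, 2, cfg_huge, ctrl, locked)
    beta <- u$beta; locked <- u$locked
  }
  expect_equal(beta, rep(0, d))
  expect_true(all(locked))

  # iterated LQA fixed point vs coordinate-descent on the exact objective
  cfg <- penalty_config(lambda1 = 0.2, lambda2 = 0)
  gamma <- rep(1, n); sigma <- 1; p <- 2
  b <- gamma * 1 / (2 * sigma^2)   # quadratic weights (w = 1 at p = 2)
  beta0 <- unname(lm.fit(x, y)$coefficients)
  ours <- iterate_beta_update(x, y, gamma, sigma, p, cfg, ctrl, beta0)
  oracle <- cd_scad_wls(x, y, b, 0.2, 3.7, beta0, n_pen = n)
  expect_equal(ours, oracle, tolerance = 1e-4)

  # zero-locked coordinates are returned as exact zeros
  u <- m_step_beta(x, y, rep(1, n), c(2, 1e-9, 0.8), 1, 2, cfg, ctrl)
  expect_identical(u$beta[2], 0)
  expect_true(u$locked[2])
})

test_that("pruning removes negligible components and renormalizes", {
  th <- mixture_theta(c(0.6, 0.4), rbind(c(1, 0), c(0, 1)), c(1, 1), c(2, 2))
  post <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  pr <- prune_components(th, post, 1e-3)
  expect_identical(pr$theta, th)

  th3 <- mixture_theta(c(0.5, 0.5 - 1e-6, 1e-6),
                       rbind(c(1, 0), c(0, 1), c(5, 5)),
                       c(1, 1, 1), c(2, 2, 2))
  post3 <- matrix(1 / 3, 4, 3)
  pr3 <- prune_components(th3, post3, 1e-3)
  expect_equal(pr3$theta$m, 2)
  expect_equal(pr3$theta$pi, c(0.5, 0.5 - 1e-6) / (1 - 1e-6),
               tolerance = 1e-12)
  expect_equal(rowSums(pr3$posteriors), rep(1, 4), tolerance = 1e-12)

  # never removes the last component
  th1 <- mixture_theta(1, matrix(c(1, 1), 1), 1, 2)
  expect_equal(prune_components(th1, matrix(1, 3, 1), 0.5)$theta$m, 1)
})

test_that("classical regression limit: one component, no penalty, Gaussian", {
  set.seed(12)
  n <- 100
  x <- cbind(1, rnorm(n))
  y <- drop(x %*% c(1, 2)) + rnorm(n, sd = 0.7)
  fit <- epmix_fit(x, y, m = 1, penalty_config(0, 0),
                   em_control(fixed_p = 2, refine = FALSE))
  ols <- unname(lm.fit(x, y)$coefficients)
  expect_equal(drop(fit$theta$beta), ols, tolerance = 1e-6)
  expect_equal(fit$theta$sigma,
               sqrt(mean((y - drop(x %*% ols))^2)), tolerance = 1e-6)
  expect_equal(fit$m_hat, 1)
})

test_that("classical EM never decreases the likelihood (50 seeds)", {
  ctrl <- em_control(max_iter = 25, fixed_p = 2, refine = FALSE)
  cfg <- penalty_config(0, 0)
  for (seed in 1:50) {
    toy <- make_toy_mixture(n = 60, seed = seed)
    fit <- epmix_fit(toy$x, toy$y, 2, cfg, ctrl, seed = seed)
    expect_true(all(diff(fit$objective_trace) >= -1e-6))
    expect_equal(rowSums(fit$posteriors), rep(1, 60), tolerance = 1e-10)
  }
})

test_that("fit results satisfy their structural invariants", {
  toy <- make_toy_mixture(n = 120, seed = 99, sd = 0.3)
  cfg <- penalty_config(0.1, 0.02)
  fit <- epmix_fit(toy$x, toy$y, 2, cfg, em_control(), seed = 99)
  expect_s3_class(fit, "epmix_fit")
  expect_equal(rowSums(fit$posteriors), rep(1, 120), tolerance = 1e-10)
  # reported components sorted by decreasing weight
  expect_true(all(diff(fit$theta$pi) <= 1e-12))
  # final trace entry equals the objective of the reported state
  expect_equal(fit$objective_trace[length(fit$objective_trace)],
               penalized_objective(toy$x, toy$y, fit$theta, cfg),
               tolerance = 1e-8)
  # label-permuted start yields the same reported fit
  init <- epmix_init(toy$x, toy$y, 2, em_control())
  initp <- mixture_theta(init$pi[2:1], init$beta[2:1, ],
                         init$sigma[2:1], init$p[2:1])
  f1 <- epmix_fit(toy$x, toy$y, 2, cfg, em_control(), init = init)
  f2 <- epmix_fit(toy$x, toy$y, 2, cfg, em_control(), init = initp)
  expect_equal(f1$theta$beta, f2$theta$beta, tolerance = 1e-6)
  expect_equal(f1$theta$pi, f2$theta$pi, tolerance = 1e-6)
})

test_that("strong mixing penalty collapses pure-noise responses toward one component", {
  set.seed(77)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)   # no mixture structure at all
  fit <- epmix_fit(x, y, m = 3, penalty_config(0.1, 0.08), em_control())
  expect_lte(fit$m_hat, 2)
})
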