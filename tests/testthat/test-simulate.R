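test_that("scenario generator reproduces the study design", {
  spec <- scenario_spec(1, 1e5)
  dat <- generate_scenario(spec, seed = 123)
  expect_equal(dim(dat$x), c(1e5, 7))

  # mixing weights within Monte-Carlo tolerance of (0.4, 0.3, 0.3)
  freq <- as.numeric(table(dat$labels)) / 1e5
  expect_equal(freq, c(0.4, 0.3, 0.3), tolerance = 0.02)

  # standard normal errors: unit residual variance within each component
  for (j in 1:3) {
    idx <- dat$labels == j
    res <- dat$y[idx] - rowSums(dat$x[idx, ] * rep(spec$true_beta[j, ],
                                                   each = sum(idx)))
    expect_equal(var(res), 1, tolerance = 0.03)
  }

  # bit-reproducible under a fixed seed
  dat2 <- generate_scenario(spec, seed = 123)
  expect_identical(dat$y, dat2$y)
  expect_identical(dat$x, dat2$x)

  # heavy-tailed scenario: extreme-tail frequency matches t(2)
  dat_t <- generate_scenario(scenario_spec(2, 1e5), seed = 11)
  res <- dat_t$y - rowSums(dat_t$x * spec$true_beta[dat_t$labels, ])
  expect_lt(abs(mean(abs(res) > 5) - 2 * pt(-5, df = 2)), 0.005)

  # scenario 4 contamination widens the error but keeps the 95% core
  dat_c <- generate_scenario(scenario_spec(4, 1e5), seed = 12)
  res_c <- dat_c$y - rowSums(dat_c$x * spec$true_beta[dat_c$labels, ])
  expect_equal(var(res_c), 0.95 * 1 + 0.05 * 25, tolerance = 0.1)
})

test_that("component matching undoes label switching", {
  beta <- rbind(c(1, 1, 1, 1, 0, 0, 0),
                c(1, 2, 3, 4, 0, 0, 0),
                c(5, 6, 7, 8, 0, 0, 0))
  truth <- mixture_theta(c(0.4, 0.3, 0.3), beta, rep(1, 3), rep(2, 3))
  expect_equal(match_components(truth, truth), c(1L, 2L, 3L))

  swapped <- mixture_theta(truth$pi[c(2, 1, 3)], beta[c(2, 1, 3), ],
                           rep(1, 3), rep(2, 3))
  expect_equal(match_components(swapped, truth), c(2L, 1L, 3L))

  # stability under small perturbations, every permutation
  set.seed(31)
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) {
    noisy <- mixture_theta(truth$pi[pm], beta[pm, ] + rnorm(21, sd = 0.05),
                           rep(1, 3), rep(2, 3))
    got <- match_components(noisy, truth)
    expect_equal(noisy$beta[got, ], beta, tolerance = 0.2)
  }

  m1 <- mixture_theta(1, matrix(beta[1, ], 1), 1, 2)
  expect_error(match_components(m1, truth), "equal")
})

test_that("error metrics follow their definitions", {
  truth_pi <- c(0.4, 0.3, 0.3)
  expect_equal(rmse_pi(rbind(truth_pi, truth_pi), truth_pi), c(0, 0, 0))
  expect_equal(rmse_pi(rbind(truth_pi + 0.1, truth_pi - 0.1), truth_pi),
               rep(0.1, 3), tolerance = 1e-12)
  set.seed(14)
  est <- rbind(matrix(rep(truth_pi, 4000), ncol = 3, byrow = TRUE)) +
    rnorm(12000, sd = 0.02)
  expect_equal(rmse_pi(est, truth_pi), rep(0.02, 3), tolerance = 0.05)

  beta <- rbind(c(1, 1, 1, 1, 0, 0, 0),
                c(1, 2, 3, 4, 0, 0, 0),
                c(5, 6, 7, 8, 0, 0, 0))
  expect_equal(rmse_beta(list(beta), beta), c(0, 0, 0))
  pert <- beta; pert[1, 1] <- pert[1, 1] + 0.1
  expect_equal(rmse_beta(list(pert), beta), c(0.1, 0, 0), tolerance = 1e-12)
  set.seed(15)
  many <- replicate(2000, beta + rnorm(21, sd = 0.05), simplify = FALSE)
  expect_equal(rmse_beta(many, beta), rep(0.05 * sqrt(7), 3),
               tolerance = 0.01)

  # zero-classification counts
  expect_equal(ncz_niz(beta, beta)$ncz, c(3, 3, 3))
  expect_equal(ncz_niz(beta, beta)$niz, c(0, 0, 0))
  expect_equal(ncz_niz(matrix(0, 3, 7), beta)$niz, c(4, 4, 4))
  bh <- rbind(c(1, 1, 1, 1, 0.002, 0, 0), beta[2:3, ])
  expect_equal(ncz_niz(bh, beta)$ncz, c(2, 3, 3))
  expect_equal(ncz_niz(bh, beta)$niz, c(0, 0, 0))

  expect_identical(classify_order(2), "underfitted")
  expect_identical(classify_order(3), "correct")
  expect_identical(classify_order(5), "overfitted")
  expect_error(classify_order(0))
})

test_that("study driver assembles per-replicate records into the table layout", {
  st <- run_study(1, n = 200, replicates = 2, m_max = 3,
                  grid = tuning_grid(0.1, 0.045),
                  control = em_control(max_iter = 60),
                  master_seed = 3)
  expect_s3_class(st, "epmix_study")
  expect_equal(st$underfitted + st$correctly_fitted + st$overfitted, 1,
               tolerance = 1e-12)
  expect_equal(nrow(st$table), 3)
  expect_named(st$table, c("scenario", "n", "component", "underfitted",
                           "correctly_fitted", "overfitted", "rmse_pi",
                           "rmse_beta", "ncz", "niz"))
  expect_length(st$records, 2)
  # metrics exist exactly when some replicate had the correct order
  if (st$m_star > 0) {
    expect_true(all(is.finite(st$rmse_beta)))
    expect_true(all(st$ncz >= 0 & st$ncz <= 3))
  } else {
    expect_true(all(is.na(st$rmse_beta)))
  }
  # deterministic given the master seed
  st2 <- run_study(1, n = 200, replicates = 2, m_max = 3,
                   grid = tuning_grid(0.1, 0.045),
                   control = em_control(max_iter = 60),
                   master_seed = 3)
  expect_identical(st$table, st2$table)
})
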