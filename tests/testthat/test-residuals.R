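test_that("Bartlett scores match the closed-form weight matrix", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 60),
                                 seed = 2)
  fit <- fit_growth_model(sim$y, sp)
  sc <- bartlett_scores(fit, sim$y)
  # independent oracle: plain matrix algebra, row by row
  lam <- growth_loadings(sp)
  th_inv <- diag(1 / fit$params$theta)
  w <- solve(t(lam) %*% th_inv %*% lam) %*% t(lam) %*% th_inv
  for (i in c(1, 17, 60)) {
    expect_equal(unname(sc[i, ]),
                 unname(drop(fit$params$eta_mean +
                               w %*% (sim$y[i, ] - fit$implied_mu))),
                 tolerance = 1e-10)
  }
  # W Lambda = I makes the scores conditionally unbiased
  expect_equal(unname(w %*% lam), diag(2), tolerance = 1e-10)
})

test_that("noise-free individuals are scored exactly", {
  set.seed(9)
  eta <- cbind(rnorm(50, 1, 0.5), rnorm(50, 0.3, 0.2))
  y <- exact_trajectories(eta)
  fit <- fit_growth_model(y, paper_spec())
  sc <- bartlett_scores(fit, y)
  expect_equal(unname(sc), unname(eta), tolerance = 1e-3)
})

test_that("Bartlett scores are conditionally unbiased on simulated data", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 4000),
                                 seed = 13)
  set.seed(13)  # regenerate the true factor scores alongside
  means <- class_mean_grid(sim$design)
  eta_true <- means[sim$labels, ] +
    matrix(rnorm(4000 * 2), 4000, 2) %*% t(chol(diag(c(0.25, 0.04))))
  fit <- fit_growth_model(sim$y, sp)
  sc <- bartlett_scores(fit, sim$y)
  for (j in 1:2) {
    slope <- stats::coef(stats::lm(sc[, j] ~ eta_true[, j]))[2]
    expect_equal(unname(slope), 1, tolerance = 0.05)
  }
  expect_equal(unname(colMeans(sc)), unname(colMeans(eta_true)),
               tolerance = 0.05)
})

test_that("per-factor case residuals equal least-squares residuals", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 80),
                                 seed = 4)
  fit <- fit_growth_model(sim$y, sp)
  members <- 1:50
  b <- residual_bundle(fit, sim$y, members)
  # oracle: lm() fit on the members, residual evaluated for everyone
  for (j in 1:2) for (t in c(1, 4)) {
    lmfit <- stats::lm(sim$y[members, t] ~ b$scores[members, j])
    pred_all <- stats::coef(lmfit)[1] + stats::coef(lmfit)[2] * b$scores[, j]
    expect_equal(b$icr[, t, j], unname(sim$y[, t] - pred_all),
                 tolerance = 1e-10)
  }
  # within-class means are zero to machine precision
  for (j in 1:2)
    expect_equal(unname(colMeans(b$icr[members, , j])), rep(0, 4),
                 tolerance = 1e-12)
  expect_true(all(is.finite(b$icr)))
})

test_that("perfect linear relation gives zero residuals and unit communality", {
  sp <- paper_spec()
  set.seed(6)
  eta <- cbind(rnorm(40, 1, 0.6), rnorm(40, 0.3, 0.2))
  y <- exact_trajectories(eta)
  fit <- fit_growth_model(y, sp)
  b <- residual_bundle(fit, y, com_mode = "per_occasion")
  # y_t = eta0 + t * eta1; y_1 depends on eta0 alone, so the intercept-factor
  # regression of y_1 is exact: zero residual, communality 1
  expect_lt(max(abs(b$icr[, 1, 1])), 1e-3)
  expect_gt(b$communality[1, 1], 0.999)
})

test_that("communalities equal squared correlations and stay in [0, 1]", {
  # hand oracle: y = (1,2,3), s = (1,2,4): r^2 = 2.25 / (1 * 7/3) = 27/28
  y <- matrix(c(1, 2, 3), ncol = 1)
  s <- matrix(c(1, 2, 4), ncol = 1)
  expect_equal(communalities(s, y)[1, 1], 27 / 28, tolerance = 1e-12)
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 120),
                                 seed = 7)
  fit <- fit_growth_model(sim$y, sp)
  b <- residual_bundle(fit, sim$y, com_mode = "per_occasion")
  expect_true(all(b$communality >= 0 & b$communality <= 1))
  # per-occasion mode matches an element-wise correlation oracle
  expect_equal(b$communality[3, 2],
               stats::cor(sim$y[, 3], b$scores[, 2])^2, tolerance = 1e-10)
  # factor-mean mode averages the per-occasion values over occasions
  bm <- residual_bundle(fit, sim$y, com_mode = "factor_mean")
  expect_equal(bm$communality[1, 2], mean(b$communality[, 2]),
               tolerance = 1e-10)
  # independent noise has communality near zero
  set.seed(99)
  noise <- matrix(rnorm(120), ncol = 1)
  expect_lt(max(communalities(b$scores, noise)), 0.1)
})

test_that("degenerate classes are rejected with informative errors", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 60),
                                 seed = 3)
  fit <- fit_growth_model(sim$y, sp)
  expect_error(residual_bundle(fit, sim$y, members = 1:2), "at least 3")
  y_const <- sim$y
  y_const[1:10, 2] <- 5
  expect_error(residual_bundle(fit, y_const, members = 1:10), "zero variance")
  expect_error(communalities(matrix(1, 10, 2), sim$y[1:10, ]), "zero variance")
})

test_that("residuals export to long-format CSV", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 40),
                                 seed = 12)
  fit <- fit_growth_model(sim$y, sp)
  b <- residual_bundle(fit, sim$y)
  p <- withr::local_tempfile(fileext = ".csv")
  write_residuals(b, p)
  long <- utils::read.csv(p)
  expect_equal(nrow(long), 40 * 4 * 2)
  expect_equal(long$residual[long$id == 7 & long$occasion == 2 &
                               long$factor == "slope"],
               b$icr[7, 2, 2])
})
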