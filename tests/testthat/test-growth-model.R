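test_that("loading matrices follow the linear and latent-basis conventions", {
  expect_equal(unname(growth_loadings(growth_spec(4))),
               cbind(1, 0:3))
  expect_equal(unname(growth_loadings(growth_spec(4, "latent_basis"),
                                      free = c(0.4, 0.7))),
               cbind(1, c(0, 0.4, 0.7, 1)))
  expect_error(growth_loadings(growth_spec(3, "latent_basis"), free = numeric(0)),
               "free coefficients")
  expect_error(growth_loadings(growth_spec(4), free = 0.5), "no free")
  expect_error(growth_spec(2), ">= 3")
})

test_that("implied moments equal the moment structure evaluated by hand", {
  sp <- paper_spec()
  pars <- paper_params()
  m <- implied_moments(pars, sp)
  # direct matrix-product oracle
  lam <- cbind(1, 0:3)
  expect_equal(m$sigma,
               lam %*% diag(c(0.25, 0.04)) %*% t(lam) +
                 diag(c(0.15, 0.20, 0.20, 0.35)),
               tolerance = 1e-12)
  expect_equal(m$sigma[1, 1], 0.40)
  expect_equal(m$sigma[3, 3], 0.25 + 4 * 0.04 + 0.20)
  expect_equal(m$mu, c(0.5, 0.8, 1.1, 1.4))
  expect_equal(m$sigma, t(m$sigma))
})

test_that("parameter validation rejects inadmissible inputs", {
  sp <- paper_spec()
  expect_error(growth_params(c(0, 0), matrix(c(1, 2, 2, 1), 2), rep(0.1, 4),
                             spec = sp), "correlation")
  expect_error(growth_params(c(0, 0), diag(2), c(0.1, 0.1, 0.1, -1),
                             spec = sp), "positive")
  expect_error(growth_params(c(0, 0), diag(2), c(0.1, 0.2, 0.1, 0.1),
                             spec = growth_spec(4, residual = "homoscedastic")),
               "homoscedastic")
})

test_that("ML discrepancy matches hand evaluation and is zero at saturation", {
  # saturated equality
  sp <- paper_spec()
  m <- implied_moments(paper_params(), sp)
  expect_equal(ml_discrepancy(m$mu, m$sigma, m$mu, m$sigma), 0)
  # 2x2 toy: S = [[2,1],[1,2]], Sigma = I, equal means:
  # F = ln 1 + tr(S) - ln 3 - 2 = 2 - ln 3
  s <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(ml_discrepancy(c(0, 0), s, c(0, 0), diag(2)), 2 - log(3),
               tolerance = 1e-12)
  # mean term: (ybar - mu)' Sigma^-1 (ybar - mu) adds on top
  expect_equal(ml_discrepancy(c(1, 0), s, c(0, 0), diag(2)),
               2 - log(3) + 1, tolerance = 1e-12)
  expect_error(ml_discrepancy(c(0, 0), diag(c(1, 0)), c(0, 0), diag(2)),
               "singular")
})

test_that("ML fit recovers the generating parameters on a large sample", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 10000),
                                 seed = 11)
  fit <- fit_growth_model(sim$y, sp)
  expect_true(fit$converged)
  est <- c(fit$params$psi[1, 1], fit$params$psi[2, 2], fit$params$theta)
  truth <- c(0.25, 0.04, 0.15, 0.20, 0.20, 0.35)
  expect_lt(max(abs(est - truth) / truth), 0.10)
  expect_lt(abs(fit$params$eta_mean[1] - 1.0), 0.05)
  expect_lt(abs(fit$params$eta_mean[2] - 0.3), 0.02)
})

test_that("fitted models reproduce their own implied moments exactly", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 2, N = 300),
                                 seed = 5)
  fit <- fit_growth_model(sim$y, sp)
  m <- implied_moments(fit$params, sp)
  expect_equal(fit$implied_sigma, m$sigma, tolerance = 1e-12)
  expect_equal(fit$implied_mu, m$mu, tolerance = 1e-12)
  expect_gt(min(eigen(fit$implied_sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("noise-free data drive residual variances and discrepancy to zero", {
  set.seed(3)
  eta <- cbind(rnorm(80, 1, 0.5), rnorm(80, 0.3, 0.2))
  y <- exact_trajectories(eta)
  fit <- fit_growth_model(y, paper_spec())
  expect_lt(max(fit$params$theta), 1e-3)
  expect_lt(fit$discrepancy, 1e-4)
})

test_that("refitting from the solution is a fixed point", {
  sp <- paper_spec()
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 400),
                                 seed = 8)
  fit1 <- fit_growth_model(sim$y, sp)
  fit2 <- fit_growth_model(sim$y, sp, start = fit1$params)
  expect_equal(fit2$params$eta_mean, fit1$params$eta_mean, tolerance = 1e-5)
  expect_equal(fit2$params$psi, fit1$params$psi, tolerance = 1e-5)
  expect_equal(fit2$params$theta, fit1$params$theta, tolerance = 1e-5)
  expect_lte(fit2$discrepancy, fit1$discrepancy + 1e-10)
})

test_that("parameter recovery is unbiased over replications", {
  # mean estimates within 3 Monte Carlo SEs of truth over 50 datasets
  sp <- paper_spec()
  truth <- c(1.0, 0.3, 0.25, 0.04, 0.15, 0.20, 0.20, 0.35)
  est <- t(vapply(1:50, function(s) {
    sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 2000),
                                   seed = 100 + s)
    f <- fit_growth_model(sim$y, sp)
    c(f$params$eta_mean, f$params$psi[1, 1], f$params$psi[2, 2],
      f$params$theta)
  }, numeric(8)))
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-8))
})

test_that("latent-basis fit of linear-truth data matches the linear fit", {
  sp_lin <- paper_spec()
  sp_lb <- growth_spec(4, "latent_basis")
  sim <- simulate_growth_mixture(simulation_design(model = 1, K = 1, N = 2000),
                                 seed = 21)
  fit_lin <- fit_growth_model(sim$y, sp_lin)
  fit_lb <- fit_growth_model(sim$y, sp_lb)
  # linear truth: free basis loadings approach (1/3, 2/3) and the
  # latent-basis model nests the linear one, so log-likelihoods agree
  expect_equal(fit_lb$params$free_loadings, c(1, 2) / 3, tolerance = 0.05)
  expect_gte(fit_lb$loglik, fit_lin$loglik - 0.05)
  expect_lt(abs(fit_lb$loglik - fit_lin$loglik), 2)
})

test_that("longitudinal CSV round trip preserves the data", {
  sim <- separated_sim(N = 50)
  p <- withr::local_tempfile(fileext = ".csv")
  write_simulated(sim, p)
  y2 <- read_longitudinal(p)
  expect_equal(unname(y2), unname(sim$y), tolerance = 1e-12)
  fitp <- withr::local_tempfile(fileext = ".csv")
  fit <- fit_growth_model(sim$y, paper_spec())
  write_growth_fit(fit, fitp)
  tab <- utils::read.csv(fitp)
  expect_equal(tab$value[tab$parameter == "eta_intercept"],
               fit$params$eta_mean[1])
})
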