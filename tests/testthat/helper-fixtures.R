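# Shared fixtures: all data built in code, fixed seeds per use site.

paper_spec <- function() growth_spec(4)

# The fixed population parameters of the simulation design
paper_params <- function(spec = paper_spec(), eta = c(0.5, 0.3)) {
  growth_params(eta, diag(c(0.25, 0.04)), c(0.15, 0.20, 0.20, 0.35),
                spec = spec)
}

# Noise-free trajectories y = Lambda eta_i for given factor scores
exact_trajectories <- function(eta_mat, spec = paper_spec()) {
  lam <- growth_loadings(spec)
  eta_mat %*% t(lam)
}

# A well-separated two-class dataset (large Mahalanobis distance)
separated_sim <- function(N = 200, md = 5, seed = 42, model = 1) {
  simulate_growth_mixture(
    simulation_design(model = model, K = 2, N = N, md = md), seed = seed)
}

# Adjusted Rand index (independent implementation for label agreement)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_ind <- (sum_a + sum_b) / 2
  if (abs(max_ind - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_ind - expected)
}
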