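#' Describe one cell of the simulation design
#'
#' Fixes the population of a K-class mixture of linear latent growth
#' trajectories. Defaults reproduce the fixed factors of the Monte Carlo
#' design: four measurement occasions, factor covariance
#' `Psi = diag(0.25, 0.04)` with zero intercept-slope covariance,
#' heteroscedastic residual variances `(0.15, 0.20, 0.20, 0.35)`, equal
#' mixing (`N/K` per class), and adjacent-class separation at a Mahalanobis
#' distance of 1 in the growth-factor metric — a deliberately severe
#' low-separation condition.
#'
#' Two trajectory conditions are supported. Model 1
#' (different-intercept-same-slope) places the whole separation budget on
#' the intercept. Model 2 (different-intercept-different-slope) splits the
#' squared-distance budget across intercept and slope with weight
#' `md_split` on the intercept (default one half).
#'
#' @param model 1 (same slope) or 2 (different slope).
#' @param K True number of classes.
#' @param N Total sample size; must be divisible by `K`.
#' @param T Number of occasions (default 4).
#' @param psi Factor covariance matrix (default `diag(0.25, 0.04)`).
#' @param theta Residual variances, length `T` (default
#'   `c(0.15, 0.20, 0.20, 0.35)`).
#' @param md Adjacent-class Mahalanobis distance (default 1).
#' @param md_split Share of the squared separation on the intercept under
#'   Model 2 (default 0.5).
#' @param base_mean Growth-factor means of the first (reference) class;
#'   results are invariant to translation of this choice.
#' @param loading Generating loading convention (default `"linear"`,
#'   slope loadings `0, 1, ..., T-1`).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(model = 1, K = 2, N = 180, T = 4,
                              psi = diag(c(0.25, 0.04)),
                              theta = c(0.15, 0.20, 0.20, 0.35),
                              md = 1, md_split = 0.5,
                              base_mean = c(1.0, 0.3),
                              loading = c("linear", "latent_basis")) {
  loading <- match.arg(loading)
  model <- as.integer(model)
  stopifnot(model %in% c(1L, 2L), K >= 1, N > 0, T >= 3,
            length(theta) == T, md > 0, md_split >= 0, md_split <= 1)
  if (N %% K != 0)
    stop("N must be divisible by K (equal mixing ratio)", call. = FALSE)
  psi <- as.matrix(psi)
  if (min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("psi must be positive definite", call. = FALSE)
  structure(list(model = model, K = as.integer(K), N = as.integer(N),
                 T = as.integer(T), psi = psi, theta = as.numeric(theta),
                 md = md, md_split = md_split,
                 base_mean = as.numeric(base_mean), loading = loading),
            class = "simulation_design")
}

#' Class mean grid with fixed adjacent Mahalanobis separation
#'
#' Places the `K` class means equally spaced along a line in growth-factor
#' space so that each adjacent pair is separated by Mahalanobis distance
#' `md` under the metric `Psi^-1`: `MD^2 = d' Psi^-1 d`. Model 1 uses
#' `d = (sqrt(md^2 * psi_11), 0)`; Model 2 splits `MD^2` with weight
#' `md_split` on the intercept, `d = (sqrt(s * md^2 * psi_11),
#' sqrt((1-s) * md^2 * psi_22))`. Non-adjacent classes are `|k - k'| * md`
#' apart (collinear means).
#'
#' @param design A [simulation_design()].
#' @return `K x 2` matrix of class means (intercept, slope).
#' @examples
#' class_mean_grid(simulation_design(model = 2, K = 3, N = 540))
#' @export
class_mean_grid <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  s <- if (design$model == 1L) 1 else design$md_split
  delta <- c(sqrt(s * design$md^2 * design$psi[1, 1]),
             sqrt((1 - s) * design$md^2 * design$psi[2, 2]))
  means <- t(vapply(seq_len(design$K),
                    function(k) design$base_mean + (k - 1) * delta,
                    numeric(2)))
  colnames(means) <- c("intercept", "slope")
  means
}

#' Simulate a K-class growth mixture dataset
#'
#' Draws, for each individual in class `k`, growth factors
#' `eta_i ~ MVN(mean_k, Psi)` and residuals `e_i ~ MVN(0, diag(theta))`,
#' and sets `y_i = Lambda eta_i + e_i` with the generating loading matrix.
#' Classes have exactly `N/K` members; true labels are returned. Fully
#' reproducible from `seed`.
#'
#' @param design A [simulation_design()].
#' @param seed Integer random seed.
#' @return A list of class `simulated_gmm`: `y` (`N x T`), `labels`
#'   (true classes), `class_means` (`K x 2`), `design`, `seed`.
#' @export
simulate_growth_mixture <- function(design, seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(as.integer(seed))
  n <- design$N
  t_ <- design$T
  k_ <- design$K
  spec <- growth_spec(t_, loading = design$loading)
  free <- if (design$loading == "latent_basis")
    seq(0, 1, length.out = t_)[2:(t_ - 1L)] else numeric(0)
  lam <- growth_loadings(spec, free)
  means <- class_mean_grid(design)
  labels <- rep(seq_len(k_), each = n / k_)
  l_psi <- t(chol(design$psi))
  eta <- means[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * 2), n, 2) %*% t(l_psi)
  e <- matrix(stats::rnorm(n * t_), n, t_) %*% diag(sqrt(design$theta))
  y <- eta %*% t(lam) + e
  colnames(y) <- paste0("y", seq_len(t_))
  rownames(y) <- seq_len(n)
  structure(list(y = y, labels = labels, class_means = means,
                 design = design, seed = as.integer(seed)),
            class = "simulated_gmm")
}

#' Write a simulated dataset to CSV
#'
#' @param sim A [simulate_growth_mixture()] result.
#' @param path CSV path for the data (`id, y1, ..., yT`).
#' @param labels_path Optional CSV path for the true labels (`id, class`).
#' @return `path`, invisibly.
#' @export
write_simulated <- function(sim, path, labels_path = NULL) {
  stopifnot(inherits(sim, "simulated_gmm"))
  df <- data.frame(id = rownames(sim$y), sim$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labels_path))
    utils::write.csv(data.frame(id = rownames(sim$y), class = sim$labels),
                     labels_path, row.names = FALSE)
  invisible(path)
}
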