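#' Normal-theory ML discrepancy for a mean-and-covariance structure
#'
#' The maximum-likelihood fit function for a structured mean vector and
#' covariance matrix against the sample moments:
#' `F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - T + (ybar - mu)' Sigma^-1 (ybar - mu)`.
#' `F >= 0` with equality exactly at the saturated solution `S = Sigma`,
#' `ybar = mu`. Minimizing `F` is equivalent to maximizing the multivariate
#' normal likelihood of the data.
#'
#' @param sample_mean Sample mean vector (length `T`).
#' @param sample_cov Sample covariance matrix (`T x T`, ML divisor `n`).
#' @param mu Model-implied mean vector.
#' @param sigma Model-implied covariance matrix (positive definite).
#' @return The scalar discrepancy `F`.
#' @export
ml_discrepancy <- function(sample_mean, sample_cov, mu, sigma) {
  t_ <- length(sample_mean)
  ch_s <- tryCatch(chol(sample_cov), error = function(e) NULL)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch_s) || is.null(ch))
    stop("singular or non-positive-definite covariance matrix in ML discrepancy",
         call. = FALSE)
  sigma_inv <- chol2inv(ch)
  d <- sample_mean - mu
  f <- 2 * sum(log(diag(ch))) - 2 * sum(log(diag(ch_s))) +
    sum(sigma_inv * sample_cov) - t_ + drop(crossprod(d, sigma_inv %*% d))
  max(f, 0)
}

## --- internal parameter packing -------------------------------------------
## optimizer vector layout:
##   eta (2) | log l11, l21, log l22 (Cholesky of Psi) | log theta (T or 1)
##   | free basis loadings (T-2, latent basis only)

.pack_params <- function(params, spec) {
  l <- tryCatch(t(chol(params$psi + diag(1e-10, 2))), error = function(e) NULL)
  if (is.null(l)) {
    d <- pmax(diag(params$psi), 1e-6)
    l <- diag(sqrt(d))
  }
  th <- if (spec$residual == "homoscedastic") params$theta[1] else params$theta
  c(params$eta_mean, log(max(l[1, 1], 1e-8)), l[2, 1],
    log(max(l[2, 2], 1e-8)), log(th), params$free_loadings)
}

.unpack_params <- function(x, spec) {
  t_ <- spec$n_occasions
  eta <- x[1:2]
  l <- matrix(c(exp(x[3]), x[4], 0, exp(x[5])), 2, 2)
  psi <- l %*% t(l)
  i <- 5L
  if (spec$residual == "homoscedastic") {
    theta <- rep(exp(x[i + 1L]), t_); i <- i + 1L
  } else {
    theta <- exp(x[i + seq_len(t_)]); i <- i + t_
  }
  free <- if (spec$loading == "latent_basis") x[i + seq_len(t_ - 2L)] else numeric(0)
  list(eta_mean = eta, psi = psi, theta = theta, free_loadings = free, l = l)
}

.fml_objective <- function(x, spec, ybar, s_cov, logdet_s) {
  p <- .unpack_params(x, spec)
  lam <- growth_loadings(spec, p$free_loadings)
  sigma <- lam %*% p$psi %*% t(lam) + diag(p$theta)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  sigma_inv <- chol2inv(ch)
  d <- ybar - drop(lam %*% p$eta_mean)
  2 * sum(log(diag(ch))) - logdet_s + sum(sigma_inv * s_cov) -
    spec$n_occasions + drop(crossprod(d, sigma_inv %*% d))
}

## analytic gradient of .fml_objective in the packed parameterization
.fml_gradient <- function(x, spec, ybar, s_cov, logdet_s) {
  p <- .unpack_params(x, spec)
  lam <- growth_loadings(spec, p$free_loadings)
  sigma <- lam %*% p$psi %*% t(lam) + diag(p$theta)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(x)))
  sigma_inv <- chol2inv(ch)
  d <- ybar - drop(lam %*% p$eta_mean)
  sid <- drop(sigma_inv %*% d)
  ## dF = tr(G dSigma) - 2 d' Sigma^-1 dmu, G below
  g_mat <- sigma_inv - sigma_inv %*% (s_cov + tcrossprod(d)) %*% sigma_inv
  grad_eta <- -2 * drop(crossprod(lam, sid))
  m <- 2 * crossprod(lam, g_mat %*% lam) %*% p$l     # d/dL of tr(G Lam Psi Lam')
  grad_l <- c(m[1, 1] * p$l[1, 1], m[2, 1], m[2, 2] * p$l[2, 2])
  gdiag <- diag(g_mat)
  grad_th <- if (spec$residual == "homoscedastic")
    sum(gdiag) * p$theta[1] else gdiag * p$theta
  out <- c(grad_eta, grad_l, grad_th)
  if (spec$loading == "latent_basis") {
    glp <- 2 * (g_mat %*% lam %*% p$psi)[, 2] - 2 * sid * p$eta_mean[2]
    out <- c(out, glp[2:(spec$n_occasions - 1L)])
  }
  out
}

#' Deterministic starting values for a growth model fit
#'
#' Per-person ordinary least squares on the loading matrix provides the
#' factor means (mean of the per-person estimates), the factor covariance
#' (their sample covariance), and residual variances (mean squared OLS
#' residual per occasion). Latent-basis free loadings start at an equally
#' spaced grid on (0, 1).
#'
#' @param y `N x T` data matrix.
#' @param spec A [growth_spec()].
#' @return A [growth_params()] set.
#' @keywords internal
starting_values <- function(y, spec) {
  t_ <- spec$n_occasions
  free0 <- if (spec$loading == "latent_basis")
    seq(0, 1, length.out = t_)[2:(t_ - 1L)] else numeric(0)
  lam <- growth_loadings(spec, free0)
  xtx_inv <- solve(crossprod(lam))
  beta <- y %*% lam %*% xtx_inv            # N x 2 per-person OLS estimates
  eta <- colMeans(beta)
  psi <- stats::cov(beta)
  ## keep the start admissible: shrink covariance if needed, floor variances
  diag(psi) <- pmax(diag(psi), 0.01)
  r <- psi[1, 2] / sqrt(psi[1, 1] * psi[2, 2])
  if (abs(r) > 0.95) psi[1, 2] <- psi[2, 1] <- sign(r) * 0.95 *
      sqrt(psi[1, 1] * psi[2, 2])
  resid <- y - beta %*% t(lam)
  theta <- pmax(colMeans(resid^2), 1e-3)
  if (spec$residual == "homoscedastic") theta <- rep(mean(theta), t_)
  growth_params(eta, psi, theta, free0, spec)
}

#' Fit a latent growth curve model by maximum likelihood
#'
#' Fits the two-factor growth model to the sample mean vector and
#' covariance matrix of `y` by minimizing the normal-theory
#' [ml_discrepancy()] with a quasi-Newton (BFGS) optimizer and analytic
#' gradients. Variances are optimized on the log scale and the factor
#' covariance through its Cholesky factor, so estimates are admissible by
#' construction.
#'
#' @param y `N x T` numeric matrix of repeated measures (one row per
#'   individual, no missing values), or a data frame coercible to one.
#' @param spec A [growth_spec()].
#' @param start Optional [growth_params()] starting values; by default
#'   [starting_values()] is used.
#' @param control List: `maxit` (default 500) and `reltol` (default 1e-10)
#'   passed to [stats::optim()].
#' @return An object of class `fitted_growth_model`: `spec`, `params`,
#'   `loglik`, `discrepancy`, `converged`, `n_obs`, `implied_mu`,
#'   `implied_sigma`, `sample_mean`, `sample_cov`, `n_iter`.
#' @examples
#' sp <- growth_spec(4)
#' sim <- simulate_growth_mixture(simulation_design(model = 1, K = 2, N = 180),
#'                                seed = 1)
#' fit <- fit_growth_model(sim$y, sp)
#' fit$params$eta_mean
#' @export
fit_growth_model <- function(y, spec, start = NULL, control = list()) {
  stopifnot(inherits(spec, "growth_spec"))
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (anyNA(y)) stop("missing values are not supported", call. = FALSE)
  t_ <- spec$n_occasions
  if (ncol(y) != t_)
    stop(sprintf("data have %d columns but spec has %d occasions",
                 ncol(y), t_), call. = FALSE)
  n <- nrow(y)
  if (n <= n_free_params(spec))
    stop("more free parameters than observations", call. = FALSE)
  maxit <- if (is.null(control$maxit)) 500L else control$maxit
  reltol <- if (is.null(control$reltol)) 1e-10 else control$reltol

  ybar <- colMeans(y)
  s_cov <- crossprod(sweep(y, 2, ybar)) / n      # ML divisor n
  ch_s <- tryCatch(chol(s_cov), error = function(e) NULL)
  if (is.null(ch_s)) {
    ## rank-deficient sample covariance (e.g. exactly noise-free
    ## trajectories): regularize minimally so the fit limit is defined
    ridge <- 1e-8 * mean(diag(s_cov))
    while (is.null(ch_s) && ridge < mean(diag(s_cov))) {
      ch_s <- tryCatch(chol(s_cov + diag(ridge, t_)), error = function(e) NULL)
      ridge <- ridge * 10
    }
    if (is.null(ch_s))
      stop("sample covariance matrix is singular", call. = FALSE)
    s_cov <- s_cov + diag(ridge / 10, t_)
  }
  logdet_s <- 2 * sum(log(diag(ch_s)))

  if (is.null(start)) start <- starting_values(y, spec)
  x0 <- .pack_params(start, spec)
  opt <- stats::optim(x0, .fml_objective, .fml_gradient, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol),
                      spec = spec, ybar = ybar, s_cov = s_cov,
                      logdet_s = logdet_s)
  p <- .unpack_params(opt$par, spec)
  params <- growth_params(p$eta_mean, p$psi, p$theta, p$free_loadings, spec)
  mom <- implied_moments(params, spec)
  f <- max(opt$value, 0)
  loglik <- -(n / 2) * (f + logdet_s + t_ + t_ * log(2 * pi))
  structure(
    list(spec = spec, params = params, loglik = loglik, discrepancy = f,
         converged = (opt$convergence == 0L), n_obs = n,
         implied_mu = mom$mu, implied_sigma = mom$sigma,
         sample_mean = ybar, sample_cov = s_cov,
         n_iter = opt$counts[["function"]]),
    class = "fitted_growth_model"
  )
}

#' @export
print.fitted_growth_model <- function(x, ...) {
  cat("Fitted latent growth curve model (", x$spec$loading, ", T = ",
      x$spec$n_occasions, ", N = ", x$n_obs, ")\n", sep = "")
  cat(sprintf("  logLik %.3f   discrepancy F = %.6g   converged: %s\n",
              x$loglik, x$discrepancy, x$converged))
  cat(sprintf("  eta: intercept %.4f  slope %.4f\n",
              x$params$eta_mean[1], x$params$eta_mean[2]))
  cat(sprintf("  psi: var(i) %.4f  var(s) %.4f  cov %.4f\n",
              x$params$psi[1, 1], x$params$psi[2, 2], x$params$psi[1, 2]))
  cat("  theta:", paste(sprintf("%.4f", x$params$theta), collapse = " "), "\n")
  if (length(x$params$free_loadings))
    cat("  basis:", paste(sprintf("%.4f", x$params$free_loadings),
                          collapse = " "), "\n")
  invisible(x)
}

#' Read wide-format longitudinal data from CSV
#'
#' Expects a header `id,y1,...,yT`; returns the `N x T` data matrix with
#' the ids as row names.
#'
#' @param path Path to a CSV file.
#' @return Numeric matrix with one row per individual.
#' @export
read_longitudinal <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"id" %in% names(df))
    stop("expected an 'id' column", call. = FALSE)
  y <- as.matrix(df[setdiff(names(df), "id")])
  storage.mode(y) <- "double"
  if (anyNA(y)) stop("missing values are not supported", call. = FALSE)
  rownames(y) <- as.character(df$id)
  y
}

#' Write fitted growth-model parameters
#'
#' Writes a flat key-value CSV of the parameter estimates, and optionally a
#' structured JSON report.
#'
#' @param fit A [fit_growth_model()] result.
#' @param path Output CSV path.
#' @param json_path Optional JSON report path (requires jsonlite).
#' @return The path, invisibly.
#' @export
write_growth_fit <- function(fit, path, json_path = NULL) {
  stopifnot(inherits(fit, "fitted_growth_model"))
  p <- fit$params
  kv <- c(eta_intercept = p$eta_mean[1], eta_slope = p$eta_mean[2],
          psi_intercept = p$psi[1, 1], psi_slope = p$psi[2, 2],
          psi_cov = p$psi[1, 2],
          stats::setNames(p$theta, paste0("theta_", seq_along(p$theta))),
          loglik = fit$loglik, discrepancy = fit$discrepancy,
          converged = as.numeric(fit$converged), n_obs = fit$n_obs)
  if (length(p$free_loadings))
    kv <- c(kv, stats::setNames(p$free_loadings,
                                paste0("basis_", seq_along(p$free_loadings) + 1L)))
  utils::write.csv(data.frame(parameter = names(kv), value = unname(kv)),
                   path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output", call. = FALSE)
    jsonlite::write_json(
      list(spec = list(n_occasions = fit$spec$n_occasions,
                       loading = fit$spec$loading,
                       residual = fit$spec$residual),
           estimates = as.list(kv),
           implied_mu = fit$implied_mu,
           implied_sigma = fit$implied_sigma),
      json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}
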