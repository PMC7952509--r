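#' Specify a latent growth curve model
#'
#' A growth model specification fixes the number of measurement occasions,
#' the loading convention for the slope (shape) factor, and the residual
#' variance structure. All models carry two growth factors: a latent
#' intercept (level) and a latent slope (shape).
#'
#' Two loading conventions are supported. `"linear"` fixes the slope
#' loadings at `0, 1, ..., T-1`, so the intercept is the status at the first
#' occasion and the slope is the constant change per occasion. The
#' `"latent_basis"` (level-and-shape) convention fixes the first slope
#' loading at 0 and the last at 1 and estimates the `T - 2` intermediate
#' loadings freely, so the slope factor is total change between first and
#' last occasion and the free loadings describe the shape of that change.
#'
#' @param n_occasions Integer number of repeated measures `T`, at least 3
#'   (a two-factor model with free basis loadings is not identified below
#'   that).
#' @param loading Either `"linear"` or `"latent_basis"`.
#' @param residual Either `"occasion_specific"` (a free residual variance at
#'   every occasion, the default) or `"homoscedastic"` (one shared residual
#'   variance).
#' @return An object of class `growth_spec`.
#' @seealso [growth_loadings()], [fit_growth_model()]
#' @examples
#' growth_spec(4)
#' growth_spec(5, loading = "latent_basis", residual = "homoscedastic")
#' @export
growth_spec <- function(n_occasions,
                        loading = c("linear", "latent_basis"),
                        residual = c("occasion_specific", "homoscedastic")) {
  loading <- match.arg(loading)
  residual <- match.arg(residual)
  n_occasions <- as.integer(n_occasions)
  if (length(n_occasions) != 1L || is.na(n_occasions) || n_occasions < 3L)
    stop("'n_occasions' must be a single integer >= 3", call. = FALSE)
  structure(
    list(n_occasions = n_occasions, loading = loading, residual = residual,
         n_factors = 2L),
    class = "growth_spec"
  )
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Latent growth curve specification\n")
  cat("  occasions:", x$n_occasions,
      " loading:", x$loading,
      " residuals:", x$residual, "\n")
  invisible(x)
}

#' Number of free parameters of a growth model
#'
#' Counts the free parameters of a specification: 2 factor means, 3 entries
#' of the factor covariance matrix, the residual variances (`T` or 1), and
#' `T - 2` basis loadings for the latent-basis convention.
#'
#' @param spec A [growth_spec()].
#' @return Integer count.
#' @export
n_free_params <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  t_ <- spec$n_occasions
  2L + 3L +
    (if (spec$residual == "occasion_specific") t_ else 1L) +
    (if (spec$loading == "latent_basis") t_ - 2L else 0L)
}

#' Build the factor loading matrix
#'
#' Returns the `T x 2` loading matrix Lambda of a growth model. The first
#' column (intercept) is all ones. The second column (slope) is
#' `0, 1, ..., T-1` for the linear convention, or
#' `0, b_2, ..., b_{T-1}, 1` for the latent-basis convention with the
#' intermediate loadings supplied in `free`.
#'
#' @param spec A [growth_spec()].
#' @param free Numeric vector of free basis loadings; length `T - 2` for
#'   `"latent_basis"`, length 0 for `"linear"`.
#' @return A `T x 2` numeric matrix.
#' @examples
#' growth_loadings(growth_spec(4))
#' growth_loadings(growth_spec(4, "latent_basis"), free = c(0.4, 0.7))
#' @export
growth_loadings <- function(spec, free = numeric(0)) {
  stopifnot(inherits(spec, "growth_spec"))
  t_ <- spec$n_occasions
  if (spec$loading == "linear") {
    if (length(free) != 0L)
      stop("linear loadings take no free coefficients", call. = FALSE)
    slope <- seq_len(t_) - 1
  } else {
    if (length(free) != t_ - 2L)
      stop(sprintf("latent-basis loadings need %d free coefficients, got %d",
                   t_ - 2L, length(free)), call. = FALSE)
    slope <- c(0, free, 1)
  }
  cbind(intercept = rep(1, t_), slope = slope)
}

#' Construct a growth parameter set
#'
#' Bundles the free parameters of a latent growth curve model: the factor
#' means, the factor covariance matrix Psi, the diagonal of the residual
#' covariance Theta, and (for latent-basis models) the free slope loadings.
#'
#' @param eta_mean Length-2 numeric: mean intercept and mean slope.
#' @param psi 2 x 2 symmetric positive-semidefinite factor covariance.
#' @param theta Residual variances: length `T` vector, or a single value for
#'   a homoscedastic model (recycled to length `T`).
#' @param free_loadings Free basis loadings (empty for linear models).
#' @param spec A [growth_spec()] used to validate dimensions.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(eta_mean, psi, theta, free_loadings = numeric(0),
                          spec) {
  stopifnot(inherits(spec, "growth_spec"))
  t_ <- spec$n_occasions
  eta_mean <- as.numeric(eta_mean)
  if (length(eta_mean) != 2L) stop("'eta_mean' must have length 2", call. = FALSE)
  psi <- as.matrix(psi)
  if (!all(dim(psi) == c(2L, 2L)) || max(abs(psi - t(psi))) > 1e-8)
    stop("'psi' must be a symmetric 2 x 2 matrix", call. = FALSE)
  psi <- (psi + t(psi)) / 2
  if (any(diag(psi) < 0))
    stop("'psi' variances must be non-negative", call. = FALSE)
  if (all(diag(psi) > 0) &&
      abs(psi[1, 2]) > sqrt(psi[1, 1] * psi[2, 2]) + 1e-8)
    stop("'psi' implies a factor correlation outside [-1, 1]", call. = FALSE)
  theta <- as.numeric(theta)
  if (length(theta) == 1L) theta <- rep(theta, t_)
  if (length(theta) != t_)
    stop(sprintf("'theta' must have length %d (or 1)", t_), call. = FALSE)
  if (any(theta <= 0)) stop("'theta' entries must be positive", call. = FALSE)
  if (spec$residual == "homoscedastic" && diff(range(theta)) > 1e-12)
    stop("homoscedastic spec requires equal residual variances", call. = FALSE)
  growth_loadings(spec, free_loadings)  # validates length
  structure(
    list(eta_mean = eta_mean, psi = psi, theta = theta,
         free_loadings = as.numeric(free_loadings)),
    class = "growth_params"
  )
}

#' Model-implied mean vector and covariance matrix
#'
#' Evaluates the moment structure of the latent growth curve model:
#' `mu = Lambda eta` and `Sigma = Lambda Psi Lambda' + Theta`.
#'
#' @param params A [growth_params()] set.
#' @param spec The matching [growth_spec()].
#' @return A list with components `mu` (length `T`) and `sigma` (`T x T`).
#' @examples
#' sp <- growth_spec(4)
#' pars <- growth_params(c(0.5, 0.3), diag(c(0.25, 0.04)),
#'                       c(0.15, 0.20, 0.20, 0.35), spec = sp)
#' implied_moments(pars, sp)
#' @export
implied_moments <- function(params, spec) {
  stopifnot(inherits(params, "growth_params"), inherits(spec, "growth_spec"))
  lam <- growth_loadings(spec, params$free_loadings)
  mu <- drop(lam %*% params$eta_mean)
  sigma <- lam %*% params$psi %*% t(lam) + diag(params$theta)
  sigma <- (sigma + t(sigma)) / 2
  list(mu = mu, sigma = sigma)
}
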