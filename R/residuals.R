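#' Bartlett factor scores
#'
#' Conditionally unbiased factor-score estimates under a fitted growth
#' model: `eta_hat_i = eta_bar + (Lambda' Theta^-1 Lambda)^-1 Lambda'
#' Theta^-1 (y_i - mu)`. Because the weight matrix satisfies
#' `W Lambda = I`, the scores reproduce each individual's true factor
#' values plus a zero-mean error that does not depend on the class means.
#'
#' @param fit A [fit_growth_model()] result (converged, invertible Theta).
#' @param y `N x T` data matrix of individuals to score (defaults would be
#'   the data the model was fitted to, but any individuals measured on the
#'   same occasions can be scored).
#' @return `N x 2` matrix of scores (columns: intercept, slope).
#' @examples
#' sp <- growth_spec(4)
#' sim <- simulate_growth_mixture(simulation_design(model = 1, K = 2, N = 180),
#'                                seed = 1)
#' fit <- fit_growth_model(sim$y, sp)
#' head(bartlett_scores(fit, sim$y))
#' @export
bartlett_scores <- function(fit, y) {
  stopifnot(inherits(fit, "fitted_growth_model"))
  y <- as.matrix(y)
  p <- fit$params
  lam <- growth_loadings(fit$spec, p$free_loadings)
  lt <- t(lam) / rep(p$theta, each = 2L)       # Lambda' Theta^-1
  a <- lt %*% lam
  w <- tryCatch(solve(a, lt), error = function(e)
    stop("degenerate loading matrix: Lambda' Theta^-1 Lambda is singular",
         call. = FALSE))
  scores <- sweep(y, 2, fit$implied_mu) %*% t(w)
  scores <- sweep(scores, 2, p$eta_mean, `+`)
  colnames(scores) <- c("intercept", "slope")
  scores
}

#' Residual bundle: scores, per-factor case residuals, communalities
#'
#' Computes, for one class's local growth model, everything the closeness
#' measure needs: Bartlett factor scores for all `N` individuals, the
#' per-factor individual case residuals (ICRs), and the per-(occasion,
#' factor) communalities.
#'
#' The per-factor ICR of individual `i` at occasion `t` for factor `j` is
#' the residual of `y_t` from the least-squares regression of `y_t` on the
#' factor score `eta_hat_j`, with the regression line fitted on the class
#' members only; outsiders are evaluated against that same line. The
#' communality `com[t, j]` is the squared Pearson correlation between
#' `y_t` and `eta_hat_j` over the class members.
#'
#' With `method = "full_model"` the per-factor decomposition is replaced by
#' the whole-model residual `y_i - Lambda eta_hat_i`, identical for every
#' factor.
#'
#' @param fit Local model fitted to the class members.
#' @param y `N x T` data matrix for all individuals to evaluate.
#' @param members Integer (or logical) index of the rows of `y` that belong
#'   to this class; at least 3 individuals.
#' @param class_id Integer identifier carried in the result.
#' @param method `"per_factor"` (default) or `"full_model"`.
#' @param com_mode How the communality normalizer is formed:
#'   `"factor_mean"` (default) averages the squared correlations over the
#'   `T` occasions within each factor, giving one bounded-away-from-zero
#'   weight per factor; `"per_occasion"` keeps a separate `com[t, j]` per
#'   cell, which can be numerically degenerate when an occasion is nearly
#'   uncorrelated with a factor score (e.g. the first occasion and the
#'   slope factor, whose loading there is 0).
#' @return An object of class `residual_bundle`: `scores` (`N x 2`), `icr`
#'   (`N x T x 2` array), `communality` (`T x 2`), `members`, `class_id`.
#' @export
residual_bundle <- function(fit, y, members = seq_len(nrow(y)),
                            class_id = 1L,
                            method = c("per_factor", "full_model"),
                            com_mode = c("factor_mean", "per_occasion")) {
  method <- match.arg(method)
  com_mode <- match.arg(com_mode)
  y <- as.matrix(y)
  n <- nrow(y)
  t_ <- ncol(y)
  if (is.logical(members)) members <- which(members)
  if (length(members) < 3L)
    stop("a class needs at least 3 members", call. = FALSE)
  scores <- bartlett_scores(fit, y)
  j_ <- ncol(scores)
  ym <- y[members, , drop = FALSE]
  icr <- array(NA_real_, dim = c(n, t_, j_))
  com <- matrix(NA_real_, t_, j_)
  ycm <- colMeans(ym)
  yc <- sweep(ym, 2, ycm)
  ssy <- colSums(yc^2)
  if (any(ssy < 1e-12))
    stop("degenerate class: an occasion has zero variance", call. = FALSE)
  for (j in seq_len(j_)) {
    if (method == "per_factor") {
      xm <- scores[members, j]
      mx <- mean(xm)
      xc <- xm - mx
      sxx <- sum(xc^2)
      if (sxx < 1e-12)
        stop("degenerate class: factor score has zero variance", call. = FALSE)
      b <- drop(crossprod(xc, yc)) / sxx          # slopes, one per occasion
      a <- ycm - b * mx
      fitted <- outer(scores[, j], b) + rep(a, each = n)
      icr[, , j] <- y - fitted
      com[, j] <- b^2 * sxx / ssy                 # = cor(y_t, eta_hat_j)^2
    } else {
      lam <- growth_loadings(fit$spec, fit$params$free_loadings)
      resid <- y - scores %*% t(lam)
      icr[, , j] <- resid
      for (t in seq_len(t_)) com[t, j] <- stats::cor(ym[, t], scores[members, j])^2
    }
  }
  if (com_mode == "factor_mean")
    com <- matrix(colMeans(com), t_, j_, byrow = TRUE)
  structure(list(scores = scores, icr = icr, communality = com,
                 members = members, class_id = as.integer(class_id)),
            class = "residual_bundle")
}

#' Communalities of observed variables with factor scores
#'
#' Squared Pearson correlation between each observed occasion and each
#' estimated factor score, computed over one class's individuals.
#'
#' @param scores `N x J` factor score matrix.
#' @param y `N x T` data matrix for the same individuals.
#' @return `T x J` matrix with entries in `[0, 1]`.
#' @export
communalities <- function(scores, y) {
  y <- as.matrix(y)
  scores <- as.matrix(scores)
  if (nrow(y) < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (any(apply(y, 2, stats::sd) < 1e-12) ||
      any(apply(scores, 2, stats::sd) < 1e-12))
    stop("zero variance in data or scores", call. = FALSE)
  stats::cor(y, scores)^2
}

#' Export a residual bundle to long-format CSV
#'
#' One row per (individual, occasion, factor) with the ICR value.
#'
#' @param bundle A [residual_bundle()].
#' @param path Output CSV path.
#' @param ids Optional individual identifiers (default row index).
#' @return The path, invisibly.
#' @export
write_residuals <- function(bundle, path, ids = NULL) {
  stopifnot(inherits(bundle, "residual_bundle"))
  d <- dim(bundle$icr)
  if (is.null(ids)) ids <- seq_len(d[1])
  out <- data.frame(
    id = rep(ids, times = d[2] * d[3]),
    occasion = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    factor = rep(c("intercept", "slope")[seq_len(d[3])], each = d[1] * d[2]),
    residual = as.vector(bundle$icr)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
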