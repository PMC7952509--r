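#' Control settings for residual-based class enumeration
#'
#' @param delta Relative drop in mean within-class raw closeness required to
#'   accept a larger number of classes (default 0.33; calibrated so that the
#'   sequential rule retains the algorithm's characteristic conservatism —
#'   essentially never extracting more classes than the data support — see
#'   the package vignette).
#' @param min_class_size Minimum admissible class size; by default
#'   `max(10, 2 * n_free_params(spec))`, resolved when the spec is known.
#' @param max_iter Maximum reassignment iterations (default 50).
#' @param stop_frac Stopping threshold on the fraction of individuals that
#'   change class between iterations; iteration stops when the fraction is
#'   strictly below this value (default 0.05).
#' @param icr_method Passed to [residual_bundle()]: `"per_factor"` or
#'   `"full_model"`.
#' @param com_mode Communality normalization mode passed to
#'   [residual_bundle()]: `"factor_mean"` (default) or `"per_occasion"`.
#' @return A list of class `enum_control`.
#' @export
enum_control <- function(delta = 0.33, min_class_size = NULL, max_iter = 50L,
                         stop_frac = 0.05,
                         icr_method = c("per_factor", "full_model"),
                         com_mode = c("factor_mean", "per_occasion")) {
  structure(list(delta = delta, min_class_size = min_class_size,
                 max_iter = as.integer(max_iter), stop_frac = stop_frac,
                 icr_method = match.arg(icr_method),
                 com_mode = match.arg(com_mode)),
            class = "enum_control")
}

.resolve_min_size <- function(control, spec) {
  if (!is.null(control$min_class_size)) return(control$min_class_size)
  max(10L, 2L * n_free_params(spec))
}

#' Closeness of every individual to every class
#'
#' For each class `k`, the raw closeness of individual `i` is the
#' communality-weighted sum of squared per-factor case residuals,
#' `A_ik = sum_j sum_t icr_itjk^2 / com_k[t, j]`. The closeness measure
#' normalizes by the column mean scaled by `N - 2`:
#' `CM_ik = A_ik / (sum_i A_ik / (N - 2))`, so each column of the `CM`
#' matrix sums to `N - 2` exactly.
#'
#' @param bundles List of `K` [residual_bundle()] objects, each evaluated
#'   for all `N` individuals against one class's local model.
#' @return A list of class `closeness_matrix`: `cm` and `raw` (`N x K`
#'   matrices), `class_sizes`.
#' @export
closeness_measure <- function(bundles) {
  if (!length(bundles)) stop("need at least one residual bundle", call. = FALSE)
  n <- nrow(bundles[[1]]$scores)
  if (n <= 2L) stop("closeness measure needs N > 2", call. = FALSE)
  k_ <- length(bundles)
  raw <- matrix(NA_real_, n, k_)
  for (k in seq_len(k_)) {
    b <- bundles[[k]]
    com <- b$communality
    if (any(!is.finite(com)) || any(com < 1e-10))
      stop("degenerate class: zero communality", call. = FALSE)
    a <- 0
    for (j in seq_len(dim(b$icr)[3])) {
      e2 <- b$icr[, , j, drop = FALSE]
      dim(e2) <- dim(b$icr)[1:2]
      a <- a + e2^2 %*% (1 / com[, j])
    }
    raw[, k] <- a
  }
  cm <- sweep(raw, 2, colSums(raw) / (n - 2), `/`)
  structure(list(cm = cm, raw = raw,
                 class_sizes = vapply(bundles, function(b) length(b$members),
                                      integer(1))),
            class = "closeness_matrix")
}

#' Assign individuals to their closest class
#'
#' Row-wise argmin of the closeness matrix; ties break toward the lowest
#' class index.
#'
#' @param cm A [closeness_measure()] result or a bare `N x K` matrix.
#' @return Integer vector of class labels in `1..K`.
#' @export
assign_classes <- function(cm) {
  m <- if (inherits(cm, "closeness_matrix")) cm$cm else as.matrix(cm)
  if (any(!is.finite(m))) stop("non-finite closeness values", call. = FALSE)
  max.col(-m, ties.method = "first")
}

## Dissolve classes smaller than min_size, reassigning members to their
## next-best class by CM. Returns new labels (renumbered 1..K') and the map
## of surviving original class indices.
.repair_small_classes <- function(labels, cm_mat, min_size) {
  k_ <- ncol(cm_mat)
  alive <- rep(TRUE, k_)
  repeat {
    sizes <- tabulate(labels, nbins = k_)
    bad <- which(alive & sizes < min_size)
    if (!length(bad)) break
    drop_k <- bad[which.min(sizes[bad])]
    alive[drop_k] <- FALSE
    if (sum(alive) == 0L) break
    m <- cm_mat
    m[, !alive] <- Inf
    movers <- labels == drop_k
    labels[movers] <- max.col(-m[movers, , drop = FALSE], ties.method = "first")
  }
  keep <- which(alive)
  list(labels = match(labels, keep), keep = keep)
}

#' Iterative residual-based class reassignment
#'
#' Alternates (i) fitting a local growth model to each current class,
#' (ii) scoring every individual against every local model and forming the
#' residual bundles, (iii) computing the closeness matrix, and (iv)
#' reassigning every individual to the class with its smallest closeness
#' value, until strictly fewer than `stop_frac` (default 5%) of individuals
#' change class from one iteration to the next or `max_iter` is reached.
#' Final local models are re-fitted on the final labels.
#'
#' Classes that fall below the minimum admissible size are dissolved and
#' their members reassigned to the next-best class; the returned partition
#' then has fewer classes than requested and is flagged `degenerate`.
#'
#' @param y `N x T` data matrix.
#' @param spec A [growth_spec()].
#' @param labels Initial class labels (`K >= 2` non-empty classes).
#' @param control An [enum_control()].
#' @return An object of class `gmm_partition`: `labels`, `models` (list of
#'   local fits), `bundles`, `cm` ([closeness_measure()] under the final
#'   models), `n_iterations`, `converged`, `history` (fraction changed per
#'   iteration), `K`, `K_init`, `degenerate`.
#' @export
refine_partition <- function(y, spec, labels, control = enum_control()) {
  y <- as.matrix(y)
  n <- nrow(y)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  min_size <- .resolve_min_size(control, spec)
  k_init <- max(labels)
  if (any(tabulate(labels, k_init) == 0L))
    stop("initial labels contain an empty class", call. = FALSE)
  fits <- vector("list", k_init)
  history <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    k_ <- max(labels)
    if (k_ < 2L) break
    bundles <- vector("list", k_)
    ok <- TRUE
    for (k in seq_len(k_)) {
      members <- which(labels == k)
      fits[[k]] <- tryCatch(
        fit_growth_model(y[members, , drop = FALSE], spec,
                         start = if (!is.null(fits[[k]])) fits[[k]]$params),
        error = function(e) NULL)
      if (is.null(fits[[k]])) { ok <- FALSE; break }
      bundles[[k]] <- tryCatch(
        residual_bundle(fits[[k]], y, members, class_id = k,
                        method = control$icr_method,
                        com_mode = control$com_mode),
        error = function(e) NULL)
      if (is.null(bundles[[k]])) { ok <- FALSE; break }
    }
    if (!ok) break
    cmx <- tryCatch(closeness_measure(bundles), error = function(e) NULL)
    if (is.null(cmx)) break
    new_labels <- assign_classes(cmx)
    rep_ <- .repair_small_classes(new_labels, cmx$cm, min_size)
    if (length(rep_$keep) < ncol(cmx$cm)) {
      ## classes were dissolved: renumber and keep iterating with fewer
      labels <- rep_$labels
      fits <- fits[rep_$keep]
      history <- c(history, 1)        # structural change, not converged yet
      next
    }
    frac <- mean(new_labels != labels)
    labels <- new_labels
    history <- c(history, frac)
    if (frac < control$stop_frac) { converged <- TRUE; break }
  }
  k_ <- max(labels)
  ## final refit on the final labels
  bundles <- vector("list", k_)
  fits <- if (length(fits) == k_) fits else vector("list", k_)
  for (k in seq_len(k_)) {
    members <- which(labels == k)
    fits[[k]] <- fit_growth_model(y[members, , drop = FALSE], spec,
                                  start = if (!is.null(fits[[k]])) fits[[k]]$params)
    bundles[[k]] <- residual_bundle(fits[[k]], y, members, class_id = k,
                                    method = control$icr_method,
                                    com_mode = control$com_mode)
  }
  cmx <- closeness_measure(bundles)
  structure(list(labels = labels, models = fits, bundles = bundles, cm = cmx,
                 n_iterations = it, converged = converged, history = history,
                 K = k_, K_init = k_init, degenerate = (k_ < k_init)),
            class = "gmm_partition")
}

#' @export
print.gmm_partition <- function(x, ...) {
  cat("Residual-based partition: K =", x$K,
      if (x$degenerate) sprintf("(degenerate, started at %d)", x$K_init) else "",
      "\n")
  cat("  sizes:", paste(tabulate(x$labels, x$K), collapse = " "), "\n")
  cat(sprintf("  iterations: %d  converged: %s\n", x$n_iterations, x$converged))
  invisible(x)
}

#' Initial partition from Ward clustering of global-model case residuals
#'
#' Fits the global (one-class) growth model, computes every individual's
#' per-factor case residual profile, and cuts a Ward-linkage hierarchical
#' clustering of those profiles at `K` clusters. Deterministic given the
#' data.
#'
#' @param y `N x T` data matrix.
#' @param spec A [growth_spec()].
#' @param K Number of clusters (`K = 1` returns all-ones labels).
#' @param global_fit Optional pre-computed global model fit.
#' @param control An [enum_control()] (for the ICR method).
#' @return Integer labels of length `N`; the hclust tree is attached as
#'   attribute `"hclust"` and the global residual bundle as `"bundle"`.
#' @export
initialize_partition <- function(y, spec, K, global_fit = NULL,
                                 control = enum_control()) {
  y <- as.matrix(y)
  n <- nrow(y)
  K <- as.integer(K)
  min_size <- .resolve_min_size(control, spec)
  if (K > n / min_size)
    stop("K too large for the sample size at this minimum class size",
         call. = FALSE)
  if (is.null(global_fit)) global_fit <- fit_growth_model(y, spec)
  bundle <- residual_bundle(global_fit, y, seq_len(n),
                            method = control$icr_method,
                            com_mode = control$com_mode)
  icr_mat <- matrix(bundle$icr, nrow = n)   # N x (T*J)
  hc <- stats::hclust(stats::dist(icr_mat), method = "ward.D2")
  labels <- if (K == 1L) rep(1L, n) else stats::cutree(hc, k = K)
  attr(labels, "hclust") <- hc
  attr(labels, "bundle") <- bundle
  labels
}

#' Determine the number of latent trajectory classes
#'
#' Runs the full residual-based enumeration: a global model is fitted and
#' its case residuals clustered (Ward linkage) to propose initial
#' partitions; for each candidate `K = 1, 2, ..., K_max` the iterative
#' reassignment of [refine_partition()] is run; candidates are scanned in
#' increasing order and a larger `K` is accepted only while it is
#' non-degenerate and reduces the mean within-class raw closeness by more
#' than `delta` (relative); scanning stops at the first rejected candidate,
#' so the selected `k_hat` is the last accepted one. This makes the rule
#' conservative: ambiguity keeps the smaller number of classes.
#'
#' @param y `N x T` data matrix.
#' @param spec A [growth_spec()].
#' @param K_max Largest candidate number of classes (default 5).
#' @param control An [enum_control()].
#' @return An object of class `enumeration_result`: `k_hat`, `partition`
#'   (the selected [refine_partition()] result, `NULL` for `k_hat = 1`),
#'   `global_fit`, `diagnostics` (one row per examined candidate:
#'   within-class closeness `W`, relative drop, convergence, iterations,
#'   effective `K`, accepted flag), `dendrogram_heights`.
#' @examples
#' sim <- simulate_growth_mixture(
#'   simulation_design(model = 1, K = 2, N = 180, md = 3), seed = 7)
#' res <- enumerate_classes(sim$y, growth_spec(4), K_max = 3)
#' res$k_hat
#' @export
enumerate_classes <- function(y, spec, K_max = 5L, control = enum_control()) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (K_max < 1L) stop("K_max must be at least 1", call. = FALSE)
  min_size <- .resolve_min_size(control, spec)
  global_fit <- fit_growth_model(y, spec)
  bundle1 <- residual_bundle(global_fit, y, seq_len(n),
                             method = control$icr_method,
                             com_mode = control$com_mode)
  w1 <- mean(closeness_measure(list(bundle1))$raw[, 1])
  icr_mat <- matrix(bundle1$icr, nrow = n)
  hc <- stats::hclust(stats::dist(icr_mat), method = "ward.D2")

  diag_rows <- list(data.frame(K = 1L, W = w1, drop = NA_real_,
                               converged = TRUE, n_iterations = 0L,
                               effective_K = 1L, accepted = TRUE,
                               reason = "baseline"))
  k_hat <- 1L
  best_partition <- NULL
  w_best <- w1
  k_feasible <- min(K_max, floor(n / min_size))
  k <- 2L
  while (k <= k_feasible) {
    labels0 <- stats::cutree(hc, k = k)
    if (any(tabulate(labels0, k) < 3L)) {
      diag_rows[[k]] <- data.frame(K = k, W = NA_real_, drop = NA_real_,
                                   converged = FALSE, n_iterations = 0L,
                                   effective_K = NA_integer_, accepted = FALSE,
                                   reason = "initial cut below minimum size")
      break
    }
    part <- tryCatch(refine_partition(y, spec, labels0, control),
                     error = function(e) NULL)
    if (is.null(part)) {
      diag_rows[[k]] <- data.frame(K = k, W = NA_real_, drop = NA_real_,
                                   converged = FALSE, n_iterations = 0L,
                                   effective_K = NA_integer_, accepted = FALSE,
                                   reason = "refinement failed")
      break
    }
    w_k <- mean(part$cm$raw[cbind(seq_len(n), part$labels)])
    drop_k <- (w_best - w_k) / w_best
    ok <- !part$degenerate && part$converged && drop_k > control$delta
    reason <- if (part$degenerate) "class dissolved below minimum size"
      else if (!part$converged) "reassignment did not converge"
      else if (drop_k <= control$delta) "closeness drop below threshold"
      else "accepted"
    diag_rows[[k]] <- data.frame(K = k, W = w_k, drop = drop_k,
                                 converged = part$converged,
                                 n_iterations = part$n_iterations,
                                 effective_K = part$K, accepted = ok,
                                 reason = reason)
    if (!ok) break
    k_hat <- k
    best_partition <- part
    w_best <- w_k
    k <- k + 1L
  }
  structure(list(k_hat = k_hat, partition = best_partition,
                 global_fit = global_fit,
                 diagnostics = do.call(rbind, diag_rows),
                 dendrogram_heights = hc$height),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("Residual-based class enumeration\n")
  cat("  selected number of classes:", x$k_hat, "\n")
  print(x$diagnostics[, c("K", "W", "drop", "converged", "effective_K",
                          "accepted")], row.names = FALSE)
  invisible(x)
}
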