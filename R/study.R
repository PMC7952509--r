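## Deterministic seed stream: one sub-seed per (cell, replication), kept
## inside the 32-bit integer range.
.rep_seed <- function(master_seed, cell_index, rep) {
  as.integer((as.numeric(master_seed) * 97 + cell_index * 10007 +
                rep * 101) %% 2147483647)
}

#' Run one cell of the Monte Carlo study
#'
#' For `reps` replications: simulate a dataset from `design`, run
#' [enumerate_classes()], and record whether the selected number of classes
#' equals the true one. Replication-level failures are caught and counted,
#' never aborting the cell.
#'
#' @param design A [simulation_design()].
#' @param reps Number of replications (default 100).
#' @param K_max Largest candidate number of classes (default 5).
#' @param control An [enum_control()].
#' @param master_seed Integer master seed; per-replication seeds are derived
#'   deterministically from it and the cell's design coordinates.
#' @param spec Analysis model specification; default linear with
#'   occasion-specific residual variances on `design$T` occasions.
#' @return A list of class `study_cell`: the design coordinates,
#'   `percent_correct`, `se` (binomial proportion SE, proportion scale),
#'   `n_reps`, `n_correct`, `n_under`, `n_over`, `n_fail`, and the vector
#'   of selected `k_hat` per replication.
#' @export
run_condition <- function(design, reps = 100L, K_max = 5L,
                          control = enum_control(), master_seed = 1L,
                          spec = NULL) {
  stopifnot(inherits(design, "simulation_design"), reps >= 1)
  if (is.null(spec)) spec <- growth_spec(design$T)
  cell_index <- design$model * 1000L + design$K * 100L + design$N %% 97L
  k_hat <- integer(reps)
  fails <- 0L
  for (r in seq_len(reps)) {
    seed_r <- .rep_seed(master_seed, cell_index, r)
    res <- tryCatch({
      sim <- simulate_growth_mixture(design, seed_r)
      enumerate_classes(sim$y, spec, K_max = K_max, control = control)$k_hat
    }, error = function(e) NA_integer_)
    if (is.na(res)) fails <- fails + 1L
    k_hat[r] <- res
  }
  ok <- !is.na(k_hat)
  n_correct <- sum(k_hat[ok] == design$K)
  p <- n_correct / reps
  structure(list(model = design$model, K_true = design$K, N = design$N,
                 percent_correct = 100 * p,
                 se = sqrt(p * (1 - p) / reps),
                 n_reps = reps, n_correct = n_correct,
                 n_under = sum(k_hat[ok] < design$K),
                 n_over = sum(k_hat[ok] > design$K),
                 n_fail = fails, k_hat = k_hat,
                 master_seed = master_seed),
            class = "study_cell")
}

#' @export
print.study_cell <- function(x, ...) {
  cat(sprintf(
    "Model %d, K = %d, N = %d: %.1f%% correct (SE %.3f) over %d reps [under %d, over %d, failed %d]\n",
    x$model, x$K_true, x$N, x$percent_correct, x$se, x$n_reps,
    x$n_under, x$n_over, x$n_fail))
  invisible(x)
}

#' Run the Monte Carlo study over a design grid
#'
#' Iterates [run_condition()] over the cross of trajectory models, true
#' class counts, and sample sizes, and returns a tidy table of performance
#' rates: the percentage of replications in which the true number of
#' classes was identified, with binomial standard errors.
#'
#' @param models Trajectory conditions to run (subset of `c(1, 2)`).
#' @param Ks True class counts (default `c(2, 3, 4)`).
#' @param Ns Sample sizes (default `c(180, 540, 1080)`).
#' @param reps Replications per cell (default 100).
#' @param K_max Largest candidate `K` (default 5); cells with `K_true >=
#'   K_max` are run with `K_max = K_true + 2` so over-extraction stays
#'   observable.
#' @param control An [enum_control()].
#' @param master_seed Master seed for the whole study.
#' @param verbose Print each cell as it completes.
#' @param ... Additional arguments passed to [simulation_design()].
#' @return A list of class `study_result`: `table` (data frame with one row
#'   per cell: model, K_true, N, reps, percent_correct, se, n_under,
#'   n_over, n_fail) and `cells` (the full [run_condition()] results).
#' @export
run_study <- function(models = c(1, 2), Ks = c(2, 3, 4),
                      Ns = c(180, 540, 1080), reps = 100L, K_max = 5L,
                      control = enum_control(), master_seed = 1L,
                      verbose = FALSE, ...) {
  grid <- expand.grid(model = models, K = Ks, N = Ns)
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    design <- simulation_design(model = grid$model[i], K = grid$K[i],
                                N = grid$N[i], ...)
    kmax_i <- max(K_max, grid$K[i] + 2L)
    cell <- run_condition(design, reps = reps, K_max = kmax_i,
                          control = control, master_seed = master_seed)
    if (verbose) print(cell)
    cells[[i]] <- cell
    rows[[i]] <- data.frame(model = cell$model, K_true = cell$K_true,
                            N = cell$N, reps = cell$n_reps,
                            percent_correct = cell$percent_correct,
                            se = cell$se, n_under = cell$n_under,
                            n_over = cell$n_over, n_fail = cell$n_fail)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$model, tab$K_true, tab$N), ]
  rownames(tab) <- NULL
  structure(list(table = tab, cells = cells, master_seed = master_seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Class-enumeration performance rates (% replications with correct K)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a study result as CSV (and optionally JSON)
#'
#' @param result A [run_study()] result.
#' @param path Output CSV path.
#' @param json_path Optional JSON mirror (requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
write_study_result <- function(result, path, json_path = NULL) {
  stopifnot(inherits(result, "study_result"))
  utils::write.csv(result$table, path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output", call. = FALSE)
    jsonlite::write_json(result$table, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
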