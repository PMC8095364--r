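#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot, with SS_tot taken about the mean of the
#' observed (validation) values.
#'
#' @param model Predicted values.
#' @param obs Observed values (same length).
#' @return Scalar R^2 (<= 1; can be negative for poor fits).
#' @export
r_squared <- function(model, obs) {
  stopifnot(length(model) == length(obs), length(obs) >= 2L)
  1 - sum((obs - model)^2) / sum((obs - mean(obs))^2)
}

#' Root mean squared error
#' @inheritParams r_squared
#' @return Scalar RMSE in the units of the inputs (ug/m3 here).
#' @export
rmse <- function(model, obs) {
  stopifnot(length(model) == length(obs), length(obs) >= 1L)
  sqrt(mean((model - obs)^2))
}

#' Normalized mean bias factor
#'
#' Symmetric factor-style bias metric for model-vs-observation comparison:
#' when mean(model) >= mean(obs) it is sum(M - O)/sum(O); otherwise
#' sum(M - O)/sum(M). A model a factor of two high gives +1; a factor of
#' two low gives -1; `nmbf(m, o) = -nmbf(o, m)`.
#'
#' @param model Modeled concentrations (positive mean).
#' @param obs Observed concentrations (positive mean, same length).
#' @return Scalar NMBF (unitless).
#' @export
#' @examples
#' nmbf(c(2, 4), c(1, 2))   # model doubled -> 1
nmbf <- function(model, obs) {
  stopifnot(length(model) == length(obs), length(obs) >= 1L)
  if (sum(obs) <= 0 || sum(model) <= 0)
    stop("degenerate input: NMBF requires positive model and observation sums")
  num <- sum(model - obs)
  if (mean(model) >= mean(obs)) num / sum(obs) else num / sum(model)
}

#' Normalized mean absolute error factor
#'
#' Companion error metric to [nmbf()]: sum(|M - O|)/sum(O) when
#' mean(model) >= mean(obs), else sum(|M - O|)/sum(M). Always satisfies
#' `nmaef >= |nmbf|`.
#'
#' @inheritParams nmbf
#' @return Scalar NMAEF (unitless, >= 0).
#' @export
nmaef <- function(model, obs) {
  stopifnot(length(model) == length(obs), length(obs) >= 1L)
  if (sum(obs) <= 0 || sum(model) <= 0)
    stop("degenerate input: NMAEF requires positive model and observation sums")
  num <- sum(abs(model - obs))
  if (mean(model) >= mean(obs)) num / sum(obs) else num / sum(model)
}

# pooled + per-cell metric table for matched prediction/observation matrices
metric_table <- function(pred, obs) {
  per_cell <- data.frame(
    cell_id = colnames(obs),
    r2 = vapply(seq_len(ncol(obs)),
                function(i) r_squared(pred[, i], obs[, i]), 0),
    rmse = vapply(seq_len(ncol(obs)),
                  function(i) rmse(pred[, i], obs[, i]), 0),
    row.names = NULL)
  pooled <- data.frame(
    r2 = r_squared(as.numeric(pred), as.numeric(obs)),
    rmse = rmse(as.numeric(pred), as.numeric(obs)),
    nmbf = nmbf(as.numeric(pred), as.numeric(obs)),
    nmaef = nmaef(as.numeric(pred), as.numeric(obs)))
  list(per_cell = per_cell, pooled = pooled)
}

#' Evaluate fitted emulators on a held-out run set
#'
#' Predicts every cell at the test design and reports accuracy (R^2),
#' precision (RMSE), and the factor metrics NMBF/NMAEF, both pooled over
#' all (cell, run) pairs and per cell.
#'
#' @param emulators An `emulator_set` from [fit_grid()].
#' @param design_test Held-out design (runs x sectors).
#' @param Y_test Held-out simulator outputs (runs x cells).
#' @return An `eval_report`: list with `pooled` (one-row data frame),
#'   `per_cell` (data frame), `mean_per_cell_r2`, `role`, `n_folds = NA`.
#' @export
evaluate_emulators <- function(emulators, design_test, Y_test) {
  Y_test <- as.matrix(Y_test)
  pred <- predict_grid(emulators, as.matrix(design_test))
  mt <- metric_table(pred, Y_test)
  structure(list(pooled = mt$pooled, per_cell = mt$per_cell,
                 mean_per_cell_r2 = mean(mt$per_cell$r2),
                 role = "test", n_folds = NA_integer_),
            class = "eval_report")
}

#' K-fold cross-validation of the emulator design
#'
#' Randomly partitions the training runs into k folds (seeded), fits the
#' per-cell emulators on each set of k-1 folds, predicts the held-out fold,
#' and averages the performance measures across folds. Per-fold predictions
#' are retained so the averaging can be audited.
#'
#' @param design Training design (runs x sectors).
#' @param Y Simulator outputs (runs x cells).
#' @param k Number of folds (2 <= k <= n_runs); k = n_runs is
#'   leave-one-out.
#' @param seed Integer seed for the fold assignment and fits.
#' @param restarts,ard Passed to [fit_cell()].
#' @return An `eval_report` with `pooled` (fold-averaged pooled metrics),
#'   `per_fold` (data frame of pooled metrics per fold), `folds` (the
#'   index partition), `predictions` (runs x cells matrix of held-out
#'   predictions), `mean_per_cell_r2` (mean over cells of per-cell CV R^2),
#'   `n_folds`, `role = "cv"`.
#' @export
kfold_cv <- function(design, Y, k = 10, seed = 1, restarts = 3,
                     ard = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(design)
  n <- nrow(X)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of runs")
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(k), n))
  folds <- split(seq_len(n), fold_of)
  pred <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds[[f]]
    ems <- fit_grid(X[-hold, , drop = FALSE], Y[-hold, , drop = FALSE],
                    restarts = restarts, seed = seed + f, ard = ard)
    pred[hold, ] <- predict_grid(ems, X[hold, , drop = FALSE])
    p <- as.numeric(pred[hold, , drop = FALSE])
    o <- as.numeric(Y[hold, , drop = FALSE])
    per_fold[[f]] <- data.frame(
      fold = f,
      r2 = if (length(o) >= 2L) r_squared(p, o) else NA_real_,
      rmse = rmse(p, o), nmbf = nmbf(p, o), nmaef = nmaef(p, o))
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- data.frame(r2 = mean(per_fold$r2), rmse = mean(per_fold$rmse),
                       nmbf = mean(per_fold$nmbf),
                       nmaef = mean(per_fold$nmaef))
  per_cell_r2 <- vapply(seq_len(ncol(Y)),
                        function(i) r_squared(pred[, i], Y[, i]), 0)
  structure(list(pooled = pooled, per_fold = per_fold, folds = folds,
                 predictions = pred, mean_per_cell_r2 = mean(per_cell_r2),
                 n_folds = k, role = "cv"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (", x$role, ")\n", sep = "")
  print(round(x$pooled, 4))
  invisible(x)
}
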