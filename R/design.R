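#' Maximin Latin hypercube design
#'
#' Generates `n_iter` random Latin hypercube candidates (one point per
#' equal-width stratum and column, uniformly placed within its stratum) and
#' returns the candidate that maximizes the minimum pairwise Euclidean
#' distance, computed on the unit-scaled cube. This is the space-filling
#' design used for both the training and test run sets; the two are drawn
#' independently with their own seeds.
#'
#' @param n_runs Number of design points (rows).
#' @param n_dims Number of input dimensions (columns); 5 for the five
#'   emission sectors.
#' @param lower,upper Common bounds for every dimension (default the
#'   emission-scaling bounds 0 and 1.5).
#' @param n_iter Number of random candidates scored (the reference analysis
#'   used 100,000; desk-scale work uses far fewer).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param role Label stored on the design: `"train"` or `"test"`.
#' @return A data frame of class `design_matrix` (`n_runs` rows, sector
#'   columns) with attributes `role` and `min_distance`.
#' @export
#' @examples
#' d <- lhs_maximin(10, 5, n_iter = 50, seed = 1)
#' attr(d, "min_distance")
lhs_maximin <- function(n_runs, n_dims = 5, lower = scaling_bounds()[1],
                        upper = scaling_bounds()[2], n_iter = 100,
                        seed = 1, role = c("train", "test")) {
  role <- match.arg(role)
  n_runs <- as.integer(n_runs); n_dims <- as.integer(n_dims)
  n_iter <- as.integer(n_iter)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be a positive integer")
  if (is.na(n_dims) || n_dims < 1L) stop("n_dims must be a positive integer")
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be a positive integer")
  if (!(upper > lower)) stop("upper must exceed lower")
  set.seed(as.integer(seed))
  best <- NULL; best_score <- -Inf
  for (i in seq_len(n_iter)) {
    cand <- lhs::randomLHS(n_runs, n_dims)   # unit cube, Latin per column
    score <- if (n_runs > 1L) min(stats::dist(cand)) else Inf
    if (score > best_score) { best_score <- score; best <- cand }
  }
  out <- as.data.frame(lower + best * (upper - lower))
  colnames(out) <- if (n_dims == 5L) sectors() else
    paste0("x", seq_len(n_dims))
  rownames(out) <- sprintf("run%03d", seq_len(n_runs))
  structure(out, role = role, min_distance = best_score,
            class = c("design_matrix", "data.frame"))
}

#' Training-set size rule
#'
#' The number of simulator training runs is ten times the number of inputs,
#' the standard rule of thumb for Gaussian-process emulator designs. Five
#' emission sectors therefore give 50 training runs.
#'
#' @param n_inputs Number of input dimensions (>= 1).
#' @return Integer count of training runs, `10 * n_inputs`.
#' @export
#' @examples
#' training_size(5)
training_size <- function(n_inputs) {
  n_inputs <- as.integer(n_inputs)
  if (is.na(n_inputs) || n_inputs < 1L)
    stop("n_inputs must be a positive integer")
  10L * n_inputs
}

#' Check the Latin hypercube property of a design
#'
#' A design has the Latin property when, per column, each of the `n_runs`
#' equal-width strata of \[lower, upper\] contains exactly one point.
#'
#' @param design Matrix or data frame of design points.
#' @param lower,upper Design bounds.
#' @return `TRUE` if every column satisfies the property, else `FALSE`.
#' @export
is_latin <- function(design, lower = scaling_bounds()[1],
                     upper = scaling_bounds()[2]) {
  X <- as.matrix(design)
  n <- nrow(X)
  all(apply(X, 2, function(col) {
    strata <- floor((col - lower) / (upper - lower) * n)
    strata <- pmin(pmax(strata, 0), n - 1)  # boundary points
    setequal(strata, 0:(n - 1)) && length(strata) == n
  }))
}
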