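#' Saltelli sample matrix for Sobol index estimation
#'
#' Generates the radial A/B/AB_i/BA_i sampling scheme: two independent
#' base blocks A and B of `N` rows each (drawn jointly from a 2D-column
#' scrambled Sobol' sequence, so each block has stratified, Latin-like
#' per-column coverage at power-of-two N), D blocks AB_i (A with column i
#' taken from B),
#' and, when second-order indices are requested, D blocks BA_i (B with
#' column i from A). Total rows are N(2D + 2) with second order on
#' (the run budget N x (2D + 2)), or N(D + 2) without.
#'
#' Row layout: A (rows 1..N), B (next N), then AB_1 .. AB_D, then
#' BA_1 .. BA_D. [sobol_indices()] expects model outputs in this order.
#'
#' @param N Base sample count (>= 2; a power of 2 such as 1024 is
#'   recommended; N = 1000 reproduces the literal 12,000-run budget).
#' @param D Number of inputs (default 5).
#' @param lower,upper Per-input bounds (defaults 0 and 1.5).
#' @param second_order Include the BA_i blocks needed for second-order
#'   indices (default `TRUE`).
#' @param seed Integer seed; deterministic given the seed.
#' @return Numeric matrix with N(2D+2) (or N(D+2)) rows and D columns,
#'   with attributes `N`, `D`, `second_order`.
#' @export
#' @examples
#' nrow(saltelli_sample(1000, 5))   # 12,000
saltelli_sample <- function(N, D = 5, lower = scaling_bounds()[1],
                            upper = scaling_bounds()[2],
                            second_order = TRUE, seed = 1) {
  N <- as.integer(N); D <- as.integer(D)
  if (is.na(N) || N < 2L) stop("N must be at least 2")
  if (is.na(D) || D < 1L) stop("D must be at least 1")
  base <- sobol_sequence(N, 2L * D, seed = seed)
  A <- base[, seq_len(D), drop = FALSE]
  B <- base[, D + seq_len(D), drop = FALSE]
  blocks <- list(A, B)
  for (i in seq_len(D)) {
    ABi <- A; ABi[, i] <- B[, i]; blocks[[length(blocks) + 1L]] <- ABi
  }
  if (second_order) {
    for (i in seq_len(D)) {
      BAi <- B; BAi[, i] <- A[, i]; blocks[[length(blocks) + 1L]] <- BAi
    }
  }
  M <- do.call(rbind, blocks)
  M <- lower + M * (upper - lower)
  colnames(M) <- if (D == 5L) sectors() else paste0("x", seq_len(D))
  structure(M, N = N, D = D, second_order = second_order)
}

#' Sobol sensitivity indices from Saltelli-ordered model outputs
#'
#' Estimates first-order (S1), total-order (ST), and optionally
#' second-order (S2) variance-based sensitivity indices from model
#' evaluations at a [saltelli_sample()] matrix. Estimators: S1 by the
#' Saltelli (2010) formula mean(yB (yABi - yA))/V, ST by Jansen's
#' mean((yA - yABi)^2)/(2V), and S2 from the cross blocks
#' mean(yBAi yABj - yA yB)/V - S1_i - S1_j; V is the variance of the
#' pooled A and B outputs. For an additive model the S1 sum converges to 1
#' as N grows.
#'
#' @param y Model outputs, ordered as the rows of [saltelli_sample()];
#'   length must be exactly N(2D+2) (second order) or N(D+2).
#' @param N,D Base sample count and input count of the sample (taken from
#'   the sample attributes if a matrix is passed to `sample`).
#' @param second_order Whether the sample included the BA_i blocks.
#' @return List of class `sobol_indices` with `S1`, `ST` (length-D named
#'   vectors), `S2` (D x D upper-triangular matrix or `NULL`),
#'   `variance`, and `flat` (`TRUE` when the outputs have zero variance,
#'   in which case all indices are 0).
#' @export
sobol_indices <- function(y, N, D = 5, second_order = TRUE) {
  N <- as.integer(N); D <- as.integer(D)
  expect_len <- if (second_order) N * (2L * D + 2L) else N * (D + 2L)
  if (length(y) != expect_len)
    stop("output length ", length(y), " does not match the run budget ",
         expect_len, " (N = ", N, ", D = ", D, ")")
  nm <- if (D == 5L) sectors() else paste0("x", seq_len(D))
  # center and scale the outputs before estimation: the indices are
  # invariant to affine maps of y, and removing the mean offset greatly
  # reduces the Monte-Carlo variance of the product-based estimators
  if (stats::sd(y) > 0) y <- (y - mean(y)) / stats::sd(y)
  yA <- y[seq_len(N)]
  yB <- y[N + seq_len(N)]
  yAB <- matrix(y[2L * N + seq_len(N * D)], N, D)
  yBA <- if (second_order) matrix(y[(2L + D) * N + seq_len(N * D)], N, D)
  V <- stats::var(c(yA, yB))
  if (!is.finite(V) || V <= 0) {
    S1 <- ST <- stats::setNames(rep(0, D), nm)
    S2 <- if (second_order) matrix(0, D, D, dimnames = list(nm, nm))
    return(structure(list(S1 = S1, ST = ST, S2 = S2, variance = 0,
                          flat = TRUE), class = "sobol_indices"))
  }
  S1 <- vapply(seq_len(D), function(i) mean(yB * (yAB[, i] - yA)) / V, 0)
  ST <- vapply(seq_len(D), function(i) 0.5 * mean((yA - yAB[, i])^2) / V, 0)
  names(S1) <- names(ST) <- nm
  S2 <- NULL
  if (second_order) {
    S2 <- matrix(0, D, D, dimnames = list(nm, nm))
    for (i in seq_len(D - 1L)) for (j in (i + 1L):D) {
      Vij <- mean(yBA[, i] * yAB[, j] - yA * yB) / V
      S2[i, j] <- Vij - S1[i] - S1[j]
    }
  }
  structure(list(S1 = S1, ST = ST, S2 = S2, variance = V, flat = FALSE),
            class = "sobol_indices")
}

#' Absolute first-order sensitivity indices
#'
#' First-order indices scaled to concentration units by multiplying with
#' the baseline PM2.5 concentration of the cell: abs_s1_i = S1_i *
#' baseline. When the S1 sum is ~1, the absolute indices sum to ~baseline.
#'
#' @param S1 Named vector (or matrix, cells x sectors) of first-order
#'   indices.
#' @param baseline Baseline concentration(s) in ug/m3 (>= 0; recycled or
#'   one per row of a matrix `S1`).
#' @return Absolute indices in ug/m3, same shape as `S1`.
#' @export
#' @examples
#' absolute_s1(c(RES = 0.64, IND = 0.16, TRA = 0.04, AGR = 0.14,
#'               ENE = 0.01), 104.4)
absolute_s1 <- function(S1, baseline) {
  if (any(baseline < 0)) stop("baseline must be non-negative")
  if (is.matrix(S1)) S1 * baseline else S1 * baseline[1]
}

#' Sobol analysis of every fitted cell emulator
#'
#' Runs the full variance-based sensitivity analysis: draws one Saltelli
#' sample over the emission-scaling space, evaluates every cell emulator at
#' all rows, and estimates per-cell S1/ST/S2 plus the percentage
#' presentation (S1 normalized to sum to 100 per cell) and absolute
#' first-order indices (S1 times the cell's baseline prediction at
#' all-sectors-1).
#'
#' @param emulators An `emulator_set` from [fit_grid()].
#' @param N Base sample count (default 1024).
#' @param second_order Estimate second-order indices (default `TRUE`).
#' @param lower,upper Input bounds for the sensitivity measure (defaults:
#'   the full design range 0--1.5).
#' @param seed Integer seed for the Saltelli sample.
#' @return Object of class `sensitivity_result`: list with matrices `S1`,
#'   `ST`, `s1_percent`, `abs_s1` (cells x sectors), array `S2`
#'   (cells x D x D) or `NULL`, `baseline` (per-cell, ug/m3), and the
#'   sampling configuration.
#' @export
sobol_grid <- function(emulators, N = 1024, second_order = TRUE,
                       lower = scaling_bounds()[1],
                       upper = scaling_bounds()[2], seed = 1) {
  M <- saltelli_sample(N, D = 5, lower = lower, upper = upper,
                       second_order = second_order, seed = seed)
  ids <- names(emulators)
  nm <- sectors()
  S1 <- ST <- matrix(NA_real_, length(ids), 5, dimnames = list(ids, nm))
  S2 <- if (second_order)
    array(NA_real_, c(length(ids), 5, 5), dimnames = list(ids, nm, nm))
  baseline <- stats::setNames(numeric(length(ids)), ids)
  ones <- matrix(rep(1, 5), nrow = 1)
  for (i in seq_along(ids)) {
    em <- emulators[[i]]
    y <- predict(em, M)$mean
    si <- sobol_indices(y, N = N, D = 5, second_order = second_order)
    S1[i, ] <- si$S1
    ST[i, ] <- si$ST
    if (second_order) S2[i, , ] <- si$S2
    baseline[i] <- predict(em, ones)$mean
  }
  s1_percent <- S1 / rowSums(S1) * 100
  structure(list(S1 = S1, ST = ST, S2 = S2, s1_percent = s1_percent,
                 abs_s1 = absolute_s1(S1, baseline), baseline = baseline,
                 N = N, second_order = second_order, seed = seed,
                 bounds = c(lower, upper)),
            class = "sensitivity_result")
}

#' Regional summary of first-order sensitivities
#'
#' Aggregates per-cell first-order indices to regional sector percentages
#' (the presentation used in regional sensitivity tables): a
#' population-weighted (default) or unweighted mean of per-cell S1 per
#' region, normalized to sum to 100 and rounded to integers. A country-wide
#' row labelled `"China"` aggregates all cells.
#'
#' @param sens A `sensitivity_result` from [sobol_grid()].
#' @param grid The [grid_spec()] the emulators were built on.
#' @param pop Optional named per-cell population counts (from
#'   [make_population()]); `NULL` gives the unweighted mean.
#' @return Data frame: `region`, one integer-percent column per sector,
#'   and `n_cells`. Empty regions are omitted with a warning.
#' @export
regional_summary <- function(sens, grid, pop = NULL) {
  stopifnot(inherits(sens, "sensitivity_result"), inherits(grid, "grid_spec"))
  ids <- rownames(sens$S1)
  regs <- grid$region_of[ids]
  w <- if (is.null(pop)) stats::setNames(rep(1, length(ids)), ids) else
    pop[ids]
  groups <- c(list(China = ids), split(ids, regs))
  rows <- lapply(names(groups), function(rg) {
    members <- groups[[rg]]
    if (length(members) == 0L) {
      warning("region ", rg, " has no cells; omitted")
      return(NULL)
    }
    wm <- w[members] / sum(w[members])
    s1 <- colSums(sens$S1[members, , drop = FALSE] * wm)
    pct <- round(s1 / sum(s1) * 100)
    data.frame(region = rg, t(pct), n_cells = length(members),
               check.names = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
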