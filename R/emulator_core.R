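#' Matern 5/2 covariance function
#'
#' k(r) = variance * (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) *
#' exp(-sqrt(5) r / l), the kernel of the per-cell Gaussian-process
#' emulators. With ARD lengthscales, `r` is the anisotropically scaled
#' distance and `lengthscale` is 1.
#'
#' @param r Distances (>= 0).
#' @param lengthscale Kernel lengthscale (> 0).
#' @param variance Kernel amplitude sigma^2 (> 0).
#' @return Covariance values, same shape as `r`.
#' @export
#' @examples
#' matern52(0, 1, 2)              # variance at zero distance
#' matern52(1, 1, 1)              # (1 + sqrt(5) + 5/3) * exp(-sqrt(5))
matern52 <- function(r, lengthscale = 1, variance = 1) {
  if (any(r < 0)) stop("distances must be non-negative")
  if (lengthscale <= 0) stop("lengthscale must be positive")
  if (variance <= 0) stop("variance must be positive")
  s <- sqrt(5) * r / lengthscale
  variance * (1 + s + s^2 / 3) * exp(-s)
}

# scaled squared distances per dimension: list of (x_i - x'_j)^2 / ell^2
scaled_sqdist <- function(X1, X2, ell) {
  D <- ncol(X1)
  out <- vector("list", D)
  for (j in seq_len(D)) {
    d <- outer(X1[, j], X2[, j], "-")
    out[[j]] <- (d / ell[j])^2
  }
  out
}

# Matern 5/2 ARD kernel matrix between row sets X1, X2
kernel_matrix <- function(X1, X2, ell, sigma2) {
  sq <- scaled_sqdist(X1, X2, ell)
  r <- sqrt(pmax(Reduce(`+`, sq), 0))
  matern52(r, 1, sigma2)
}

# Cholesky with escalating jitter; duplicate design rows are survivable
safe_chol <- function(K) {
  jit <- 0
  for (i in 0:8) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 * mean(diag(K)) else jit * 10
  }
  stop("kernel matrix is numerically singular even with jitter")
}

# negative log marginal likelihood and its gradient in log-parameters
# theta = c(log sf2, log ell (1 or D), log sn2); Z standardized inputs,
# y standardized outputs
gp_nll <- function(theta, Z, y, ard) {
  n <- nrow(Z); D <- ncol(Z)
  sf2 <- exp(theta[1])
  ell <- if (ard) exp(theta[1 + seq_len(D)]) else rep(exp(theta[2]), D)
  sn2 <- exp(theta[length(theta)])
  sq <- scaled_sqdist(Z, Z, ell)
  r <- sqrt(pmax(Reduce(`+`, sq), 0))
  Kf <- matern52(r, 1, sf2)
  L <- safe_chol(Kf + diag(sn2, n))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)          # 0.5 * tr(A dK) terms
  g_sf2 <- 0.5 * sum(A * Kf)
  # d k / d log ell_j = sf2 * (5/3)(1 + sqrt5 r) exp(-sqrt5 r) * sq_j
  base <- sf2 * (5 / 3) * (1 + sqrt(5) * r) * exp(-sqrt(5) * r)
  if (ard) {
    g_ell <- vapply(seq_len(D), function(j) 0.5 * sum(A * (base * sq[[j]])),
                    0)
  } else {
    g_ell <- 0.5 * sum(A * (base * Reduce(`+`, sq)))
  }
  g_sn2 <- 0.5 * sum(diag(A)) * sn2
  list(value = nll, gradient = c(g_sf2, g_ell, g_sn2))
}

#' Fit a per-cell Gaussian-process emulator
#'
#' Fits the emulator design used throughout the pipeline: Yeo-Johnson
#' transform of each input column (lambda by profile maximum likelihood on
#' the training inputs only), standardization of the transformed inputs,
#' zero-mean/unit-variance standardization of the outputs, and a Matern 5/2
#' Gaussian process whose hyperparameters (signal variance, ARD
#' lengthscales, noise variance) maximize the log marginal likelihood over
#' several random restarts of an L-BFGS-B search with analytic gradients.
#' The noise variance is bounded below at 1e-10 (jitter for a deterministic
#' simulator).
#'
#' @param X Training design: matrix or data frame, one row per run, one
#'   column per input (emission-scaling factors).
#' @param y Training outputs: concentrations (ug/m3), one per run.
#' @param restarts Number of optimizer restarts (default 10); the first
#'   start is a fixed default, the rest are log-uniform random.
#' @param seed Integer seed controlling the restarts (deterministic fit).
#' @param ard Use one lengthscale per input (default `TRUE`); `FALSE`
#'   forces a single isotropic lengthscale.
#' @param cell_id Optional identifier stored on the emulator.
#' @return An object of class `cell_emulator`. Constant outputs yield a
#'   degenerate flat emulator with `degenerate = TRUE` and a warning, not
#'   an error.
#' @seealso [predict.cell_emulator()], [fit_grid()]
#' @export
#' @examples
#' d <- lhs_maximin(20, 2, n_iter = 5, seed = 1)
#' y <- 3 * d[[1]] + rnorm(20, 0, 0.01)
#' em <- fit_cell(d, y, restarts = 2, seed = 1)
#' predict(em, d[1, ])$mean
fit_cell <- function(X, y, restarts = 10, seed = 1, ard = TRUE,
                     cell_id = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); D <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L * D) stop("need at least 2 * n_dims training runs")
  # input transform: per-column Yeo-Johnson then standardization
  lambda <- numeric(D)
  for (j in seq_len(D)) {
    lambda[j] <- if (stats::sd(X[, j]) == 0) 1 else fit_lambda(X[, j])
  }
  W <- vapply(seq_len(D), function(j) yeo_johnson(X[, j], lambda[j]),
              numeric(n))
  in_mean <- colMeans(W)
  in_sd <- apply(W, 2, stats::sd)
  in_sd[in_sd == 0] <- 1
  Z <- sweep(sweep(W, 2, in_mean), 2, in_sd, "/")
  out_mean <- mean(y)
  out_sd <- stats::sd(y)
  base <- list(cell_id = cell_id, lambda = lambda, in_mean = in_mean,
               in_sd = in_sd, out_mean = out_mean, out_sd = out_sd,
               X_raw = X, Z = Z, ard = ard)
  if (out_sd == 0) {
    warning("constant training outputs: fitting a degenerate flat emulator")
    em <- c(base, list(degenerate = TRUE, y_std = rep(0, n),
                       hyper = list(signal_variance = 1e-12,
                                    lengthscales = rep(1, D),
                                    noise_variance = 1e-10)))
    class(em) <- "cell_emulator"
    return(em)
  }
  y_std <- (y - out_mean) / out_sd
  set.seed(as.integer(seed))
  n_ell <- if (ard) D else 1L
  lower <- c(log(1e-4), rep(log(0.05), n_ell), log(1e-10))
  upper <- c(log(1e4), rep(log(50), n_ell), log(1))
  starts <- vector("list", max(1L, restarts))
  starts[[1]] <- c(0, rep(0, n_ell), log(1e-6))
  for (k in seq_len(length(starts) - 1L)) {
    starts[[k + 1L]] <- c(stats::runif(1, log(0.1), log(10)),
                          stats::runif(n_ell, log(0.2), log(10)),
                          stats::runif(1, log(1e-9), log(1e-3)))
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0,
                   fn = function(th) gp_nll(th, Z, y_std, ard)$value,
                   gr = function(th) gp_nll(th, Z, y_std, ard)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  th <- best$par
  sf2 <- exp(th[1])
  ell <- if (ard) exp(th[1 + seq_len(D)]) else rep(exp(th[2]), D)
  sn2 <- exp(th[length(th)])
  Kf <- kernel_matrix(Z, Z, ell, sf2)
  L <- safe_chol(Kf + diag(sn2, n))
  alpha <- backsolve(L, forwardsolve(t(L), y_std))
  em <- c(base, list(degenerate = FALSE, y_std = y_std,
                     hyper = list(signal_variance = sf2, lengthscales = ell,
                                  noise_variance = sn2),
                     L = L, alpha = alpha, nll = best$value))
  class(em) <- "cell_emulator"
  em
}

# map raw inputs through the emulator's stored transforms
transform_inputs <- function(em, X) {
  X <- as.matrix(X)
  W <- vapply(seq_len(ncol(X)),
              function(j) yeo_johnson(X[, j], em$lambda[j]),
              numeric(nrow(X)))
  if (nrow(X) == 1L) W <- matrix(W, nrow = 1L)
  sweep(sweep(W, 2, em$in_mean), 2, em$in_sd, "/")
}

#' Predict from a fitted cell emulator
#'
#' Gaussian-process posterior mean and standard deviation, mapped back
#' through the output standardization to ug/m3. The reported standard
#' deviation is that of the latent function (no observation noise), so it
#' is near zero at training inputs.
#'
#' @param object A `cell_emulator` from [fit_cell()].
#' @param newdata Matrix or data frame of scaling vectors (one row per
#'   scenario). Rows outside \[0, 1.5\] raise a warning (extrapolation is
#'   allowed but untrusted).
#' @param ... Unused.
#' @return List with numeric vectors `mean` and `sd` (ug/m3).
#' @export
predict.cell_emulator <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  b <- scaling_bounds()
  if (any(X < b[1]) || any(X > b[2]))
    warning("inputs outside [", b[1], ", ", b[2], "]: extrapolating")
  if (isTRUE(object$degenerate)) {
    return(list(mean = rep(object$out_mean, nrow(X)),
                sd = rep(0, nrow(X))))
  }
  Zs <- transform_inputs(object, X)
  h <- object$hyper
  Ks <- kernel_matrix(Zs, object$Z, h$lengthscales, h$signal_variance)
  mu <- as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var_lat <- pmax(h$signal_variance - colSums(V^2), 0)
  list(mean = object$out_mean + object$out_sd * mu,
       sd = object$out_sd * sqrt(var_lat))
}

#' Fit emulators for every grid cell
#'
#' @param design Training design (runs x sectors), e.g. from
#'   [lhs_maximin()].
#' @param Y Output matrix (runs x cells) from the simulator, e.g. from
#'   [simulate_runs()].
#' @param restarts,seed,ard Passed to [fit_cell()]; each cell gets its own
#'   sub-seed derived from `seed`.
#' @param verbose Print progress every 100 cells.
#' @return Object of class `emulator_set`: named list of `cell_emulator`s
#'   with the design stored as an attribute.
#' @export
fit_grid <- function(design, Y, restarts = 10, seed = 1, ard = TRUE,
                     verbose = FALSE) {
  Y <- as.matrix(Y)
  ids <- colnames(Y)
  if (is.null(ids)) ids <- sprintf("c%05d", seq_len(ncol(Y)))
  ems <- vector("list", ncol(Y))
  names(ems) <- ids
  for (i in seq_len(ncol(Y))) {
    ems[[i]] <- fit_cell(design, Y[, i], restarts = restarts,
                         seed = (seed + i) %% .Machine$integer.max,
                         ard = ard, cell_id = ids[i])
    if (verbose && i %% 100 == 0) message("fitted ", i, " / ", ncol(Y))
  }
  structure(ems, design = design, class = "emulator_set")
}

#' Predict concentrations for all cells at scenario inputs
#'
#' @param emulators An `emulator_set` from [fit_grid()].
#' @param X One scaling 5-vector or a matrix of scenarios (rows).
#' @return Matrix of posterior-mean concentrations (scenarios x cells).
#' @export
predict_grid <- function(emulators, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  out <- vapply(emulators, function(em) predict(em, X)$mean,
                numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(NULL, names(emulators)))
  out
}
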