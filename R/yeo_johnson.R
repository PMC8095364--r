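#' Yeo-Johnson power transform
#'
#' The piecewise power transform used to preprocess the emulator inputs.
#' For x >= 0: ((x+1)^lambda - 1)/lambda (log(x+1) when lambda = 0); for
#' x < 0: -(((1-x)^(2-lambda)) - 1)/(2-lambda) (-log(1-x) when lambda = 2).
#' Strictly monotone in x for any finite lambda, and total on the reals.
#'
#' @param x Numeric vector.
#' @param lambda Transform parameter (finite scalar).
#' @return Transformed values, same length as `x`.
#' @seealso [yeo_johnson_inverse()], [fit_lambda()]
#' @export
#' @examples
#' yeo_johnson(0.7, 1)   # identity at lambda = 1
#' yeo_johnson(0, 0)     # log(1) = 0
yeo_johnson <- function(x, lambda) {
  if (!is.finite(lambda)) stop("lambda must be finite")
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

#' Inverse Yeo-Johnson transform
#'
#' @param y Numeric vector on the transformed scale.
#' @param lambda Transform parameter (finite scalar).
#' @return Values x such that `yeo_johnson(x, lambda) = y`.
#' @export
yeo_johnson_inverse <- function(y, lambda) {
  if (!is.finite(lambda)) stop("lambda must be finite")
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- (lambda * y[pos] + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(y[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- 1 - (1 - (2 - lambda) * y[!pos])^(1 / (2 - lambda))
  } else {
    out[!pos] <- -expm1(-y[!pos])
  }
  out
}

#' Fit the Yeo-Johnson parameter by profile maximum likelihood
#'
#' Chooses lambda to maximize the Gaussian profile log-likelihood of the
#' transformed sample (the usual normality objective):
#' l(lambda) = -n/2 log(sigma_hat^2(lambda)) + (lambda - 1) *
#' sum(sign(x) log(|x| + 1)). Deterministic; optimized by golden-section
#' search on a bounded interval.
#'
#' @param xs Numeric sample (n >= 3, not all equal).
#' @param interval Search interval for lambda (default \[-5, 5\]).
#' @return The fitted lambda (scalar).
#' @export
#' @examples
#' set.seed(1)
#' fit_lambda(rnorm(500))  # approximately 1 for a normal sample
fit_lambda <- function(xs, interval = c(-5, 5)) {
  xs <- xs[is.finite(xs)]
  if (length(xs) < 3L) stop("need at least 3 finite values")
  if (stats::sd(xs) == 0) stop("degenerate input: sample is constant")
  n <- length(xs)
  jac <- sum(sign(xs) * log1p(abs(xs)))
  nll <- function(lambda) {
    z <- yeo_johnson(xs, lambda)
    v <- stats::var(z) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(Inf)
    n / 2 * log(v) - (lambda - 1) * jac
  }
  stats::optimize(nll, interval = interval)$minimum
}
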