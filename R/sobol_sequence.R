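#' Scrambled Sobol' low-discrepancy sequence
#'
#' Generates the first `n` points of a Sobol' sequence in up to 10
#' dimensions (Joe-Kuo direction numbers), with an optional random digital
#' shift (XOR scrambling) so different seeds give different but equally
#' well-distributed point sets. Used as the base sample of the Saltelli
#' scheme: quasi-random points converge markedly faster than plain Monte
#' Carlo for variance-based sensitivity estimation. When `n` is a power of
#' two, every one-dimensional projection places exactly one point in each
#' of the `n` equal-width strata of \[0, 1).
#'
#' @param n Number of points (>= 1).
#' @param d Number of dimensions (1--10).
#' @param seed Integer seed for the digital shift; `NULL` gives the
#'   unscrambled sequence (whose first point is the origin).
#' @return An `n` x `d` matrix of points in \[0, 1).
#' @export
#' @examples
#' sobol_sequence(8, 2, seed = NULL)
sobol_sequence <- function(n, d, seed = 1) {
  n <- as.integer(n); d <- as.integer(d)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.na(d) || d < 1L || d > 10L)
    stop("d must be between 1 and 10 (direction numbers available)")
  L <- 31L
  V <- sobol_direction_matrix(d, L)        # d x L direction integers
  pts <- matrix(0L, n, d)
  state <- integer(d)
  if (n > 1L) {
    for (i in 2:n) {
      c_bit <- lowest_zero_bit(i - 2L)     # Gray-code update
      state <- bitwXor(state, V[, c_bit])
      pts[i, ] <- state
    }
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    shift <- as.integer(floor(stats::runif(d) * 2^L))
    for (j in seq_len(d)) pts[, j] <- bitwXor(pts[, j], shift[j])
  }
  pts / 2^L
}

# index (1-based) of the lowest zero bit of a non-negative integer
lowest_zero_bit <- function(m) {
  c_bit <- 1L
  while (bitwAnd(m, 1L) == 1L) {
    m <- bitwShiftR(m, 1L)
    c_bit <- c_bit + 1L
  }
  c_bit
}

# Joe-Kuo (new-joe-kuo-6) primitive polynomials and initial direction
# numbers for dimensions 2..10; dimension 1 is the van der Corput sequence
sobol_joe_kuo <- list(
  list(s = 1L, a = 0L, m = 1L),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

# direction integers v_k (scaled by 2^(L-k)) for each dimension
sobol_direction_matrix <- function(d, L) {
  V <- matrix(0L, d, L)
  V[1, ] <- bitwShiftL(1L, L - seq_len(L))          # van der Corput
  if (d >= 2L) for (j in 2:d) {
    p <- sobol_joe_kuo[[j - 1L]]
    s <- p$s; a <- p$a; m <- p$m
    v <- integer(L)
    v[seq_len(s)] <- bitwShiftL(m, L - seq_len(s))
    if (L > s) for (k in (s + 1L):L) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1L) for (i in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
          vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
    V[j, ] <- v
  }
  V
}
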