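test_that("matern52 matches direct formula transcription", {
  expect_equal(matern52(0, 1, 2), 2)
  expect_equal(matern52(1, 1, 1), (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  r <- seq(0.1, 8, by = 0.1)
  k <- matern52(r, 2, 1.3)
  expect_equal(k, 1.3 * (1 + sqrt(5) * r / 2 + 5 * r^2 / 12) *
                 exp(-sqrt(5) * r / 2))
  expect_true(all(diff(k) < 0))            # monotone decay on this range
  expect_error(matern52(1, -1, 1), "positive")
  expect_error(matern52(1, 1, 0), "positive")
  expect_error(matern52(-0.1, 1, 1), "non-negative")
})

test_that("a linear single-input response is emulated near-exactly", {
  set.seed(4)
  d <- lhs_maximin(20, 5, n_iter = 10, seed = 9)
  y <- 40 + 12 * d$RES                      # other sectors ignored
  em <- fit_cell(d, y, restarts = 3, seed = 1)
  dt <- lhs_maximin(5, 5, n_iter = 10, seed = 10, role = "test")
  p <- predict(em, dt)
  expect_gt(r_squared(p$mean, 40 + 12 * dt$RES), 0.999)
})

test_that("a 50-run fit reproduces the synthetic simulator to R2 >= 0.999", {
  fx <- fixture_fitted_cell()
  dt <- lhs_maximin(5, 5, n_iter = 50, seed = 12, role = "test")
  yt <- apply(as.matrix(dt), 1, function(x) simulate_cell(fx$truth, x))
  p <- predict(fx$em, dt)
  expect_gt(r_squared(p$mean, yt), 0.999)
})

test_that("predictions interpolate the training data", {
  fx <- fixture_fitted_cell()
  em <- fx$em
  p <- predict(em, fx$design)
  tol <- 10 * sqrt(em$hyper$noise_variance) * em$out_sd
  expect_true(all(abs(p$mean - fx$y) <= pmax(tol, 1e-3 * em$out_sd)))
  expect_true(all(p$sd >= 0))
  expect_lt(max(p$sd), 0.05 * em$out_sd)    # near-zero at training inputs
})

test_that("posterior mean matches the textbook GP formula on a 1-D problem", {
  # independent linear-algebra oracle: k*' (K + sn I)^-1 y via solve()
  set.seed(6)
  X <- matrix(seq(0.05, 1.45, length.out = 10), ncol = 1)
  y <- 30 + 8 * sin(2 * X[, 1]) + 5 * X[, 1]
  em <- fit_cell(X, y, restarts = 4, seed = 2)
  probes <- matrix(c(0.2, 0.77, 1.31), ncol = 1)
  p <- predict(em, probes)
  h <- em$hyper
  Zs <- (yeo_johnson(probes[, 1], em$lambda) - em$in_mean) / em$in_sd
  Zt <- em$Z[, 1]
  # lengthscale folded into the distance, as the emulator defines it
  K <- outer(Zt, Zt, function(a, b)
    matern52(abs(a - b) / h$lengthscales[1], 1, h$signal_variance))
  Ks <- outer(Zs, Zt, function(a, b)
    matern52(abs(a - b) / h$lengthscales[1], 1, h$signal_variance))
  mu_std <- Ks %*% solve(K + diag(h$noise_variance, 10),
                         (y - em$out_mean) / em$out_sd)
  oracle <- em$out_mean + em$out_sd * as.numeric(mu_std)
  expect_equal(p$mean, oracle, tolerance = 1e-8)
})

test_that("degenerate fits are handled: duplicates succeed, constants warn", {
  d <- lhs_maximin(12, 2, n_iter = 5, seed = 3)
  X <- rbind(as.matrix(d), as.matrix(d)[1:3, ])   # duplicated rows
  y <- 10 + 2 * X[, 1] + X[, 2]
  em <- fit_cell(X, y, restarts = 2, seed = 1)
  expect_false(em$degenerate)
  p <- predict(em, X[1:3, ])
  expect_equal(p$mean, unname(y[1:3]), tolerance = 1e-2)
  expect_warning(em0 <- fit_cell(X, rep(5, nrow(X)), restarts = 2, seed = 1),
                 "degenerate")
  expect_true(em0$degenerate)
  expect_equal(predict(em0, X[1:2, ])$mean, c(5, 5))
})

test_that("uncertainty reverts to the prior away from data", {
  fx <- fixture_fitted_cell()
  p_in <- predict(fx$em, matrix(rep(0.75, 5), 1))
  p_corner <- predict(fx$em, matrix(rep(1.5, 5), 1))
  expect_true(p_in$sd >= 0 && p_corner$sd >= 0)
  expect_warning(predict(fx$em, matrix(rep(1.6, 5), 1)), "extrapolating")
})

test_that("standardization round-trips the training outputs", {
  fx <- fixture_fitted_cell()
  em <- fx$em
  expect_equal(em$out_mean + em$out_sd * em$y_std, unname(fx$y))
})

test_that("end-to-end emulator error is under 1% across a uniform probe set", {
  fx <- fixture_fitted_cell()
  set.seed(31)
  P <- matrix(runif(500, 0, 1.5), 100, 5)
  truth_vals <- apply(P, 1, function(x) simulate_cell(fx$truth, x))
  pred <- predict(fx$em, P)$mean
  expect_lt(max(abs(pred - truth_vals) / truth_vals), 0.01)
})

test_that("fit_cell is deterministic given its seed and validates inputs", {
  d <- lhs_maximin(16, 2, n_iter = 5, seed = 8)
  y <- 5 + d[[1]] + 0.5 * d[[2]]^2
  e1 <- fit_cell(d, y, restarts = 3, seed = 9)
  e2 <- fit_cell(d, y, restarts = 3, seed = 9)
  expect_identical(e1$hyper, e2$hyper)
  expect_error(fit_cell(d, y[-1], seed = 1), "length")
  expect_error(fit_cell(d[1:3, ], y[1:3], seed = 1), "training runs")
})
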