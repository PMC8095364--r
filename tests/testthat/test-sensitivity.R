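test_that("the Sobol sequence reproduces the reference net", {
  # first 8 points of the unscrambled 5-dim sequence, verified against an
  # independent quasi-Monte-Carlo implementation
  ref <- matrix(c(
    0,     0,     0,     0,     0,
    0.5,   0.5,   0.5,   0.5,   0.5,
    0.75,  0.25,  0.25,  0.25,  0.75,
    0.25,  0.75,  0.75,  0.75,  0.25,
    0.375, 0.375, 0.625, 0.875, 0.375,
    0.875, 0.875, 0.125, 0.375, 0.875,
    0.625, 0.125, 0.875, 0.625, 0.625,
    0.125, 0.625, 0.375, 0.125, 0.125), 8, 5, byrow = TRUE)
  expect_equal(sobol_sequence(8, 5, seed = NULL), ref)
  # scrambled: deterministic per seed, stratified per dimension at 2^m
  s1 <- sobol_sequence(64, 10, seed = 4)
  expect_identical(s1, sobol_sequence(64, 10, seed = 4))
  expect_true(is_latin(s1, 0, 1))
  expect_error(sobol_sequence(4, 11), "between 1 and 10")
})

test_that("saltelli_sample honours the run budget and bounds", {
  M <- saltelli_sample(1000, 5, seed = 1)
  expect_equal(nrow(M), 12000)                 # N (2D + 2)
  expect_equal(nrow(saltelli_sample(2, 1, seed = 1)), 8)
  expect_equal(nrow(saltelli_sample(100, 5, second_order = FALSE, seed = 1)),
               700)                            # N (D + 2)
  expect_true(all(M >= 0 & M <= 1.5))
  # A and B blocks each cover every stratum once at power-of-two N
  M2 <- saltelli_sample(256, 5, seed = 3)
  expect_true(is_latin(M2[1:256, ]))
  expect_true(is_latin(M2[257:512, ]))
  expect_error(saltelli_sample(1, 5), "at least 2")
})

test_that("estimated indices recover the additive closed form", {
  a <- c(3, 1, 0.5, 2, 0.1)
  s1_true <- a^2 / sum(a^2)                    # equal-width uniform inputs
  for (seed in 1:5) {
    M <- saltelli_sample(1024, 5, seed = seed)
    si <- sobol_indices(as.numeric(M %*% a), N = 1024, D = 5)
    expect_lt(max(abs(si$S1 - s1_true)), 0.02)
    expect_lt(abs(sum(si$S1) - 1), 0.02)
    expect_lt(max(abs(si$S2[upper.tri(si$S2)])), 0.01)
    expect_true(all(si$ST >= si$S1 - 0.02))
  }
})

test_that("a single-input model concentrates all sensitivity on that input", {
  M <- saltelli_sample(512, 5, seed = 2)
  si <- sobol_indices(M[, 3]^2, N = 512, D = 5)
  expect_equal(unname(si$S1[3]), 1, tolerance = 0.02)
  expect_equal(unname(si$ST[3]), 1, tolerance = 0.02)
  expect_lt(max(abs(si$S1[-3])), 0.02)
  expect_lt(max(si$ST[-3]), 0.02)
})

test_that("flat outputs flag and mismatched lengths refuse", {
  si <- sobol_indices(rep(3, 12 * 16), N = 16, D = 5)
  expect_true(si$flat)
  expect_true(all(si$S1 == 0) && all(si$ST == 0))
  expect_error(sobol_indices(rep(1, 100), N = 16, D = 5), "run budget")
})

test_that("absolute first-order indices scale with the baseline", {
  S1 <- c(RES = 0.64, IND = 0.16, TRA = 0.04, AGR = 0.14, ENE = 0.01)
  abs1 <- absolute_s1(S1, 104.4)
  expect_equal(unname(abs1["RES"]), 66.8, tolerance = 0.01)
  expect_equal(sum(abs1), 104.4 * sum(S1))
  expect_equal(unname(absolute_s1(S1, 0)), rep(0, 5))
  expect_error(absolute_s1(S1, -1), "non-negative")
})

test_that("grid-level analysis recovers the generating regional shares", {
  fx <- fixture_fitted_grid()
  sens <- sobol_grid(fx$ems, N = 512, seed = 6)
  # every cell: indices within tolerance bands, ST >= S1, s1_percent sums
  expect_true(all(sens$S1 > -0.02 & sens$S1 < 1.02))
  expect_true(all(sens$ST - sens$S1 > -0.02))
  expect_true(all(sens$ST - sens$S1 < 0.01 + 0.02))  # weak interactions
  expect_equal(unname(rowSums(sens$s1_percent)), rep(100, nrow(sens$S1)))
  reg <- regional_summary(sens, fx$grid, fx$pop)
  prof <- region_profiles()
  for (rg in setdiff(reg$region, "China")) {
    got <- as.numeric(reg[reg$region == rg, sectors()])
    want <- 100 * as.numeric(prof[prof$region == rg, sectors()])
    expect_lt(max(abs(got - want)), 3)
    expect_lte(abs(sum(got) - 100), 1)       # integer rounding
  }
  # unweighted aggregation also available
  reg_u <- regional_summary(sens, fx$grid, pop = NULL)
  expect_setequal(reg_u$region, reg$region)
})

test_that("single-cell regions report that cell's own percentages", {
  fx <- fixture_fitted_grid()
  sens <- sobol_grid(fx$ems, N = 256, seed = 8)
  id <- fx$grid$cell_ids[1]
  g1 <- grid_spec(1, 1, region_names = fx$grid$region_of[[id]])
  g1$cell_ids <- id
  g1$region_of <- setNames(fx$grid$region_of[id], id)
  sens1 <- sens
  for (f in c("S1", "ST", "s1_percent", "abs_s1"))
    sens1[[f]] <- sens[[f]][id, , drop = FALSE]
  sens1$baseline <- sens$baseline[id]
  reg <- regional_summary(sens1, g1, pop = NULL)
  expect_equal(as.numeric(reg[reg$region != "China", sectors()]),
               as.numeric(round(sens$s1_percent[id, ] /
                                  sum(sens$s1_percent[id, ]) * 100)))
})
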