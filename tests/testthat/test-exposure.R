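test_that("population weighting matches hand arithmetic and its identities", {
  concs <- c(a = 10, b = 20, c = 30)
  expect_equal(pop_weighted_exposure(concs, c(a = 1, b = 2, c = 7)), 26)
  # uniform population: arithmetic mean
  expect_equal(pop_weighted_exposure(concs, c(a = 5, b = 5, c = 5)),
               mean(concs))
  # all population in one cell: that cell's concentration
  expect_equal(pop_weighted_exposure(concs, c(a = 0, b = 0, c = 4)), 30)
  expect_error(pop_weighted_exposure(concs, c(a = 0, b = 0, c = 0)),
               "degenerate")
  expect_error(pop_weighted_exposure(concs, c(a = -1, b = 1, c = 1)),
               "non-negative")
})

test_that("attainment flags use inclusive thresholds", {
  expect_true(all(attainment(9.9)))
  a35 <- attainment(35)
  expect_true(a35[["NAQT"]] && a35[["IT-1"]])
  expect_false(a35[["AQG"]])
  a153 <- attainment(15.3)
  expect_false(a153[["AQG"]])
  expect_false(a153[["IT-3"]])    # 15.3 > 15
  expect_true(a153[["IT-2"]])
  expect_equal(dim(attainment(c(5, 20))), c(2L, 5L))
  expect_error(attainment(-1), "non-negative")
})

test_that("baseline exposure is consistent across modules", {
  fx <- fixture_fitted_grid()
  base <- baseline_exposure(fx$ems, fx$grid, fx$pop)
  concs <- predict_grid(fx$ems, rep(1, 5))[1, ]
  expect_equal(unname(base["China"]),
               pop_weighted_exposure(concs, fx$pop, fx$grid$cell_ids))
  rg <- "GBA"
  cells <- fx$grid$cell_ids[fx$grid$region_of == rg]
  expect_equal(unname(base[rg]),
               pop_weighted_exposure(concs, fx$pop, cells))
})

test_that("single sweeps are monotone and anchored at the baseline", {
  fx <- fixture_fitted_grid()
  sw <- sweep_single(fx$ems, "RES", fx$grid, fx$pop)
  base <- baseline_exposure(fx$ems, fx$grid, fx$pop)
  for (rg in unique(sw$region)) {
    s <- sw[sw$region == rg, ]
    s <- s[order(s$level), ]
    expect_equal(nrow(s), 16)
    # positive sector slopes: exposure non-decreasing in the level
    expect_true(all(diff(s$exposure) > -1e-6))
    expect_equal(s$exposure[abs(s$level - 1) < 1e-9], unname(base[rg]),
                 tolerance = 1e-9)
  }
  expect_true(all(sw$exposure > 0))
})

test_that("pair sweeps slice to single sweeps and to the baseline corner", {
  fx <- fixture_fitted_grid()
  levels <- c(0, 0.5, 1, 1.5)
  pw <- sweep_pair(fx$ems, "RES", "IND", fx$grid, fx$pop, levels = levels)
  expect_equal(nrow(pw), length(levels)^2 * length(unique(pw$region)))
  sw <- sweep_single(fx$ems, "IND", fx$grid, fx$pop, levels = levels)
  slice <- pw[abs(pw$level_a - 1) < 1e-9, ]
  m <- merge(slice, sw, by.x = c("region", "level_b"),
             by.y = c("region", "level"))
  expect_equal(m$exposure.x, m$exposure.y, tolerance = 1e-12)
  base <- baseline_exposure(fx$ems, fx$grid, fx$pop)
  corner <- pw[abs(pw$level_a - 1) < 1e-9 & abs(pw$level_b - 1) < 1e-9, ]
  expect_equal(corner$exposure, unname(base[corner$region]),
               tolerance = 1e-12)
  expect_error(sweep_pair(fx$ems, "RES", "RES", fx$grid, fx$pop), "differ")
})

test_that("two-sector response is near-additive on synthetic cells", {
  fx <- fixture_fitted_grid()
  # 30% joint reduction, the canonical single-sector policy scenario scale
  levels <- c(0.7, 1)
  pw <- sweep_pair(fx$ems, "RES", "AGR", fx$grid, fx$pop, levels = levels)
  ch <- pw[pw$region == "China", ]
  e <- function(a, b) ch$exposure[abs(ch$level_a - a) < 1e-9 &
                                    abs(ch$level_b - b) < 1e-9]
  lhs_val <- e(0.7, 0.7)
  rhs_val <- e(0.7, 1) + e(1, 0.7) - e(1, 1)
  expect_lt(abs(lhs_val - rhs_val) / e(1, 1), 0.01)
})

test_that("the full-lattice floor sits at all-zeros and stays positive", {
  fx <- fixture_fitted_grid()
  # coarse 3-level full factorial over all 5 sectors
  lv <- c(0, 0.75, 1.5)
  lattice <- as.matrix(expand.grid(RES = lv, IND = lv, TRA = lv,
                                   AGR = lv, ENE = lv))
  conc <- predict_grid(fx$ems, lattice)
  ex <- apply(conc, 1, function(cc)
    pop_weighted_exposure(setNames(cc, colnames(conc)), fx$pop))
  expect_equal(which.min(ex), which(rowSums(lattice) == 0))
  expect_gt(min(ex), 0)
})
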