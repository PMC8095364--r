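# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small multi-region truth set (24 cells, 3 regions)
fixture_truth_small <- function() {
  fixture("truth_small", function() {
    grid <- grid_spec(4, 6, region_names = c("North China", "GBA",
                                             "South West China"))
    list(grid = grid,
         truth = build_truth(grid, region_profiles(), seed = 42),
         pop = make_population(grid, seed = 43))
  })
}

# one China-profile cell with no share jitter (exact closed-form targets)
fixture_china_cell <- function() {
  fixture("china_cell", function() {
    grid <- grid_spec(1, 1, region_names = "North China")
    tr <- build_truth(grid, region_profiles(china_only = TRUE), seed = 7,
                      share_jitter = 0)
    tr$cells[[1]]
  })
}

# a fitted emulator on one synthetic cell (50-run maximin design)
fixture_fitted_cell <- function() {
  fixture("fitted_cell", function() {
    tc <- fixture_china_cell()
    design <- lhs_maximin(50, 5, n_iter = 50, seed = 11)
    y <- apply(as.matrix(design), 1, function(x) simulate_cell(tc, x))
    list(truth = tc, design = design, y = y,
         em = fit_cell(design, y, restarts = 4, seed = 3))
  })
}

# small fitted emulator set over the 24-cell grid, plus test runs
fixture_fitted_grid <- function() {
  fixture("fitted_grid", function() {
    fx <- fixture_truth_small()
    d_train <- lhs_maximin(50, 5, n_iter = 50, seed = 21)
    d_test <- lhs_maximin(5, 5, n_iter = 50, seed = 22, role = "test")
    Y_train <- simulate_runs(fx$truth, d_train)
    Y_test <- simulate_runs(fx$truth, d_test)
    ems <- fit_grid(d_train, Y_train, restarts = 3, seed = 30)
    c(fx, list(d_train = d_train, d_test = d_test, Y_train = Y_train,
               Y_test = Y_test, ems = ems))
  })
}
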