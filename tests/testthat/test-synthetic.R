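test_that("all generators are reproducible from the root seed", {
  i1 <- make_island(seed = 7); i2 <- make_island(seed = 7)
  expect_identical(i1, i2)
  expect_false(identical(make_island(seed = 8)$layers[[1]]$grid,
                         i1$layers[[1]]$grid))
  expect_identical(simulate_point_intercept(0.3, seed = 7),
                   simulate_point_intercept(0.3, seed = 7))
  expect_identical(simulate_belt(0.2, seed = 7),
                   simulate_belt(0.2, seed = 7))
  expect_identical(make_response_field(seed = 7),
                   make_response_field(seed = 7))
  # stream splitting: different generators draw from different streams
  expect_false(identical(simulate_belt(0.2, seed = 7)$N[1:5],
                         simulate_point_intercept(0.2, seed = 7)$n[1:5]))
})

test_that("synthetic island honours its spec downstream", {
  isl <- make_island(nrow = 10, ncol = 10, cellsize = 5, seed = 3)
  expect_length(isl$layers, 4)
  expect_equal(dim(isl$layers[[1]]$grid), c(10, 10))
  expect_equal(sum(isl$composition), 10 * 10 * 5^2)
  # forbidden fraction 1 -> no suitable land at all
  dead <- make_island(nrow = 6, ncol = 6, forbidden_frac = 1, seed = 3)
  cls <- classify_suitability(score_cells(dead$layers))
  expect_equal(suitable_area(cls, dead$cell_area), 0)
  # pure construction-land cover -> Sum LAI 0.5 downstream
  town <- make_island(cover_fractions = c("Construction land" = 1),
                      seed = 3)
  expect_equal(sum_lai(town$composition), 0.5)
  expect_error(make_island(cover_fractions = c(Woodland = 0.5)), "sum to 1")
})

test_that("point-intercept and belt simulators hit their degenerate cases", {
  expect_true(all(simulate_point_intercept(0, seed = 1)$n == 0))
  pit <- simulate_point_intercept(1, points = 50, seed = 1)
  expect_true(all(pit$n == 50))
  expect_true(all(simulate_belt(0, seed = 1)$N == 0))
  expect_error(simulate_point_intercept(1.2), "\\[0, 1\\]")
  expect_error(simulate_belt(-0.1), "non-negative")
  # Poisson mean 2*L*W*rho
  belt <- simulate_belt(1, length = 50, width = 1, n_transects = 1000,
                       seed = 2)
  expect_lt(abs(mean(belt$N) - 100), 3 * sqrt(100 / 1000))
})

test_that("synthetic response fields are feasible and oracle-consistent", {
  for (seed in 1:10) {
    rf <- make_response_field(n_areas = 3, n_sources = 3, seed = seed)
    expect_true(all(rf$P > 0))
    r <- solve_capacity(rf$P, rf$limits, rf$lower, rf$upper)
    expect_equal(r$status, "optimal")
    orc <- oracle_lp(rf$P, rf$limits, rf$lower, rf$upper)
    expect_equal(r$capacity, orc$capacity, tolerance = 1e-8)
  }
})

test_that("the case-study fixture stores the published ratios and structure", {
  tr <- zsi_tree()
  flat <- as.data.frame(tr)
  expect_equal(nrow(flat), 11)
  expect_equal(1 - flat$pressure / flat$support,
               c(0.38, 0.44, 0.87, -0.04, -1.45, 0.14, -0.67, 0.14,
                 0.04, 0.08, -0.60), tolerance = 1e-12)
  modes <- vapply(tr$dimensions, `[[`, character(1), "mode")
  expect_equal(unname(modes), c("flat", "flat", "nested", "flat"))
  # overall carrying state is surplus (warning under the default buffer)
  fit <- corecc(tr)
  expect_gt(fit$overall, 0)
  expect_equal(classify_state(fit$overall, warning_width = 0), "surplus")
  expect_equal(classify_state(fit$overall, warning_width = 0.10), "warning")
})
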