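test_that("single source capacity is standard/response or the upper bound", {
  r <- solve_capacity(matrix(0.5, 1, 1), limits = 1, lower = 0, upper = 10)
  expect_equal(r$status, "optimal")
  expect_equal(r$capacity, 2)
  r <- solve_capacity(matrix(0.5, 1, 1), limits = 1, lower = 0, upper = 1)
  expect_equal(r$capacity, 1)
})

test_that("LP equals the vertex-enumeration oracle on random instances", {
  set.seed(13)
  for (rep in 1:40) {
    na <- sample(1:3, 1); ns <- sample(1:4, 1)
    P <- matrix(runif(na * ns, 0.05, 1), na, ns)
    u <- runif(ns, 0.5, 5)
    l <- runif(ns, 0, 0.1)
    lim <- drop(P %*% u) * runif(na, 0.3, 1.2)
    lim <- pmax(lim, drop(P %*% l) * 1.5 + 0.01)  # keep feasible
    got <- solve_capacity(P, lim, l, u)
    orc <- oracle_lp(P, lim, l, u)
    expect_equal(got$status, "optimal")
    expect_equal(got$capacity, orc$capacity, tolerance = 1e-8)
    # constraints hold at the optimum
    expect_true(all(P %*% got$loads <= lim * (1 + 1e-9)))
    expect_true(all(got$loads >= l - 1e-9 & got$loads <= u + 1e-9))
  }
})

test_that("capacity responds monotonically to standards, bounds and P", {
  set.seed(5)
  P <- matrix(runif(6, 0.1, 1), 2, 3)
  u <- c(2, 3, 1); lim <- c(1, 1.5)
  ac <- solve_capacity(P, lim, 0, u)$capacity
  expect_gte(solve_capacity(P, lim * 2, 0, u)$capacity, ac)
  expect_gte(solve_capacity(P, lim, 0, u * 2)$capacity, ac)
  expect_lte(solve_capacity(P * 2, lim, 0, u)$capacity, ac)
  # scaling P and limits together changes nothing
  expect_equal(solve_capacity(P * 3, lim * 3, 0, u)$capacity, ac,
               tolerance = 1e-9)
  # with slack standards the upper bounds are the only limit
  expect_equal(solve_capacity(P, c(1e9, 1e9), 0, u)$capacity, sum(u),
               tolerance = 1e-9)
})

test_that("infeasible lower bounds are reported with the violated areas", {
  P <- matrix(c(1, 0.01), 2, 1)
  r <- solve_capacity(P, limits = c(0.5, 1), lower = 1, upper = 2)
  expect_equal(r$status, "infeasible")
  expect_equal(r$violated, "1")
  expect_true(is.na(r$capacity))
  expect_error(solve_capacity(P, limits = c(1, 1), lower = 0, upper = 2,
                              background = c(1, 0)), "background")
  expect_error(solve_capacity(P, limits = c(1, 1), lower = 2, upper = 1),
               "below lower")
})

test_that("background concentration tightens the effective standard", {
  P <- matrix(0.5, 1, 1)
  expect_equal(solve_capacity(P, 1, 0, 10, background = 0.5)$capacity, 1)
})

test_that("multi-pollutant surplus combines by minimum or RMS", {
  expect_equal(assimilation_surplus(c(IN = 100), c(IN = 13)), 0.87)
  expect_equal(assimilation_surplus(c(IN = 10, IP = 2), c(IN = 10, IP = 2)),
               0)
  expect_equal(assimilation_surplus(c(a = 10, b = 2), c(a = 1, b = 1)),
               0.5)  # min of 0.9 and 0.5
  expect_equal(assimilation_surplus(c(a = 10, b = 2), c(a = 1, b = 1),
                                    combine = "rms"),
               aggregate_ratios(c(0.9, 0.5)))
  expect_error(assimilation_surplus(c(a = 1), c(b = 1)), "one side only")
  expect_error(assimilation_surplus(c(a = 0), c(a = 1)), "positive")
  # accepts solve_capacity results directly
  res <- list(IN = solve_capacity(matrix(0.5, 1, 1), 1, 0, 10))
  expect_equal(assimilation_surplus(res, c(IN = 0.26)), 0.87)
})
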