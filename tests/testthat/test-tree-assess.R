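test_that("tree constructors validate structure and values", {
  expect_error(cc_indicator("x", pressure = 1, support = 0), "x")
  expect_error(cc_indicator("x", pressure = -1, support = 1), "x")
  expect_error(cc_factor("f"), "no indicators")
  expect_error(cc_dimension("d"), "no factors")
  expect_error(cc_tree(), "no dimensions")
  expect_error(
    cc_factor("f", cc_indicator("a", 1, 2), cc_indicator("a", 1, 2)),
    "duplicated")
  # a bare indicator is promoted to a single-indicator factor
  dm <- cc_dimension("d", cc_indicator("a", 1, 2))
  expect_s3_class(dm$factors[[1]], "cc_factor")
})

test_that("a degenerate one-indicator tree at full load is full-loaded everywhere", {
  tr <- cc_tree(cc_dimension("d", cc_indicator("a", pressure = 3,
                                               support = 3)))
  fit <- corecc(tr)
  expect_equal(fit$overall, 0)
  expect_true(all(fit$report$ratio == 0))
  expect_true(all(fit$report$state == "full-loaded"))
})

test_that("the bundled case-study tree reproduces the published ratios", {
  fit <- corecc(zsi_tree())
  ind <- fit$report[fit$report$level == "indicator", ]
  expect_equal(ind$ratio[match(c("land", "water", "water_assim", "sum_lai",
                                 "hcc", "coral_spp", "fish_density",
                                 "fish_spp", "gdp", "env_invest", "rnd"),
                               ind$id)],
               c(0.38, 0.44, 0.87, -0.04, -1.45, 0.14, -0.67, 0.14,
                 0.04, 0.08, -0.60),
               tolerance = 1e-12)
  expect_equal(unname(coef(fit)[["resources"]]), 0.409237780490323,
               tolerance = 1e-12)
  expect_equal(unname(coef(fit)[["assimilation"]]), 0.87, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[["ecosystem"]]), -0.35078680775317,
               tolerance = 1e-12)
  expect_equal(unname(coef(fit)[["socioeconomic"]]), -0.201110597183568,
               tolerance = 1e-12)
  expect_equal(fit$overall, 0.0469533502148666, tolerance = 1e-12)
  # degrees are |ratio| x 100 at full precision
  expect_equal(fit$report$degree, abs(fit$report$ratio) * 100)
  # hard-coral row: 145% overload
  expect_equal(ind$degree[ind$id == "hcc"], 145)
  expect_equal(ind$state[ind$id == "hcc"], "over-loaded")
})

test_that("assessment matches the brute-force oracle on random trees", {
  for (seed in 1:60) {
    tr <- random_tree(seed)
    fit <- corecc(tr)
    orc <- oracle_assess(tr)
    expect_equal(unname(fit$dimensions), orc$dimensions,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(fit$overall, orc$overall, tolerance = 1e-12)
  }
})

test_that("nested and flat modes differ exactly as the grouping implies", {
  ind <- function(id, d) cc_indicator(id, pressure = 1 - d, support = 1)
  fl <- corecc(cc_tree(cc_dimension(
    "e", cc_factor("t", ind("a", -0.04)),
    cc_factor("c", ind("b", -1.45), ind("c", 0.14), ind("d", -0.67),
              ind("e", 0.14)),
    mode = "flat")))
  ne <- corecc(cc_tree(cc_dimension(
    "e", cc_factor("t", ind("a", -0.04)),
    cc_factor("c", ind("b", -1.45), ind("c", 0.14), ind("d", -0.67),
              ind("e", 0.14)),
    mode = "nested")))
  expect_equal(ne$overall, -0.35078680775317, tolerance = 1e-12)
  expect_equal(fl$overall,
               aggregate_ratios(c(-0.04, -1.45, 0.14, -0.67, 0.14)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fl$overall, ne$overall)))
})

test_that("assessment errors carry the offending node's path", {
  tr <- zsi_tree()
  tr$dimensions[[1]]$factors[[1]]$indicators[[1]]$support <- -1
  expect_error(corecc(tr), "resources/land/land")
  expect_error(corecc(list()), "cc_tree")
})

test_that("every report value is recomputable from the (p, s) pairs alone", {
  fit <- corecc(zsi_tree(), warning_width = 0.10)
  flat <- as.data.frame(zsi_tree())
  d <- 1 - flat$pressure / flat$support
  ind <- fit$report[fit$report$level == "indicator", ]
  expect_equal(ind$ratio[match(flat$indicator, ind$id)], d,
               tolerance = 1e-12)
  expect_equal(ind$state, classify_state(ind$ratio, 0.10))
})
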