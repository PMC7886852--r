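unclass_g <- function(g) { attributes(g) <- attributes(g)["dim"]; g }

test_that("weighted overlay scores cells and vetoes forbidden factors", {
  a <- cc_layer(matrix(c(4, 0, 2, 4), 2), 0.5, "cover")
  b <- cc_layer(matrix(c(2, 5, 2, 4), 2), 0.5, "slope")
  sc <- score_cells(list(a, b))
  expect_equal(sc[1, 1], 3)            # weighted mean of 4 and 2
  expect_equal(sc[2, 1], 0)            # grade 0 vetoes despite the 5
  expect_equal(sc[1, 2], 2)
  expect_equal(sc[2, 2], 4)
})

test_that("overlay matches a per-cell loop oracle on random grids", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    w <- runif(k); w <- w / sum(w)
    grids <- replicate(k, matrix(sample(c(0, 1, 3, 5), 64, replace = TRUE,
                                        prob = c(0.15, 0.3, 0.3, 0.25)),
                                 8, 8), simplify = FALSE)
    layers <- Map(cc_layer, grids, w, paste0("f", seq_len(k)))
    sc <- score_cells(layers)
    # naive per-cell loop
    expect_true(all(vapply(seq_len(64), function(i) {
      g <- vapply(grids, `[`, numeric(1), i)
      want <- if (any(g == 0)) 0 else sum(w * g)
      abs(sc[i] - want) < 1e-12
    }, logical(1))))
    # bounded by child grades when none vetoes
    ok <- sc > 0
    if (any(ok)) {
      lo <- Reduce(pmin, grids); hi <- Reduce(pmax, grids)
      expect_true(all(sc[ok] >= lo[ok] - 1e-12 & sc[ok] <= hi[ok] + 1e-12))
    }
  }
})

test_that("overlay rejects bad weights, shapes and grades", {
  a <- cc_layer(matrix(1, 2, 2), 0.6)
  b <- cc_layer(matrix(1, 2, 2), 0.3)
  expect_error(score_cells(list(a, b)), "sum to 1")
  expect_error(score_cells(list(a, cc_layer(matrix(1, 3, 2), 0.4))),
               "shape")
  expect_error(cc_layer(matrix(-1, 2, 2), 0.5), "negative")
  # mismatched no-data masks
  g1 <- matrix(1, 2, 2); g2 <- matrix(1, 2, 2); g2[1] <- NA
  expect_error(score_cells(list(cc_layer(g1, 0.5), cc_layer(g2, 0.5))),
               "mask")
})

test_that("four-level classification and area accounting are exact", {
  sc <- matrix(c(0, 1, 3, 4.5), 2)
  cls <- classify_suitability(sc, thresholds = c(2, 4))
  expect_equal(as.vector(cls),
               c("forbidden", "limited", "less-suitable", "suitable"))
  expect_equal(suitable_area(cls, 100), 200)
  expect_error(classify_suitability(sc, thresholds = c(4, 2)), "t1 < t2")
  expect_error(suitable_area(matrix("meh", 1, 1), 1), "classified")
  # all scores below t1 -> zero suitable area
  cls0 <- classify_suitability(matrix(0.5, 3, 3), c(2, 4))
  expect_equal(suitable_area(cls0, 50), 0)
  # counting oracle on a random grid + monotone in thresholds
  set.seed(9)
  sc <- matrix(runif(64, 0, 6), 8, 8)
  for (th in list(c(1, 3), c(2, 4), c(3, 5))) {
    cls <- classify_suitability(sc, th)
    expect_equal(suitable_area(cls, 25), 25 * sum(sc >= th[1]))
  }
  a1 <- suitable_area(classify_suitability(sc, c(1, 3)), 1)
  a2 <- suitable_area(classify_suitability(sc, c(2, 4)), 1)
  expect_gte(a1, a2)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  g <- matrix(runif(30), 5, 6)
  g[c(3, 17)] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path, xllcorner = 112.5, yllcorner = 16.25, cellsize = 10)
  back <- read_asc(path)
  expect_equal(unclass_g(back), g, tolerance = 0)   # bit-exact
  expect_equal(attr(back, "cellsize"), 10)
  expect_equal(attr(back, "xllcorner"), 112.5)
  expect_error(read_asc(file.path(tempdir(), "nope.asc")), "not found")
})
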