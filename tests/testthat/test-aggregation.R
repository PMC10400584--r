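test_that("single-cell and symmetric two-cell counties get exact weights", {
  g <- makeGrid(2, 1, 1)
  # county = exactly the first cell
  cs <- countySet("one", "Midwest", 10, list(rectRing(0, 1, 0, 1)))
  w <- computeAreaWeights(g, cs)
  expect_equal(as.numeric(weightMatrix(w)), c(1, 0))
  # county straddling both cells symmetrically
  cs2 <- countySet("two", "Midwest", 10, list(rectRing(0.5, 1.5, 0, 1)))
  w2 <- computeAreaWeights(g, cs2)
  expect_equal(as.numeric(weightMatrix(w2)), c(0.5, 0.5))
  expect_equal(unname(coverageFraction(w2)), 1)
})

test_that("aggregation is the weighted mean of overlapped cells", {
  g <- makeGrid(2, 1, 1)
  exposure <- new("ExposureGrid", aot40 = matrix(c(4, 8), 1, 2),
                  window = exposureWindow("2020-05-01", "2020-08-01"),
                  threshold = 0.04, grid = g, naSkipped = 0L)
  # hand-built 1 x 2 weight row (0.25, 0.75): expect 0.25*4 + 0.75*8 = 7
  W <- new("AreaWeightMatrix",
           weights = Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2),
                                          x = c(0.25, 0.75), dims = c(1, 2)),
           countyId = "c", coverageFraction = 1, grid = g,
           outsideCounties = character(0))
  expect_equal(aggregateExposure(exposure, W)$aot40, 7.0)
  # uniform field: every county gets the field value
  uni <- new("ExposureGrid", aot40 = matrix(3.3, 1, 2),
             window = exposureWindow("2020-05-01", "2020-08-01"),
             threshold = 0.04, grid = g, naSkipped = 0L)
  expect_equal(aggregateExposure(uni, W)$aot40, 3.3)
})

test_that("county values are convex combinations of their cells", {
  g <- makeGrid(5, 4, 1)
  cs <- makeCounties(g, 3, 2, snap = FALSE, seed = 4)
  w <- computeAreaWeights(g, cs)
  expect_true(all(abs(Matrix::rowSums(weightMatrix(w)) - 1) < 1e-9))
  set.seed(99)
  field <- matrix(runif(20, 0, 30), 4, 5)
  exposure <- new("ExposureGrid", aot40 = field,
                  window = exposureWindow("2020-05-01", "2020-08-01"),
                  threshold = 0.04, grid = g, naSkipped = 0L)
  agg <- aggregateExposure(exposure, w)
  v <- as.vector(field)
  W <- weightMatrix(w)
  for (i in seq_len(nrow(agg))) {
    cells <- which(W[i, ] > 0)
    expect_gte(agg$aot40[i], min(v[cells]) - 1e-12)
    expect_lte(agg$aot40[i], max(v[cells]) + 1e-12)
  }
})

test_that("equal-area tiling makes the county mean equal the cell mean", {
  g <- makeGrid(4, 4, 1)
  cs <- makeCounties(g, 2, 2, snap = TRUE)
  w <- computeAreaWeights(g, cs)
  set.seed(7)
  field <- matrix(runif(16, 0, 20), 4, 4)
  exposure <- new("ExposureGrid", aot40 = field,
                  window = exposureWindow("2020-05-01", "2020-08-01"),
                  threshold = 0.04, grid = g, naSkipped = 0L)
  agg <- aggregateExposure(exposure, w)
  expect_equal(mean(agg$aot40), mean(field), tolerance = 1e-9)
})

test_that("area weights match the Monte-Carlo oracle on random polygons", {
  skip_if_not_installed("sp")
  g <- makeGrid(3, 3, 1)
  for (seed in 1:5) {
    poly <- randomSimplePolygon(seed)
    cs <- countySet("p", "Midwest", 1, list(poly))
    w <- computeAreaWeights(g, cs)
    mine <- as.numeric(weightMatrix(w))
    mc <- mcWeightsOracle(poly, g, n = 4e4, seed = seed + 100)
    expect_lt(max(abs(mine - mc)), 0.01)
  }
})

test_that("counties straddling or outside the domain edge are handled", {
  g <- makeGrid(2, 2, 1)
  cs <- countySet(c("edge", "out"), c("Midwest", "West"), c(10, 20),
                  list(rectRing(1.5, 2.5, 0, 1),    # half outside
                       rectRing(5, 6, 5, 6)))       # fully outside
  expect_message(w <- computeAreaWeights(g, cs), "fully outside")
  cf <- coverageFraction(w)
  expect_equal(unname(cf["edge"]), 0.5)
  expect_equal(unname(cf["out"]), 0)
  # the covered part is renormalised to weight 1
  expect_equal(Matrix::rowSums(weightMatrix(w))[1], 1, ignore_attr = TRUE)
  exposure <- new("ExposureGrid", aot40 = matrix(1:4, 2, 2),
                  window = exposureWindow("2020-05-01", "2020-08-01"),
                  threshold = 0.04, grid = g, naSkipped = 0L)
  expect_message(agg <- aggregateExposure(exposure, w), "excluded 1")
  expect_equal(agg$county_id, "edge")
})

test_that("aggregation orders agree exactly in the linear (all-exceeding) regime", {
  g <- makeGrid(3, 2, 1)
  set.seed(5)
  nt <- 48
  vals <- array(runif(nt * 6, 0.045, 0.09), c(nt, 2, 3))  # always > threshold
  times <- as.POSIXct("2020-05-01", tz = "UTC") + 3600 * (seq_len(nt) - 1)
  cube <- hourlyO3Grid(vals, times, g)
  cs <- makeCounties(g, 2, 1, snap = FALSE, seed = 2)
  w <- computeAreaWeights(g, cs)
  a <- countyAOT40(cube, w, order = "exposure_first")
  b <- countyAOT40(cube, w, order = "concentration_first")
  expect_equal(a$aot40, b$aot40, tolerance = 1e-10)
  # and differ in general, below-threshold hours present
  cube2 <- tinyCube(6, nx = 3, ny = 2)
  a2 <- countyAOT40(cube2, w, order = "exposure_first")
  b2 <- countyAOT40(cube2, w, order = "concentration_first")
  expect_false(isTRUE(all.equal(a2$aot40, b2$aot40, tolerance = 1e-12)))
})

test_that("mismatched grids are rejected", {
  g <- makeGrid(2, 2, 1)
  g2 <- makeGrid(2, 2, 2)
  cs <- makeCounties(g, 1, 1)
  w <- computeAreaWeights(g, cs)
  exposure <- new("ExposureGrid", aot40 = matrix(1, 2, 2),
                  window = exposureWindow("2020-05-01", "2020-08-01"),
                  threshold = 0.04, grid = g2, naSkipped = 0L)
  expect_error(aggregateExposure(exposure, w), "grid")
})
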