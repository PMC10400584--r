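baseGrid <- makeGrid(6, 5, 10)

test_that("identical seeds reproduce scenario fields exactly", {
  cfg <- scenarioFieldConfig(seed = 7, nDays = 3,
                             deltaRegions = defaultDeltaRegions(baseGrid))
  a <- generateScenarioFields(baseGrid, cfg)
  b <- generateScenarioFields(baseGrid, cfg)
  expect_identical(o3Values(a$BAU), o3Values(b$BAU))
  expect_identical(o3Values(a$C19), o3Values(b$C19))
  expect_identical(o3Times(a$BAU), o3Times(b$BAU))
  # and a different seed gives a different field
  c2 <- generateScenarioFields(baseGrid,
          scenarioFieldConfig(seed = 8, nDays = 3,
                              deltaRegions = defaultDeltaRegions(baseGrid)))
  expect_false(identical(o3Values(a$BAU), o3Values(c2$BAU)))
})

test_that("with no delta regions the two scenarios are identical", {
  cfg <- scenarioFieldConfig(seed = 1, nDays = 2, deltaRegions = NULL)
  f <- generateScenarioFields(baseGrid, cfg)
  expect_identical(o3Values(f$BAU), o3Values(f$C19))
})

test_that("a full-domain delta shifts the spatio-temporal mean exactly", {
  b <- domainBounds(baseGrid)
  whole <- rectRing(b["xmin"] - 1, b["xmax"] + 1, b["ymin"] - 1, b["ymax"] + 1)
  cfg <- scenarioFieldConfig(seed = 3, nDays = 2,
                             deltaRegions = list(list(polygon = whole,
                                                      offset = 0.003)))
  f <- generateScenarioFields(baseGrid, cfg)
  expect_equal(mean(o3Values(f$C19)) - mean(o3Values(f$BAU)), 0.003,
               tolerance = 1e-12)
  # per-cell, per-hour the shift is exact too
  expect_equal(max(abs(o3Values(f$C19) - o3Values(f$BAU) - 0.003)), 0,
               tolerance = 1e-15)
})

test_that("degenerate config (no noise, no diurnal cycle) is constant", {
  cfg <- scenarioFieldConfig(seed = 1, nDays = 1, baselineMean = 0.05,
                             diurnalAmplitude = 0, noiseSd = 0)
  f <- generateScenarioFields(baseGrid, cfg)
  expect_true(all(o3Values(f$BAU) == 0.05))
  expect_true(all(o3Values(f$C19) == 0.05))
})

test_that("negative values are clipped to zero with a logged count", {
  cfg <- scenarioFieldConfig(seed = 2, nDays = 1, baselineMean = 0.005,
                             diurnalAmplitude = 0.02, noiseSd = 0.01,
                             spatialCorrLength = 0)
  expect_message(f <- generateScenarioFields(baseGrid, cfg), "clipped")
  expect_gte(min(o3Values(f$BAU)), 0)
  expect_gte(min(o3Values(f$C19)), 0)
})

test_that("hour-of-day mean follows a mid-afternoon-peaked diurnal cycle", {
  cfg <- scenarioFieldConfig(seed = 5, nDays = 10, noiseSd = 0.001)
  f <- generateScenarioFields(baseGrid, cfg)
  hr <- as.integer(format(o3Times(f$BAU), "%H", tz = "UTC"))
  hourMean <- vapply(0:23, function(h)
    mean(o3Values(f$BAU)[hr == h, , ]), numeric(1))
  expect_equal(which.max(hourMean) - 1L, 15L)
  expect_equal(which.min(hourMean) - 1L, 3L)
})

test_that("overlapping delta polygons sum their offsets", {
  b <- domainBounds(baseGrid)
  whole <- rectRing(b["xmin"], b["xmax"], b["ymin"], b["ymax"])
  cfg <- scenarioFieldConfig(seed = 1, nDays = 1, noiseSd = 0,
    deltaRegions = list(list(polygon = whole, offset = 0.001),
                        list(polygon = whole, offset = 0.002)))
  f <- generateScenarioFields(baseGrid, cfg)
  dd <- as.vector(o3Values(f$C19) - o3Values(f$BAU))
  expect_true(all(abs(dd - 0.003) < 1e-12))
})

test_that("county tessellation covers the domain with valid geometry", {
  # one county spanning the whole domain
  one <- makeCounties(baseGrid, 1, 1)
  b <- domainBounds(baseGrid)
  expect_equal(polygonArea(countyPolygons(one)[[1]]),
               unname((b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"])))

  # snapped 2x2 tessellation of a 4x4 unit grid: each county = 4 cells
  g4 <- makeGrid(4, 4, 1)
  cs <- makeCounties(g4, 2, 2, snap = TRUE)
  expect_length(cs, 4L)
  w <- computeAreaWeights(g4, cs)
  expect_true(all(Matrix::rowSums(weightMatrix(w) > 0) == 4))
  expect_true(all(abs(weightMatrix(w)@x - 0.25) < 1e-12))

  # jittered tessellation still tiles: areas sum to the domain area
  cj <- makeCounties(baseGrid, 3, 2, snap = FALSE, seed = 9)
  areas <- vapply(countyPolygons(cj), polygonArea, numeric(1))
  b <- domainBounds(baseGrid)
  expect_equal(sum(areas), (b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"]),
               ignore_attr = TRUE)
  expect_true(all(countyRegions(cj) %in% REGIONS))
})

test_that("zero production is retained and withheld records are marked NA", {
  g4 <- makeGrid(4, 4, 1)
  cs <- makeCounties(g4, 2, 2, production = c(0, 100, 200, 300),
                     nWithheld = 1, seed = 3)
  expect_length(cs, 4L)
  expect_equal(sum(is.na(productionBu(cs))), 1L)
  expect_true(0 %in% productionBu(cs))
})

test_that("invalid county sets are rejected", {
  sq <- rectRing(0, 1, 0, 1)
  expect_error(countySet(c("a", "a"), c("Midwest", "West"), c(1, 2),
                         list(sq, sq)), "duplicate")
  expect_error(countySet("a", "Atlantis", 1, list(sq)), "unknown region")
  expect_error(countySet("a", "Midwest", -5, list(sq)), ">= 0")
})
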