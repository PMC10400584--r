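test_that("series AOT40 matches hand summation", {
  expect_equal(aot40Series(rep(0.05, 10)), 0.10)
  expect_equal(aot40Series(c(0.01, 0.04, 0.039, 0)), 0)     # all at/below threshold
  expect_equal(aot40Series(c(0.030, 0.045, 0.060, 0.041)),
               0.005 + 0.020 + 0.001)
  # a value exactly at the threshold contributes zero either way
  expect_equal(aot40Series(c(0.04, 0.04)), 0)
})

test_that("missing-hour policy is explicit and never rescales", {
  x <- c(0.05, NA, 0.06)
  expect_error(aot40Series(x), "missing")
  expect_message(v <- aot40Series(x, naAction = "skip"), "skipped 1")
  expect_equal(v, 0.01 + 0.02)   # sum over present hours, no rescaling
  expect_error(aot40Series(c(-0.01, 0.05)), "negative")
  expect_error(aot40Series(c(0.05), threshold = 0), "threshold")
})

test_that("AOT40 is monotone in each hourly value and in the threshold", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- runif(30, 0, 0.08)
    base <- aot40Series(x)
    i <- sample(30, 1)
    x2 <- x; x2[i] <- x2[i] + runif(1, 0, 0.02)
    expect_gte(aot40Series(x2), base)
    t1 <- runif(1, 0.01, 0.04); t2 <- t1 + runif(1, 0.001, 0.03)
    expect_gte(aot40Series(x, t1), aot40Series(x, t2))
  }
})

test_that("AOT40 is additive over adjoining windows", {
  cube <- tinyCube(11, nt = 72)
  t0 <- o3Times(cube)[1]
  w1 <- exposureWindow(t0, t0 + 24 * 3600)
  w2 <- exposureWindow(t0 + 24 * 3600, t0 + 72 * 3600)
  w  <- exposureWindow(t0, t0 + 72 * 3600)
  expect_equal(aot40Values(aot40Grid(cube, w1)) + aot40Values(aot40Grid(cube, w2)),
               aot40Values(aot40Grid(cube, w)), tolerance = 1e-12)
})

test_that("uniform and zero cubes give the expected exposure fields", {
  g <- makeGrid(2, 2, 1)
  nt <- 92 * 24
  times <- as.POSIXct("2020-05-01", tz = "UTC") + 3600 * (seq_len(nt) - 1)
  uni <- hourlyO3Grid(array(0.05, c(nt, 2, 2)), times, g)
  e <- aot40Grid(uni, exposureWindow("2020-05-01", "2020-08-01"))
  expect_equal(as.vector(aot40Values(e)), rep(0.01 * 2208, 4))
  zero <- hourlyO3Grid(array(0, c(nt, 2, 2)), times, g)
  expect_true(all(aot40Values(aot40Grid(zero)) == 0))
})

test_that("vectorised grid AOT40 equals the per-cell loop oracle", {
  for (seed in 1:10) {
    cube <- tinyCube(seed)
    got <- aot40Values(aot40Grid(cube))
    want <- aot40LoopOracle(o3Values(cube))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("hour-of-day subsetting restricts the accumulation", {
  cube <- tinyCube(21, nt = 48)
  w <- exposureWindow(o3Times(cube)[1], o3Times(cube)[48] + 3600,
                      hoursOfDay = 8:19)
  got <- aot40Values(aot40Grid(cube, w))
  hr <- as.integer(format(o3Times(cube), "%H", tz = "UTC"))
  want <- aot40LoopOracle(o3Values(cube)[hr %in% 8:19, , , drop = FALSE])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("windows outside the cube's range are rejected naming the span", {
  cube <- tinyCube(31, nt = 24)
  expect_error(aot40Grid(cube, exposureWindow("2020-04-30", "2020-05-02")),
               "missing span.*2020-04-30")
  expect_error(aot40Grid(cube, exposureWindow("2020-05-01", "2020-05-03")),
               "missing span")
})

test_that("unit conversion is canonical and rejects unknown tags", {
  expect_equal(convertUnits(40, "ppbV"), 0.040)
  expect_equal(convertUnits(0.04, "ppmV"), 0.04)
  expect_equal(convertUnits(3, "ppbV"), 0.003)
  expect_error(convertUnits(1, "mgm3"), "unknown")
  g <- makeGrid(1, 1, 1)
  times <- as.POSIXct("2020-05-01", tz = "UTC") + 3600 * (0:1)
  cube <- hourlyO3Grid(array(c(40, 50), c(2, 1, 1)), times, g, units = "ppbV")
  expect_equal(as.vector(o3Values(cube)), c(0.040, 0.050))
})

test_that("cube validity enforces cadence, shape and sign", {
  g <- makeGrid(2, 2, 1)
  times <- as.POSIXct("2020-05-01", tz = "UTC") + 3600 * (0:3)
  ok <- array(0.05, c(4, 2, 2))
  expect_silent(hourlyO3Grid(ok, times, g))
  expect_error(hourlyO3Grid(ok, times + c(0, 0, 0, 3600), g), "cadence")
  expect_error(hourlyO3Grid(array(-0.01, c(4, 2, 2)), times, g), "negative")
  expect_error(hourlyO3Grid(array(0.05, c(4, 2, 3)), times, g), "grid")
})
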