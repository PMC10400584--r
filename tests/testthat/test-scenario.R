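test_that("scenario differencing is exact, antisymmetric and guarded", {
  a <- handImpactTable(c(1, 2, 3), c(100, 200, 300))
  b <- handImpactTable(c(1.5, 2, 2.5), c(100, 200, 300))
  d0 <- scenarioDifference(a, a)
  expect_true(all(d0$delta_aot40 == 0) && all(d0$delta_loss_bu == 0))
  dab <- scenarioDifference(a, b)
  dba <- scenarioDifference(b, a)
  expect_equal(dab$delta_aot40, -dba$delta_aot40)
  expect_equal(dab$delta_loss_bu, -dba$delta_loss_bu)
  expect_equal(dab$delta_aot40, c(0.5, 0, -0.5))
  # hand-computed loss delta for county 1
  r1 <- 0.0113 * 1; r2 <- 0.0113 * 1.5
  expect_equal(dab$delta_loss_bu[1],
               100 * r2 / (1 - r2) - 100 * r1 / (1 - r1))
  # mismatched county sets are rejected, naming the difference
  b2 <- b; b2$county_id[1] <- "rogue"
  expect_error(scenarioDifference(a, b2), "rogue")
})

test_that("regional summaries report per-region delta ranges", {
  d <- data.frame(
    county_id = sprintf("c%d", 1:7),
    region = c("Midwest", "Midwest", "Midwest", "Southeast", "West",
               "Northeast", "Southwest"),
    production_bu = c(10, 10, 10, 10, 0, 10, 0),
    delta_aot40 = c(-2, 0, 3, 1, -1, 0.5, 0.2),
    delta_ryl = 0,
    delta_loss_bu = c(-20, 0, 30, 12, 0, 5, 0),
    delta_loss_usd = 0, stringsAsFactors = FALSE)
  s <- regionalSummary(d)
  mw <- s[s$region == "Midwest", ]
  expect_equal(c(mw$aot40_min, mw$aot40_max), c(-2, 3))
  expect_equal(c(mw$loss_bu_min, mw$loss_bu_max), c(-20, 30))
  # single-county regions have min = max
  se <- s[s$region == "Southeast", ]
  expect_equal(se$aot40_min, se$aot40_max)
  # crop-free regions report exposure ranges only
  expect_true(is.na(s[s$region == "West", "loss_bu_min"]))
  expect_true(is.na(s[s$region == "Southwest", "loss_bu_max"]))
  # brute-force group-by oracle for the exposure ranges
  for (r in unique(d$region)) {
    expect_equal(s[s$region == r, "aot40_min"],
                 min(d$delta_aot40[d$region == r]))
    expect_equal(s[s$region == r, "aot40_max"],
                 max(d$delta_aot40[d$region == r]))
  }
  d$region[1] <- "Atlantis"
  expect_error(regionalSummary(d), "unknown region")
})

test_that("reduction percentages divide loss by the reference production", {
  expect_equal(reductionPercent(5, 100), 5)
  expect_equal(reductionPercent(0, 100), 0)
  expect_equal(reductionPercent(721006, 4216302000), 100 * 721006 / 4216302000)
  expect_error(reductionPercent(5, 0), "positive")
})

test_that("sign shares partition producing counties into three bins", {
  mk <- function(deltas, prod = rep(1, length(deltas)))
    data.frame(county_id = as.character(seq_along(deltas)),
               region = "Midwest", production_bu = prod,
               delta_loss_bu = deltas)
  expect_equal(countSignShares(mk(c(1, 2, 3))),
               c(increased = 100, improved = 0, unchanged = 0))
  expect_equal(countSignShares(mk(c(1, -1))),
               c(increased = 50, improved = 50, unchanged = 0))
  s <- countSignShares(mk(c(1, -1, 0, 0)))
  expect_equal(unname(sum(s)), 100)
  expect_equal(unname(s["unchanged"]), 50)
  # zero-production counties are excluded from the shares
  s2 <- countSignShares(mk(c(1, -1, 5), prod = c(1, 1, 0)))
  expect_equal(unname(s2["increased"]), 50)
  expect_error(countSignShares(mk(0, prod = 0)), "nonzero production")
})

test_that("report totals conserve county sums and value money after summing", {
  set.seed(42)
  for (k in 1:5) {
    n <- sample(5:20, 1)
    regions <- sample(REGIONS[1:3], n, replace = TRUE)
    a <- handImpactTable(runif(n, 0, 4), runif(n, 1e4, 1e6), regions)
    b <- handImpactTable(runif(n, 0, 4), a$production_bu, regions)
    rep <- buildScenarioReport(a, b)
    tot <- scenarioTotals(rep)
    # conservation: totals equal the sum of county losses, and the sum of
    # regional member sums, exactly (same left-to-right order)
    expect_identical(tot$total_loss_bu[1], sum(a$loss_bu))
    expect_identical(tot$total_loss_bu[2], sum(b$loss_bu))
    regSum <- sum(vapply(split(a$loss_bu, a$region), sum, numeric(1)))
    expect_equal(regSum, tot$total_loss_bu[1], tolerance = 1e-12)
    # self-consistency: gain equals price times the bushel difference
    # recomputed from the per-county table
    ov <- overallSummary(rep)
    expect_equal(ov$production_gain_usd,
                 (sum(a$loss_bu) - sum(b$loss_bu)) * 9.0075,
                 tolerance = 1e-9)
    expect_equal(ov$difference_in_reduction_percent,
                 tot$reduction_percent[1] - tot$reduction_percent[2],
                 tolerance = 1e-12)
    shares <- c(ov$share_counties_increased, ov$share_counties_improved,
                ov$share_counties_unchanged)
    expect_equal(sum(shares), 100)
  }
})
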