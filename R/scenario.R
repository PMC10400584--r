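# Scenario comparison: per-county differencing, regional ranges,
# domain-wide totals, reduction percentages and sign shares.

#' Per-county differences between two scenario impact tables
#'
#' Computes \code{b - a} for every numeric impact column (antisymmetric
#' by construction). The two tables must cover exactly the same counties
#' with the same production.
#'
#' @param tableA,tableB impact tables from [countyImpacts()] (e.g. a
#'   business-as-usual reference and a perturbed scenario; the deltas are
#'   then perturbed minus reference).
#' @return data.frame with \code{county_id}, \code{region},
#'   \code{production_bu} and \code{delta_aot40}, \code{delta_ryl},
#'   \code{delta_loss_bu}, \code{delta_loss_usd}.
#' @export
scenarioDifference <- function(tableA, tableB) {
  onlyA <- setdiff(tableA$county_id, tableB$county_id)
  onlyB <- setdiff(tableB$county_id, tableA$county_id)
  if (length(onlyA) || length(onlyB))
    stop("impact tables cover different counties; only in first: {",
         paste(onlyA, collapse = ", "), "}; only in second: {",
         paste(onlyB, collapse = ", "), "}")
  m <- match(tableA$county_id, tableB$county_id)
  B <- tableB[m, , drop = FALSE]
  if (!isTRUE(all.equal(tableA$production_bu, B$production_bu)))
    stop("production differs between scenario tables for the same counties")
  data.frame(county_id = tableA$county_id, region = tableA$region,
             production_bu = tableA$production_bu,
             delta_aot40 = B$aot40 - tableA$aot40,
             delta_ryl = B$ryl - tableA$ryl,
             delta_loss_bu = B$loss_bu - tableA$loss_bu,
             delta_loss_usd = B$loss_usd - tableA$loss_usd,
             stringsAsFactors = FALSE)
}

#' Regional (min, max) ranges of scenario deltas
#'
#' Exposure-delta ranges cover all member counties; yield-loss ranges
#' cover only counties with nonzero production, and regions with no
#' producing counties report the exposure range only (loss range NA),
#' mirroring how crop-free regions appear in regional summaries.
#'
#' @param deltas data.frame from [scenarioDifference()].
#' @return data.frame, one row per region present, with columns
#'   \code{region}, \code{n_counties}, \code{aot40_min}, \code{aot40_max},
#'   \code{loss_bu_min}, \code{loss_bu_max}.
#' @export
regionalSummary <- function(deltas) {
  bad <- setdiff(unique(deltas$region), REGIONS)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  regions <- REGIONS[REGIONS %in% deltas$region]
  rows <- lapply(regions, function(r) {
    d <- deltas[deltas$region == r, , drop = FALSE]
    crop <- d[d$production_bu > 0, , drop = FALSE]
    data.frame(region = r, n_counties = nrow(d),
               aot40_min = min(d$delta_aot40),
               aot40_max = max(d$delta_aot40),
               loss_bu_min = if (nrow(crop)) min(crop$delta_loss_bu) else NA_real_,
               loss_bu_max = if (nrow(crop)) max(crop$delta_loss_bu) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Production reduction percentage
#'
#' The fraction of total yield loss to a reference annual production,
#' in percent.
#'
#' @param totalLossBu total loss, bushels.
#' @param referenceProductionBu reference production, bushels > 0.
#' @return \code{100 * loss / reference}.
#' @export
reductionPercent <- function(totalLossBu, referenceProductionBu) {
  if (length(referenceProductionBu) != 1L || !is.finite(referenceProductionBu) ||
      referenceProductionBu <= 0)
    stop("reference production must be a single positive number")
  100 * totalLossBu / referenceProductionBu
}

#' Shares of counties with increased / improved / unchanged losses
#'
#' Over counties with nonzero production, the percentage whose loss
#' delta is positive (increased loss), negative (improved), and exactly
#' zero (unchanged). Zero deltas form their own bin and are excluded
#' from the two headline shares; the three shares sum to 100.
#'
#' @param deltas data.frame from [scenarioDifference()].
#' @return Named numeric: \code{increased}, \code{improved},
#'   \code{unchanged} (percent).
#' @export
countSignShares <- function(deltas) {
  d <- deltas[deltas$production_bu > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no counties with nonzero production")
  n <- nrow(d)
  c(increased = 100 * sum(d$delta_loss_bu > 0) / n,
    improved  = 100 * sum(d$delta_loss_bu < 0) / n,
    unchanged = 100 * sum(d$delta_loss_bu == 0) / n)
}

#' Assemble a full scenario comparison report
#'
#' Totals are formed by summing county bushel losses per scenario (in
#' county order, so regional and domain totals are exactly consistent);
#' money is valued after summation, i.e. the production gain is
#' \code{(totalLoss_A - totalLoss_B) * price}. Reduction percentages
#' divide each scenario's total loss by the reference production, which
#' defaults to the summed production of the included (non-withheld)
#' counties.
#'
#' @param tableA,tableB impact tables from [countyImpacts()]; A is the
#'   reference (e.g. business-as-usual), B the perturbed scenario.
#' @param labels character(2) scenario labels for (A, B).
#' @param price USD per bushel; default 9.0075.
#' @param referenceProductionBu denominator for reduction percentages;
#'   default \code{sum(tableA$production_bu)}.
#' @return A [ScenarioReport-class].
#' @export
buildScenarioReport <- function(tableA, tableB, labels = c("BAU", "C19"),
                                price = 9.0075,
                                referenceProductionBu = NULL) {
  deltas <- scenarioDifference(tableA, tableB)
  if (is.null(referenceProductionBu))
    referenceProductionBu <- sum(tableA$production_bu)
  totalA <- sum(tableA$loss_bu)
  totalB <- sum(tableB$loss_bu)
  totals <- data.frame(
    scenario = labels,
    total_loss_bu = c(totalA, totalB),
    mean_loss_bu = c(mean(tableA$loss_bu), mean(tableB$loss_bu)),
    total_loss_usd = economicLossUsd(c(totalA, totalB), price),
    reduction_percent = c(reductionPercent(totalA, referenceProductionBu),
                          reductionPercent(totalB, referenceProductionBu)),
    stringsAsFactors = FALSE)
  shares <- countSignShares(deltas)
  gainBu <- totalA - totalB   # negative if the perturbed scenario loses more
  overall <- list(
    production_gain_bu = gainBu,
    production_gain_usd = sign(gainBu) * economicLossUsd(abs(gainBu), price),
    difference_in_reduction_percent =
      totals$reduction_percent[1L] - totals$reduction_percent[2L],
    reference_production_bu = referenceProductionBu,
    share_counties_increased = unname(shares["increased"]),
    share_counties_improved = unname(shares["improved"]),
    share_counties_unchanged = unname(shares["unchanged"]))
  new("ScenarioReport", labels = labels, countyDeltas = deltas,
      regional = regionalSummary(deltas), totals = totals,
      overall = overall, price = price)
}

#' @rdname scenarioReport-accessors
#' @param x a [ScenarioReport-class].
#' @return \code{countyDeltas}: per-county differences;
#'   \code{regionalRanges}: per-region (min, max) ranges;
#'   \code{scenarioTotals}: one row per scenario;
#'   \code{overallSummary}: named list of domain-wide numbers.
#' @export
setMethod("countyDeltas", "ScenarioReport", function(x) x@countyDeltas)

#' @rdname scenarioReport-accessors
#' @export
setMethod("regionalRanges", "ScenarioReport", function(x) x@regional)

#' @rdname scenarioReport-accessors
#' @export
setMethod("scenarioTotals", "ScenarioReport", function(x) x@totals)

#' @rdname scenarioReport-accessors
#' @export
setMethod("overallSummary", "ScenarioReport", function(x) x@overall)

setMethod("show", "ScenarioReport", function(object) {
  o <- object@overall
  cat("ScenarioReport:", object@labels[2L], "-", object@labels[1L],
      "over", nrow(object@countyDeltas), "counties\n\n")
  cat("Totals (price $", format(object@price), "/Bu):\n", sep = "")
  print(object@totals, row.names = FALSE)
  cat("\nRegional delta ranges:\n")
  print(object@regional, row.names = FALSE)
  cat(sprintf("\nProduction gain: %s Bu = $%s\n",
              format(round(o$production_gain_bu), big.mark = ","),
              format(round(o$production_gain_usd, 2), big.mark = ",")))
  cat(sprintf("Difference in reduction: %.3f%%\n",
              o$difference_in_reduction_percent))
  cat(sprintf("Counties: %.0f%% increased loss, %.0f%% improved, %.0f%% unchanged\n",
              o$share_counties_increased, o$share_counties_improved,
              o$share_counties_unchanged))
})
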