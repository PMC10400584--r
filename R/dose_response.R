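# Dose-response stage: linear AOT40 -> relative yield loss, then bushel
# and dollar losses per county.

RYL_CAP <- 1 - 1e-9   # keep the compensated loss formula finite

#' Dose-response and valuation parameters
#'
#' @param a slope of the linear AOT40 dose-response, per ppmV hr;
#'   default 0.0113, the soybean coefficient from exposure-yield field
#'   studies.
#' @param convention how relative yield loss combines with observed
#'   production. \code{"compensated"} (default) treats observed
#'   production as post-damage: \code{loss = P * RYL / (1 - RYL)};
#'   \code{"simple"} applies RYL directly: \code{loss = P * RYL}.
#' @param priceUsdPerBu market price, USD per bushel; default 9.0075
#'   (U.S. soybean price, August 2020).
#' @return Validated parameter list of class \code{"DoseResponseParams"}.
#' @export
doseResponseParams <- function(a = 0.0113,
                               convention = c("compensated", "simple"),
                               priceUsdPerBu = 9.0075) {
  convention <- match.arg(convention)
  stopifnot(length(a) == 1L, is.finite(a), a > 0,
            length(priceUsdPerBu) == 1L, is.finite(priceUsdPerBu),
            priceUsdPerBu >= 0)
  structure(list(a = a, convention = convention,
                 priceUsdPerBu = priceUsdPerBu),
            class = "DoseResponseParams")
}

#' Relative yield loss from AOT40 exposure
#'
#' Linear dose-response \code{RYL = a * AOT40}, capped strictly below 1
#' so the compensated loss formula stays finite; hitting the cap is
#' reported loudly since it means exposure far outside the calibrated
#' range.
#'
#' @param aot40 numeric, ppmV hr, >= 0.
#' @param a slope, default 0.0113.
#' @return Fraction(s) in [0, 1).
#' @examples
#' relativeYieldLoss(1)    # 0.0113
#' relativeYieldLoss(10)   # 0.113
#' @export
relativeYieldLoss <- function(aot40, a = 0.0113) {
  if (any(!is.finite(aot40)) || any(aot40 < 0))
    stop("aot40 must be finite and >= 0")
  ryl <- a * aot40
  nCap <- sum(ryl >= RYL_CAP)
  if (nCap > 0L) {
    warning("relativeYieldLoss: ", nCap,
            " value(s) capped just below 1; exposure is far outside the ",
            "calibrated dose-response range")
    ryl <- pmin(ryl, RYL_CAP)
  }
  ryl
}

#' Production loss in bushels
#'
#' Under \code{"compensated"}, observed production is what survived the
#' damage, so the lost amount is \code{P * RYL / (1 - RYL)}; under
#' \code{"simple"} it is \code{P * RYL}. Compensated >= simple, with
#' equality only at RYL = 0.
#'
#' @param production observed production, bushels >= 0.
#' @param ryl relative yield loss fraction(s) in [0, 1).
#' @param convention \code{"compensated"} (default) or \code{"simple"}.
#' @return Loss in bushels.
#' @examples
#' productionLossBu(1000, 0.5)                        # 1000
#' productionLossBu(1000, 0.0113, "simple")           # 11.3
#' @export
productionLossBu <- function(production, ryl,
                             convention = c("compensated", "simple")) {
  convention <- match.arg(convention)
  if (any(production < 0, na.rm = TRUE))
    stop("production must be >= 0")
  if (any(ryl < 0 | ryl >= 1))
    stop("ryl must lie in [0, 1)")
  if (convention == "compensated") production * ryl / (1 - ryl)
  else production * ryl
}

#' Economic loss in USD
#'
#' @param lossBu loss in bushels, >= 0.
#' @param price USD per bushel, >= 0; default 9.0075.
#' @return USD (full floating precision; round to cents for display).
#' @examples
#' economicLossUsd(1)   # 9.0075
#' @export
economicLossUsd <- function(lossBu, price = 9.0075) {
  if (any(lossBu < 0, na.rm = TRUE) || any(price < 0))
    stop("lossBu and price must be >= 0")
  lossBu * price
}

#' Per-county impacts for one scenario
#'
#' Joins county exposures with production, applies the dose-response and
#' valuation, and drops withheld (production NA) counties with a logged
#' count. Zero-production counties are retained and contribute zero
#' loss.
#'
#' @param countyExposure data.frame from [aggregateExposure()] /
#'   [countyAOT40()] (columns \code{county_id}, \code{aot40}).
#' @param counties the [CountySet-class] supplying region and production.
#' @param params a [doseResponseParams()] list.
#' @return data.frame with columns \code{county_id}, \code{region},
#'   \code{production_bu}, \code{aot40}, \code{ryl}, \code{loss_bu},
#'   \code{loss_usd}.
#' @export
countyImpacts <- function(countyExposure, counties,
                          params = doseResponseParams()) {
  stopifnot(is.data.frame(countyExposure), is(counties, "CountySet"),
            inherits(params, "DoseResponseParams"))
  m <- match(countyExposure$county_id, counties@countyId)
  if (anyNA(m))
    stop("exposure table contains unknown county id(s): ",
         paste(countyExposure$county_id[is.na(m)], collapse = ", "))
  prod <- counties@productionBu[m]
  withheld <- is.na(prod)
  if (any(withheld))
    message("countyImpacts: excluded ", sum(withheld),
            " combined/withheld county(ies) with no attributable production")
  out <- data.frame(county_id = countyExposure$county_id,
                    region = counties@region[m],
                    production_bu = prod,
                    aot40 = countyExposure$aot40,
                    stringsAsFactors = FALSE)[!withheld, , drop = FALSE]
  out$ryl <- relativeYieldLoss(out$aot40, params$a)
  out$loss_bu <- productionLossBu(out$production_bu, out$ryl,
                                  params$convention)
  out$loss_usd <- economicLossUsd(out$loss_bu, params$priceUsdPerBu)
  rownames(out) <- NULL
  out
}
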