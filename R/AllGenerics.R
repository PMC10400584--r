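#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix rowSums colSums t
NULL

#' @rdname cellCenters
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname domainBounds
#' @export
setGeneric("domainBounds", function(x) standardGeneric("domainBounds"))

#' @rdname countyIds
#' @export
setGeneric("countyIds", function(x) standardGeneric("countyIds"))

#' @rdname countyRegions
#' @export
setGeneric("countyRegions", function(x) standardGeneric("countyRegions"))

#' @rdname productionBu
#' @export
setGeneric("productionBu", function(x) standardGeneric("productionBu"))

#' @rdname countyPolygons
#' @export
setGeneric("countyPolygons", function(x) standardGeneric("countyPolygons"))

#' @rdname o3Values
#' @export
setGeneric("o3Values", function(x) standardGeneric("o3Values"))

#' @rdname o3Times
#' @export
setGeneric("o3Times", function(x) standardGeneric("o3Times"))

#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname aot40Values
#' @export
setGeneric("aot40Values", function(x) standardGeneric("aot40Values"))

#' @rdname weightMatrix
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname coverageFraction
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))

#' @rdname scenarioReport-accessors
#' @export
setGeneric("countyDeltas", function(x) standardGeneric("countyDeltas"))

#' @rdname scenarioReport-accessors
#' @export
setGeneric("regionalRanges", function(x) standardGeneric("regionalRanges"))

#' @rdname scenarioReport-accessors
#' @export
setGeneric("scenarioTotals", function(x) standardGeneric("scenarioTotals"))

#' @rdname scenarioReport-accessors
#' @export
setGeneric("overallSummary", function(x) standardGeneric("overallSummary"))

#' @rdname convertUnits
#' @export
setGeneric("convertUnits", function(x, from) standardGeneric("convertUnits"))
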