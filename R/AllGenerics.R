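#' @import methods
NULL

#' @rdname HlaDosageSet-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname HlaDosageSet-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname ConditionalLedger-class
#' @export
setGeneric("rounds", function(x) standardGeneric("rounds"))

#' @rdname ConditionalLedger-class
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname QCReport-class
#' @export
setGeneric("removedSamples", function(x) standardGeneric("removedSamples"))

#' @rdname QCReport-class
#' @export
setGeneric("removedMarkers", function(x) standardGeneric("removedMarkers"))

#' @rdname AlleleProteinMap-class
#' @export
setGeneric("mapEntries", function(x) standardGeneric("mapEntries"))

#' @rdname AlleleProteinMap-class
#' @export
setGeneric("mappedPositions", function(x, locus) standardGeneric("mappedPositions"))

#' @rdname AlleleProteinMap-class
#' @export
setGeneric("residueAt", function(x, allele, position) standardGeneric("residueAt"))
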