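#' @rdname AmpliconLocus-class
#' @param x an object.
#' @export
setGeneric("protospacer", function(x) standardGeneric("protospacer"))

#' @rdname AmpliconLocus-class
#' @export
setGeneric("referenceSequence", function(x) standardGeneric("referenceSequence"))

#' @rdname PositionFrequencyTable-class
#' @param x an object.
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))

#' @rdname PositionFrequencyTable-class
#' @export
setGeneric("baseFrequencies", function(x) standardGeneric("baseFrequencies"))

#' @rdname PositionFrequencyTable-class
#' @export
setGeneric("positionCoverage", function(x) standardGeneric("positionCoverage"))

#' @rdname PositionFrequencyTable-class
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))

#' @rdname PositionFrequencyTable-class
#' @export
setGeneric("errorRates", function(x) standardGeneric("errorRates"))

#' @rdname PositionFrequencyTable-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname PanelSample-class
#' @param x an object.
#' @param site site name or index.
#' @export
setGeneric("siteTable", function(x, site) standardGeneric("siteTable"))

#' @rdname PanelSample-class
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))

#' @rdname PanelSample-class
#' @export
setGeneric("siteReads", function(x) standardGeneric("siteReads"))

#' @rdname PanelSample-class
#' @export
setGeneric("isPretreatment", function(x) standardGeneric("isPretreatment"))
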