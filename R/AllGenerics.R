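#' @rdname ReferenceMapping-class
#' @param x an object.
#' @export
setGeneric("refId", function(x) standardGeneric("refId"))

#' @rdname ReferenceMapping-class
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname ReferenceMapping-class
#' @export
setGeneric("columnToResidue", function(x) standardGeneric("columnToResidue"))

#' @rdname ColumnProfiles-class
#' @param x an object.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname ColumnProfiles-class
#' @export
setGeneric("profileFrequencies", function(x) standardGeneric("profileFrequencies"))

#' @rdname ColumnProfiles-class
#' @export
setGeneric("nEffective", function(x) standardGeneric("nEffective"))

#' @rdname ColumnProfiles-class
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))

#' @rdname ColumnProfiles-class
#' @export
setGeneric("allGapColumns", function(x) standardGeneric("allGapColumns"))

#' @rdname ConstructDesign-class
#' @param x an object.
#' @export
setGeneric("designName", function(x) standardGeneric("designName"))

#' @rdname ConstructDesign-class
#' @export
setGeneric("designThreshold", function(x) standardGeneric("designThreshold"))

#' @rdname ConstructDesign-class
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname ConstructDesign-class
#' @export
setGeneric("constructSequence", function(x) standardGeneric("constructSequence"))

#' @rdname ConstructDesign-class
#' @export
setGeneric("mutationCount", function(x) standardGeneric("mutationCount"))

#' @rdname ConstructDesign-class
#' @export
setGeneric("mutationPercent", function(x) standardGeneric("mutationPercent"))

#' @rdname PanelReport-class
#' @param x an object.
#' @export
setGeneric("panelConstructs", function(x) standardGeneric("panelConstructs"))

#' @rdname PanelReport-class
#' @export
setGeneric("skippedPositions", function(x) standardGeneric("skippedPositions"))
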