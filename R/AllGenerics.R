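#' @rdname SgRNALibrary-class
#' @param x,object an object.
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname SgRNALibrary-class
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' @rdname SgRNALibrary-class
#' @export
setGeneric("guideData", function(x) standardGeneric("guideData"))

#' @rdname SgRNALibrary-class
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))

#' @rdname Amplicon-class
#' @export
setGeneric("predictCutSite", function(x) standardGeneric("predictCutSite"))

#' @rdname SimulatedScreen-class
#' @export
setGeneric("screenCounts", function(x) standardGeneric("screenCounts"))

#' @rdname SimulatedScreen-class
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname SimulatedScreen-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
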