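#' @export
setGeneric("arrayChrom", function(x) standardGeneric("arrayChrom"))

#' @export
setGeneric("arraySeq", function(x) standardGeneric("arraySeq"))

#' @export
setGeneric("arrayRegions", function(x) standardGeneric("arrayRegions"))

#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @export
setGeneric("identities", function(x) standardGeneric("identities"))

#' @export
setGeneric("blockRanges", function(x) standardGeneric("blockRanges"))

#' @export
setGeneric("horPatterns", function(x) standardGeneric("horPatterns"))

#' @export
setGeneric("horUnits", function(x) standardGeneric("horUnits"))
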