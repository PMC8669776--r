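#' @export
setGeneric("pvalues", function(object, ...) standardGeneric("pvalues"))

#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @export
setGeneric("fdrs", function(object) standardGeneric("fdrs"))

#' @export
setGeneric("adjustedPValues", function(object) standardGeneric("adjustedPValues"))

#' @export
setGeneric("rejectFlags", function(object) standardGeneric("rejectFlags"))

#' @export
setGeneric("lowerBoundFDR", function(object, ...) standardGeneric("lowerBoundFDR"))

#' @export
setGeneric("pi0Value", function(object) standardGeneric("pi0Value"))

#' @export
setGeneric("adjustMethod", function(object) standardGeneric("adjustMethod"))

#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))

#' @export
setGeneric("nullLabels", function(object) standardGeneric("nullLabels"))
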