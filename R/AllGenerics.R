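#' @title Generics for collagenSHG classes
#' @name collagenSHG-generics
#' @keywords internal
NULL

#' @describeIn SHGImage-class pixel matrix accessor
#' @param x an object
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @describeIn SHGImage-class bit depth accessor (8 or 16)
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @describeIn SHGImage-class provenance label accessor
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
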