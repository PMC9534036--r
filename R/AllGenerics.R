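#' @include AllClasses.R
NULL

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @export
setGeneric("uninhabitedCode", function(x) standardGeneric("uninhabitedCode"))

#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @export
setGeneric("geometries", function(x) standardGeneric("geometries"))

#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @export
setGeneric("unitData", function(x) standardGeneric("unitData"))

#' @export
setGeneric("crsOf", function(x) standardGeneric("crsOf"))
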