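#' @include AllClasses.R
NULL

#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @export
setGeneric("fluoSpectra", function(x, ...) standardGeneric("fluoSpectra"))

#' @export
setGeneric("refSpectra", function(x, ...) standardGeneric("refSpectra"))

#' @export
setGeneric("ppixConc", function(x, ...) standardGeneric("ppixConc"))

#' @export
setGeneric("groupIds", function(x, ...) standardGeneric("groupIds"))

#' @export
setGeneric("unitTags", function(x, ...) standardGeneric("unitTags"))

#' @export
setGeneric("spectraGrid", function(x, ...) standardGeneric("spectraGrid"))

#' @export
setGeneric("endmemberMatrix", function(x, ...) standardGeneric("endmemberMatrix"))

#' @export
setGeneric("endmemberNames", function(x, ...) standardGeneric("endmemberNames"))

#' @export
setGeneric("cubeData", function(x, ...) standardGeneric("cubeData"))

#' @export
setGeneric("cubeRole", function(x, ...) standardGeneric("cubeRole"))

#' @export
setGeneric("modelKind", function(x, ...) standardGeneric("modelKind"))

#' @export
setGeneric("trainingHistory", function(x, ...) standardGeneric("trainingHistory"))

#' @export
setGeneric("lossWeights", function(x, ...) standardGeneric("lossWeights"))
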