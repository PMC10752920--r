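#' @import methods
NULL

#' @export
setGeneric("scaleLevels", function(x, ...) standardGeneric("scaleLevels"))

#' @export
setGeneric("scaleSigma", function(x, ...) standardGeneric("scaleSigma"))

#' @export
setGeneric("gridDownsample", function(x, ...) standardGeneric("gridDownsample"))

#' @export
setGeneric("smoothedImage", function(x, ...) standardGeneric("smoothedImage"))

#' @export
setGeneric("laplacianResponse", function(x, ...) standardGeneric("laplacianResponse"))

#' @export
setGeneric("densityGrid", function(x, ...) standardGeneric("densityGrid"))

#' @export
setGeneric("modelPoints", function(x, ...) standardGeneric("modelPoints"))

#' @export
setGeneric("nImages", function(x, ...) standardGeneric("nImages"))

#' @export
setGeneric("modelScales", function(x, ...) standardGeneric("modelScales"))

#' @export
setGeneric("classifiers", function(x, ...) standardGeneric("classifiers"))

#' @export
setGeneric("fixationRecords", function(x, ...) standardGeneric("fixationRecords"))
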