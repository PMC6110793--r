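#' @rdname HyperCube-accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @rdname HyperCube-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname HyperCube-accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname HyperCube-accessors
#' @export
setGeneric("pixelSizeMM", function(x) standardGeneric("pixelSizeMM"))

#' @rdname HyperCube-accessors
#' @export
setGeneric("trackID", function(x) standardGeneric("trackID"))

#' @rdname HyperCube-accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname SpectralLibrary-accessors
#' @export
setGeneric("entryIDs", function(x) standardGeneric("entryIDs"))

#' @rdname ClassificationMap-accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname ClassificationMap-accessors
#' @export
setGeneric("classLegend", function(x) standardGeneric("classLegend"))

#' @rdname ClassificationMap-accessors
#' @export
setGeneric("backgroundCategories",
           function(x) standardGeneric("backgroundCategories"))
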