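#' Construct a HyperCube
#'
#' @param values numeric array, lines x samples x bands, nonnegative and
#'   finite. Integer raw counts are accepted and stored as doubles.
#' @param wavelengths numeric, band-center wavelengths in nm, strictly
#'   increasing, one per band.
#' @param pixelSizeMM positive scalar pixel size in mm (default 1, the
#'   instrument's output resolution).
#' @param stage processing stage, one of "raw", "radiance",
#'   "pseudo_reflectance", "smoothed".
#' @param trackID survey-track identifier.
#'
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- HyperCube(array(1, c(2, 3, 4)), wavelengths = c(400, 450, 500, 550))
#' dim(cube)
#' @export
HyperCube <- function(values, wavelengths, pixelSizeMM = 1.0,
                      stage = "raw", trackID = "") {
  storage.mode(values) <- "double"
  new("HyperCube", values = values, wavelengths = as.numeric(wavelengths),
      pixelSizeMM = pixelSizeMM, stage = stage, trackID = trackID)
}

#' Accessors for HyperCube objects
#'
#' @param x a [HyperCube-class].
#' @return `cubeValues` the lines x samples x bands array; `wavelengths`
#'   the band centers in nm; `stage` the processing-stage tag;
#'   `pixelSizeMM` the pixel size; `trackID` the track identifier;
#'   `nBands` the number of spectral bands.
#' @name HyperCube-accessors
#' @aliases cubeValues wavelengths stage pixelSizeMM trackID nBands
NULL

#' @rdname HyperCube-accessors
#' @export
setMethod("cubeValues", "HyperCube", function(x) x@values)

#' @rdname HyperCube-accessors
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @rdname HyperCube-accessors
#' @export
setMethod("wavelengths", "SpectralLibrary", function(x) x@wavelengths)

#' @rdname HyperCube-accessors
#' @export
setMethod("stage", "HyperCube", function(x) x@stage)

#' @rdname HyperCube-accessors
#' @export
setMethod("pixelSizeMM", "HyperCube", function(x) x@pixelSizeMM)

#' @rdname HyperCube-accessors
#' @export
setMethod("trackID", "HyperCube", function(x) x@trackID)

#' @rdname HyperCube-accessors
#' @export
setMethod("nBands", "HyperCube", function(x) dim(x@values)[3L])

#' @describeIn HyperCube-accessors cube dimensions (lines, samples, bands)
#' @export
setMethod("dim", "HyperCube", function(x) dim(x@values))

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("HyperCube: %d lines x %d samples x %d bands\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  wavelengths: %.2f - %.2f nm | stage: %s | pixel: %g mm",
              min(object@wavelengths), max(object@wavelengths),
              object@stage, object@pixelSizeMM))
  if (nzchar(object@trackID)) cat(sprintf(" | track: %s", object@trackID))
  cat("\n")
})

setMethod("show", "SpectralLibrary", function(object) {
  cats <- vapply(object@entries, function(e) e@category, character(1))
  cat(sprintf("SpectralLibrary: %d entries, %d categories, %d bands (%.1f-%.1f nm)\n",
              length(object@entries), length(unique(cats)),
              length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult '%s': best '%s' (%s), theta_min = %.2f deg over %d entries\n",
              object@queryID, object@bestEntry, object@bestCategory,
              object@thetaMin, length(object@angles)))
})

setMethod("show", "ClassificationMap", function(object) {
  tab <- table(factor(object@legend[as.character(object@labels)],
                      levels = object@legend))
  cat(sprintf("ClassificationMap: %d x %d pixels, %d categories\n",
              nrow(object@labels), ncol(object@labels), length(object@legend)))
  for (nm in names(tab))
    cat(sprintf("  %-28s %d px\n", nm, tab[[nm]]))
})

setMethod("show", "SurveySummary", function(object) {
  cat(sprintf("SurveySummary: %d OOIs over %.1f m2\n",
              object@total, object@areaM2))
  for (nm in names(object@counts))
    cat(sprintf("  %-28s %4d  (%.2f m-2)\n", nm, object@counts[[nm]],
                object@densities[[nm]]))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d x %d px, %d objects (%d background nodules)\n",
              nrow(object@labels), ncol(object@labels),
              nrow(object@objects), sum(object@objects$background)))
})

#' Accessors for SpectralLibrary objects
#'
#' @param x a [SpectralLibrary-class].
#' @return `entries` the list of [ReferenceSpectrum-class]; `categories`
#'   the per-entry category vector; `entryIDs` the per-entry ooiIDs.
#' @name SpectralLibrary-accessors
#' @aliases entries categories entryIDs
NULL

#' @rdname SpectralLibrary-accessors
#' @export
setMethod("entries", "SpectralLibrary", function(x) x@entries)

#' @rdname SpectralLibrary-accessors
#' @export
setMethod("categories", "SpectralLibrary",
          function(x) vapply(x@entries, function(e) e@category, character(1)))

#' @rdname SpectralLibrary-accessors
#' @export
setMethod("entryIDs", "SpectralLibrary",
          function(x) vapply(x@entries, function(e) e@ooiID, character(1)))

#' @describeIn SpectralLibrary-accessors number of entries
#' @export
setMethod("length", "SpectralLibrary", function(x) length(x@entries))

#' Accessors for ClassificationMap objects
#'
#' @param x a [ClassificationMap-class].
#' @return `labelMatrix` the integer label raster; `classLegend` the named
#'   integer-to-category map; `backgroundCategories` the category names
#'   treated as seafloor background.
#' @name ClassificationMap-accessors
#' @aliases labelMatrix classLegend backgroundCategories
NULL

#' @rdname ClassificationMap-accessors
#' @export
setMethod("labelMatrix", "ClassificationMap", function(x) x@labels)

#' @rdname ClassificationMap-accessors
#' @export
setMethod("classLegend", "ClassificationMap", function(x) x@legend)

#' @rdname ClassificationMap-accessors
#' @export
setMethod("backgroundCategories", "ClassificationMap", function(x) x@background)
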