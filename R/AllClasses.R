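#' @import methods
NULL

.CUBE_STAGES <- c("raw", "radiance", "pseudo_reflectance", "smoothed")
.REFERENCE_MODES <- c("column_mean", "global_mean")
.ROI_SOURCES <- c("video_identified", "spectral_anomaly")

#' HyperCube: an underwater hyperspectral image cube
#'
#' Container for push-broom hyperspectral imagery: a lines x samples x bands
#' array of nonnegative intensities (raw counts, radiance-equivalent values,
#' or pseudo-reflectance) together with the band-center wavelengths in nm.
#' Axis 0 is the along-track line, axis 1 the cross-track sample, axis 2 the
#' spectral band.
#'
#' @slot values numeric array, lines x samples x bands, all finite and >= 0.
#' @slot wavelengths numeric, band centers in nm, strictly increasing,
#'   length equal to the band axis.
#' @slot pixelSizeMM positive scalar, ground pixel size in mm (default 1).
#' @slot stage character, one of "raw", "radiance", "pseudo_reflectance",
#'   "smoothed"; records how far along the processing chain the cube is.
#' @slot trackID character, free-text survey-track identifier.
#'
#' @exportClass HyperCube
setClass("HyperCube",
  representation(
    values = "array",
    wavelengths = "numeric",
    pixelSizeMM = "numeric",
    stage = "character",
    trackID = "character"
  ),
  prototype(
    pixelSizeMM = 1.0,
    stage = "raw",
    trackID = ""
  )
)

setValidity("HyperCube", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array [lines x samples x bands]")
  else {
    if (length(object@wavelengths) != d[3L])
      msg <- c(msg, sprintf("wavelength count (%d) != band count (%d)",
                            length(object@wavelengths), d[3L]))
  }
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all cube values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "cube values must be nonnegative")
  if (length(object@pixelSizeMM) != 1L || !is.finite(object@pixelSizeMM) ||
      object@pixelSizeMM <= 0)
    msg <- c(msg, "pixelSizeMM must be a positive scalar")
  if (length(object@stage) != 1L || !object@stage %in% .CUBE_STAGES)
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(.CUBE_STAGES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ReferenceField: scene-derived reference spectra for pseudo-reflectance
#'
#' Holds the reference spectrum (or per-cross-track-column spectra) computed
#' from a raw cube, used to divide out illumination and water-column effects.
#'
#' @slot mode "column_mean" (one spectrum per cross-track sample) or
#'   "global_mean" (one spectrum for the whole cube).
#' @slot spectra numeric matrix, samples x bands for column_mean or
#'   1 x bands for global_mean.
#' @slot validMask logical matrix, same shape; TRUE where the entry is
#'   strictly positive and usable as a divisor.
#' @slot wavelengths numeric, nm.
#'
#' @exportClass ReferenceField
setClass("ReferenceField",
  representation(
    mode = "character",
    spectra = "matrix",
    validMask = "matrix",
    wavelengths = "numeric"
  )
)

setValidity("ReferenceField", function(object) {
  msg <- character(0)
  if (!object@mode %in% .REFERENCE_MODES)
    msg <- c(msg, "mode must be column_mean or global_mean")
  if (!identical(dim(object@spectra), dim(object@validMask)))
    msg <- c(msg, "spectra and validMask must have identical dimensions")
  if (ncol(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectra column count must match wavelength count")
  if (any(object@spectra[object@validMask] <= 0))
    msg <- c(msg, "valid reference entries must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' ROI: an annotated region of interest
#'
#' A set of pixel coordinates on a cube belonging to one object of interest
#' (OOI) or background patch, with its category and annotation provenance.
#'
#' @slot ooiID character, unique identifier.
#' @slot category character, e.g. one of the default benthic categories
#'   (see [defaultCategories()]).
#' @slot pixels integer matrix, n x 2, columns (line, sample), 1-based.
#' @slot source "video_identified" or "spectral_anomaly".
#'
#' @exportClass ROI
setClass("ROI",
  representation(
    ooiID = "character",
    category = "character",
    pixels = "matrix",
    source = "character"
  ),
  prototype(source = "video_identified")
)

setValidity("ROI", function(object) {
  msg <- character(0)
  if (nrow(object@pixels) < 1L)
    msg <- c(msg, "ROI must contain at least one pixel")
  if (ncol(object@pixels) != 2L)
    msg <- c(msg, "pixels must be an n x 2 (line, sample) matrix")
  if (any(object@pixels < 1))
    msg <- c(msg, "pixel coordinates must be 1-based positive integers")
  if (!object@source %in% .ROI_SOURCES)
    msg <- c(msg, "source must be video_identified or spectral_anomaly")
  if (nrow(object@pixels) > 1L && !.isConnected4(object@pixels))
    msg <- c(msg, "ROI pixels must form one 4-connected region")
  if (length(msg)) msg else TRUE
})

#' ReferenceSpectrum: the optical fingerprint of one OOI
#'
#' The mean pseudo-reflectance spectrum over an OOI's surface pixels,
#' stored max-normalized (maximum exactly 1) with the unnormalized mean
#' retained for intensity diagnostics.
#'
#' @slot ooiID character, unique within a library.
#' @slot category character.
#' @slot taxonomy character, free text (e.g. "Arthropoda, Decapoda,
#'   Probeebei mirabilis").
#' @slot source annotation provenance.
#' @slot nPixels integer, number of pixels averaged.
#' @slot values numeric, max-normalized spectrum (max == 1).
#' @slot rawValues numeric, unnormalized mean spectrum.
#' @slot wavelengths numeric, nm.
#'
#' @exportClass ReferenceSpectrum
setClass("ReferenceSpectrum",
  representation(
    ooiID = "character",
    category = "character",
    taxonomy = "character",
    source = "character",
    nPixels = "integer",
    values = "numeric",
    rawValues = "numeric",
    wavelengths = "numeric"
  ),
  prototype(taxonomy = "", source = "video_identified")
)

setValidity("ReferenceSpectrum", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@wavelengths))
    msg <- c(msg, "values and wavelengths must have equal length")
  if (length(object@rawValues) != length(object@values))
    msg <- c(msg, "rawValues and values must have equal length")
  if (object@nPixels < 1L)
    msg <- c(msg, "nPixels must be >= 1")
  if (abs(max(object@values) - 1) > 1e-9)
    msg <- c(msg, "values must be max-normalized (maximum exactly 1)")
  if (length(msg)) msg else TRUE
})

#' SpectralLibrary: a reference library of optical fingerprints
#'
#' An ordered collection of [ReferenceSpectrum-class] entries sharing one
#' wavelength grid, used both for spectral contrast angle matching and as
#' SVM training input.
#'
#' @slot entries list of ReferenceSpectrum, unique ooiIDs.
#' @slot wavelengths numeric, the common grid in nm.
#'
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
  representation(entries = "list", wavelengths = "numeric")
)

setValidity("SpectralLibrary", function(object) {
  msg <- character(0)
  ids <- vapply(object@entries, function(e) e@ooiID, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate ooiID(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (e in object@entries) {
    if (!isTRUE(all.equal(e@wavelengths, object@wavelengths,
                          tolerance = 1e-8))) {
      msg <- c(msg, sprintf("entry '%s' is not on the library grid", e@ooiID))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' MatchResult: spectral contrast angle match of one query spectrum
#'
#' Angles (degrees) from one query spectrum to every library entry, and the
#' smallest-angle assignment.
#'
#' @slot queryID character.
#' @slot angles named numeric, degrees, one per library entry.
#' @slot bestEntry character, entry id with the smallest angle.
#' @slot bestCategory character; "unassigned" when a reject threshold was
#'   exceeded.
#' @slot thetaMin numeric, the smallest angle in degrees.
#'
#' @exportClass MatchResult
setClass("MatchResult",
  representation(
    queryID = "character",
    angles = "numeric",
    bestEntry = "character",
    bestCategory = "character",
    thetaMin = "numeric"
  )
)

setValidity("MatchResult", function(object) {
  msg <- character(0)
  if (length(object@angles) < 1L)
    msg <- c(msg, "angles must be nonempty")
  if (abs(object@thetaMin - min(object@angles)) > 1e-9)
    msg <- c(msg, "thetaMin must equal min(angles)")
  if (any(object@angles < -1e-9 | object@angles > 180 + 1e-9))
    msg <- c(msg, "angles must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' TrainingSet: labelled spectra for supervised classification
#'
#' @slot samples numeric matrix, one spectrum per row.
#' @slot labels factor, one category per row.
#' @slot ooiIDs character, source OOI of each row.
#' @slot wavelengths numeric, nm.
#' @slot mode "avg_spectra" (one sample per OOI) or "roi_pixels" (one
#'   sample per ROI pixel).
#' @slot backgroundPresent logical, whether background categories
#'   (sediment / nodule) are represented.
#'
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(
    samples = "matrix",
    labels = "factor",
    ooiIDs = "character",
    wavelengths = "numeric",
    mode = "character",
    backgroundPresent = "logical"
  )
)

setValidity("TrainingSet", function(object) {
  msg <- character(0)
  if (nrow(object@samples) != length(object@labels))
    msg <- c(msg, "one label per sample row required")
  if (nlevels(droplevels(object@labels)) < 2L)
    msg <- c(msg, "training set must contain at least 2 distinct categories")
  if (ncol(object@samples) != length(object@wavelengths))
    msg <- c(msg, "sample columns must match wavelength count")
  if (length(msg)) msg else TRUE
})

#' ClassificationMap: per-pixel category labels for a cube
#'
#' @slot labels integer matrix, lines x samples; every pixel labelled.
#' @slot legend named character vector mapping label integers (names) to
#'   category strings; covers all labels present.
#' @slot background character, the categories regarded as seafloor
#'   background (default sediment and manganese nodule).
#'
#' @exportClass ClassificationMap
setClass("ClassificationMap",
  representation(
    labels = "matrix",
    legend = "character",
    background = "character"
  ),
  prototype(background = c("sediment", "nodule"))
)

setValidity("ClassificationMap", function(object) {
  msg <- character(0)
  present <- unique(as.integer(object@labels))
  if (anyNA(present))
    msg <- c(msg, "every pixel must be labelled (no NA)")
  else if (!all(as.character(present) %in% names(object@legend)))
    msg <- c(msg, "legend must cover all labels present in the map")
  if (length(msg)) msg else TRUE
})

#' SceneTruth: ground truth emitted by the synthetic scene generator
#'
#' @slot labels integer matrix, lines x samples, category per pixel.
#' @slot legend named character, label integer (name) to category.
#' @slot objectIDs integer matrix, 0 for plain sediment, otherwise the row
#'   number of the object (fauna, anomaly, or nodule) covering the pixel.
#' @slot objects data.frame: id, category, centerLine, centerSample,
#'   diameterCM, nPixels, background (logical; TRUE for nodules).
#' @slot materials numeric matrix, true reflectance per category (rows) and
#'   band (columns).
#' @slot wavelengths numeric, nm.
#' @slot illumination numeric matrix, lines x samples multiplicative
#'   illumination field used by the forward model.
#'
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    labels = "matrix",
    legend = "character",
    objectIDs = "matrix",
    objects = "data.frame",
    materials = "matrix",
    wavelengths = "numeric",
    illumination = "matrix"
  )
)

#' SurveySummary: per-category OOI counts and densities for a survey
#'
#' @slot counts named integer, OOIs per category.
#' @slot densities named numeric, individuals per square metre (full
#'   precision; rounding is applied only when printing reports).
#' @slot total integer, total OOI count.
#' @slot areaM2 numeric, surveyed area in square metres.
#'
#' @exportClass SurveySummary
setClass("SurveySummary",
  representation(
    counts = "integer",
    densities = "numeric",
    total = "integer",
    areaM2 = "numeric"
  )
)

setValidity("SurveySummary", function(object) {
  msg <- character(0)
  if (object@total != sum(object@counts))
    msg <- c(msg, "total must equal the sum of per-category counts")
  if (object@areaM2 <= 0)
    msg <- c(msg, "surveyed area must be positive")
  if (length(msg)) msg else TRUE
})
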