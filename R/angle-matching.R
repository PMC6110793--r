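# Spectral contrast angle matching.  The angle between two spectra a and b
# is theta = arccos( sum(a_i b_i) / sqrt(sum(a_i^2) sum(b_i^2)) ): 0 deg
# means identical spectral shape; for nonnegative spectra the angle never
# exceeds 90 deg.  Unidentified OOIs are assigned the category of the
# library entry with the smallest angle.

#' Spectral contrast angle between two spectra
#'
#' Computes the angle (in degrees) between two spectra viewed as vectors:
#' `theta = arccos( sum(a*b) / sqrt(sum(a^2) * sum(b^2)) )`. The cosine
#' argument is clamped to \[-1, 1\] before the arccosine to absorb rounding.
#' The measure is symmetric and invariant to positive rescaling of either
#' spectrum; identical spectral shapes give 0 degrees, and nonnegative
#' spectra can never exceed 90 degrees.
#'
#' @param a,b numeric spectra of equal length with nonzero Euclidean norm.
#' @return angle in degrees (full floating precision; round only for
#'   reporting).
#' @examples
#' spectralContrastAngle(c(1, 2, 3), c(2, 4, 6))  # 0: same shape
#' spectralContrastAngle(c(1, 0), c(0, 1))        # 90: orthogonal
#' @export
spectralContrastAngle <- function(a, b) {
  if (length(a) != length(b))
    .stopf("spectra differ in length (%d vs %d)", length(a), length(b))
  na2 <- sum(a * a)
  nb2 <- sum(b * b)
  if (na2 == 0 || nb2 == 0)
    .stopf("spectral contrast angle is undefined for a zero-norm spectrum")
  cosTheta <- sum(a * b) / sqrt(na2 * nb2)
  cosTheta <- min(1, max(-1, cosTheta))
  acos(cosTheta) * 180 / pi
}

#' Match a query spectrum against a spectral library
#'
#' Computes the spectral contrast angle of the query against every library
#' entry and assigns the query to the category of the entry with the
#' smallest angle. Both the query and the entries are max-normalized before
#' matching (the angle is scale-invariant, so this cannot change any
#' assignment; it only makes stored diagnostics comparable). Ties within
#' 1e-9 degrees are resolved to the entry earliest in library order, with a
#' warning.
#'
#' @param query numeric spectrum on the library grid.
#' @param lib a nonempty [SpectralLibrary-class].
#' @param queryID identifier recorded in the result.
#' @param thetaMax optional reject threshold in degrees: when the smallest
#'   angle exceeds it the category is `"unassigned"` (default `NULL`, no
#'   rejection).
#' @return A [MatchResult-class].
#' @export
matchToLibrary <- function(query, lib, queryID = "query", thetaMax = NULL) {
  stopifnot(is(lib, "SpectralLibrary"))
  if (!length(lib@entries)) .stopf("cannot match against an empty library")
  if (length(query) != length(lib@wavelengths))
    .stopf("query has %d bands but the library grid has %d",
           length(query), length(lib@wavelengths))
  q <- normalizeMax(query)
  angles <- vapply(lib@entries,
                   function(e) spectralContrastAngle(q, e@values),
                   numeric(1))
  names(angles) <- entryIDs(lib)
  best <- which.min(angles)
  ties <- which(angles - angles[best] < 1e-9)
  if (length(ties) > 1L)
    .warnf("query '%s': %d library entries tie at theta = %.6f deg; using '%s' (first in library order)",
           queryID, length(ties), angles[best], names(angles)[best])
  bestCat <- lib@entries[[best]]@category
  if (!is.null(thetaMax) && angles[best] > thetaMax) bestCat <- "unassigned"
  new("MatchResult", queryID = queryID, angles = angles,
      bestEntry = names(angles)[best], bestCategory = bestCat,
      thetaMin = unname(angles[best]))
}

#' Match many ROI spectra against a library
#'
#' Convenience wrapper: extracts each ROI's mean spectrum from a
#' preprocessed cube and matches it against the library.
#'
#' @param cube a preprocessed [HyperCube-class].
#' @param rois list of [ROI-class] of unidentified OOIs.
#' @param lib a [SpectralLibrary-class].
#' @param thetaMax optional reject threshold in degrees.
#' @return list of [MatchResult-class], one per ROI.
#' @export
matchROIs <- function(cube, rois, lib, thetaMax = NULL) {
  lapply(rois, function(roi) {
    spec <- extractROISpectrum(cube, roi)
    matchToLibrary(spec@rawValues, lib, queryID = roi@ooiID,
                   thetaMax = thetaMax)
  })
}

#' Tabulate match results
#'
#' @param matches list of [MatchResult-class].
#' @return data.frame with columns `query_id`, `best_category`,
#'   `theta_min_deg`, then one angle column per library entry.
#' @export
matchesToDataFrame <- function(matches) {
  if (!length(matches)) return(data.frame())
  base <- data.frame(
    query_id = vapply(matches, function(m) m@queryID, character(1)),
    best_category = vapply(matches, function(m) m@bestCategory, character(1)),
    theta_min_deg = vapply(matches, function(m) m@thetaMin, numeric(1)),
    stringsAsFactors = FALSE)
  ang <- do.call(rbind, lapply(matches, function(m) m@angles))
  cbind(base, as.data.frame(ang))
}
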