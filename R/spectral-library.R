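# Reference spectral libraries: optical fingerprints of identified OOIs,
# built by averaging pseudo-reflectance spectra over annotated regions.

#' Default category vocabulary
#'
#' The 19 default object-of-interest categories (16 megafauna morphotypes
#' and 3 sediment-anomaly classes) plus, optionally, the two seafloor
#' background classes. User-defined categories may be used anywhere a
#' category string is accepted.
#'
#' @param background if TRUE, append the background classes `"sediment"`
#'   and `"nodule"`.
#' @return character vector of category names.
#' @export
defaultCategories <- function(background = FALSE) {
  fauna <- c("sponge_round", "sponge_disc", "glass_sponge",
             "coral_white", "coral_yellow", "coral_green",
             "holothurian_synallactidae", "holothurian_paelopatides",
             "ophiuroid_white", "ophiuroid_red",
             "crustacean", "salp_dead", "polychaete",
             "crinoid", "isopod", "bony_fish")
  anomalies <- c("white_exposed_sediment", "green_spot", "white_spot")
  out <- c(fauna, anomalies)
  if (background) out <- c(out, "sediment", "nodule")
  out
}

#' Background category names
#' @return `c("sediment", "nodule")` — the seafloor background classes.
#' @export
backgroundClasses <- function() c("sediment", "nodule")

#' Construct an ROI
#'
#' @param ooiID unique identifier string.
#' @param category category string.
#' @param pixels n x 2 integer matrix of (line, sample) coordinates,
#'   1-based; must form one 4-connected region.
#' @param source `"video_identified"` or `"spectral_anomaly"`.
#' @return An [ROI-class].
#' @export
ROI <- function(ooiID, category, pixels, source = "video_identified") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("line", "sample")
  new("ROI", ooiID = as.character(ooiID), category = as.character(category),
      pixels = pixels, source = source)
}

#' Extract the mean spectrum over an ROI
#'
#' Per-band arithmetic mean of the pixel spectra under the ROI mask, from a
#' preprocessed (pseudo-reflectance or smoothed) cube. The typical OOI
#' surface covers 20-600 pixels; sizes outside that range trigger a warning
#' (not an error), since very small masks average little noise and very
#' large ones mix surface variation.
#'
#' @param cube a [HyperCube-class] at stage `"pseudo_reflectance"` or
#'   `"smoothed"`.
#' @param roi an [ROI-class] within cube bounds.
#' @return An unnormalized [ReferenceSpectrum-class] (`values` equal to
#'   `rawValues` scaled to max 1; `rawValues` hold the raw mean).
#' @export
extractROISpectrum <- function(cube, roi) {
  stopifnot(is(cube, "HyperCube"), is(roi, "ROI"))
  if (!cube@stage %in% c("pseudo_reflectance", "smoothed"))
    .stopf("ROI spectra are extracted from preprocessed cubes, not stage '%s'",
           cube@stage)
  d <- dim(cube@values)
  px <- roi@pixels
  if (any(px[, 1L] > d[1L]) || any(px[, 2L] > d[2L]))
    .stopf("ROI '%s' has pixels outside the %d x %d cube", roi@ooiID,
           d[1L], d[2L])
  n <- nrow(px)
  if (n < 20L || n > 600L)
    .warnf("ROI '%s' covers %d pixels; OOI surfaces are typically 20-600 px",
           roi@ooiID, n)
  flat <- .cubeMatrix(cube)
  rows <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
  m <- colMeans(flat[rows, , drop = FALSE])
  new("ReferenceSpectrum",
      ooiID = roi@ooiID, category = roi@category, source = roi@source,
      nPixels = n, values = normalizeMax(m), rawValues = m,
      wavelengths = cube@wavelengths)
}

#' Max-normalize a spectrum
#'
#' Divides a spectrum by its maximum so the output maximum is exactly 1.
#' Idempotent and invariant to positive rescaling.
#'
#' @param values numeric spectrum with at least one strictly positive entry.
#' @return numeric spectrum with `max(values) == 1`.
#' @export
normalizeMax <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0)
    .stopf("cannot max-normalize a spectrum with no positive values")
  values / m
}

#' Construct an empty spectral library
#'
#' @param wavelengths the common band grid in nm.
#' @return A [SpectralLibrary-class] with no entries.
#' @export
SpectralLibrary <- function(wavelengths) {
  new("SpectralLibrary", entries = list(),
      wavelengths = as.numeric(wavelengths))
}

#' Add a reference spectrum to a library
#'
#' @param lib a [SpectralLibrary-class].
#' @param spec a [ReferenceSpectrum-class] on the library's grid. If the
#'   spectrum is not yet max-normalized it is normalized on insertion.
#' @param taxonomy optional free-text taxonomic annotation to attach.
#' @return The extended library. Duplicate `ooiID`s and grid mismatches are
#'   errors.
#' @export
addEntry <- function(lib, spec, taxonomy = NULL) {
  stopifnot(is(lib, "SpectralLibrary"), is(spec, "ReferenceSpectrum"))
  if (length(spec@values) != length(lib@wavelengths) ||
      !isTRUE(all.equal(spec@wavelengths, lib@wavelengths, tolerance = 1e-8)))
    .stopf("entry '%s' (%d bands) is not on the library grid (%d bands)",
           spec@ooiID, length(spec@values), length(lib@wavelengths))
  if (spec@ooiID %in% entryIDs(lib))
    .stopf("duplicate ooiID '%s'", spec@ooiID)
  if (!is.null(taxonomy)) spec@taxonomy <- taxonomy
  lib@entries <- c(lib@entries, spec)
  validObject(lib)
  lib
}

#' Build a library from a preprocessed cube and annotated ROIs
#'
#' Extracts the mean spectrum of each ROI and adds it to a new library on
#' the cube's band grid.
#'
#' @param cube a preprocessed [HyperCube-class].
#' @param rois list of [ROI-class].
#' @param taxonomies optional named character vector (names = ooiIDs).
#' @return A [SpectralLibrary-class].
#' @export
buildLibrary <- function(cube, rois, taxonomies = NULL) {
  lib <- SpectralLibrary(wavelengths(cube))
  for (roi in rois) {
    spec <- extractROISpectrum(cube, roi)
    tax <- if (!is.null(taxonomies) && roi@ooiID %in% names(taxonomies))
      taxonomies[[roi@ooiID]] else NULL
    lib <- addEntry(lib, spec, taxonomy = tax)
  }
  lib
}

#' Save a spectral library as JSON
#'
#' Persists the grid and all entries (category, taxonomy, provenance,
#' pixel count, normalized and raw values) as structured text.
#'
#' @param lib a [SpectralLibrary-class].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
saveLibrary <- function(lib, path) {
  stopifnot(is(lib, "SpectralLibrary"))
  obj <- list(
    wavelengths_nm = lib@wavelengths,
    entries = lapply(lib@entries, function(e) list(
      ooi_id = e@ooiID, category = e@category, taxonomy = e@taxonomy,
      source = e@source, n_pixels = e@nPixels,
      values = e@values, raw_values = e@rawValues))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a spectral library from JSON
#'
#' @param path a JSON file written by [saveLibrary()].
#' @return A [SpectralLibrary-class].
#' @export
loadLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lib <- SpectralLibrary(obj$wavelengths_nm)
  for (e in obj$entries) {
    spec <- new("ReferenceSpectrum",
                ooiID = e$ooi_id, category = e$category,
                taxonomy = e$taxonomy %||% "", source = e$source,
                nPixels = as.integer(e$n_pixels),
                values = as.numeric(e$values),
                rawValues = as.numeric(e$raw_values),
                wavelengths = lib@wavelengths)
    lib <- addEntry(lib, spec)
  }
  lib
}

#' Build ROIs from an integer label-mask raster
#'
#' Accepts the standard annotation raster: an integer matrix aligned to the
#' cube where 0 marks unannotated pixels and each positive integer is one
#' OOI.
#'
#' @param mask integer matrix (lines x samples), 0 = unannotated.
#' @param categoryByID named character vector mapping mask integers (as
#'   names) to category strings.
#' @param source annotation provenance for all ROIs.
#' @param idPrefix prefix for generated ooiIDs (default "roi").
#' @return list of [ROI-class], in increasing mask-id order.
#' @export
roisFromLabelMask <- function(mask, categoryByID, source = "video_identified",
                              idPrefix = "roi") {
  ids <- sort(unique(as.integer(mask[mask > 0])))
  lapply(ids, function(i) {
    cat <- unname(categoryByID[as.character(i)])
    if (length(cat) != 1L || is.na(cat))
      .stopf("no category given for mask id %d", i)
    ROI(sprintf("%s_%03d", idPrefix, i), cat,
        which(mask == i, arr.ind = TRUE), source = source)
  })
}

# even-odd (ray crossing) point-in-polygon test; vertices as n x 2 matrix
.pointInPolygon <- function(pl, ps, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(pl))
  for (i in seq_len(n)) {
    yi <- poly[i, 1L]; xi <- poly[i, 2L]
    yj <- poly[j, 1L]; xj <- poly[j, 2L]
    cross <- ((yi > pl) != (yj > pl)) &
      (ps < (xj - xi) * (pl - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Build ROIs from polygon annotations (JSON)
#'
#' Rasterizes polygon annotations with center-in-polygon inclusion: a pixel
#' belongs to the ROI when its center lies inside the polygon. The JSON is a
#' list of objects with fields `ooi_id`, `category`, optional `source`, and
#' `vertices` (an array of `[line, sample]` pairs in pixel coordinates).
#'
#' @param path path to the polygon JSON file, or an already-parsed list.
#' @param dims cube dimensions `c(lines, samples)` used to clip the raster.
#' @return list of [ROI-class].
#' @export
roisFromPolygons <- function(path, dims) {
  polys <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE) else path
  lapply(polys, function(p) {
    v <- do.call(rbind, lapply(p$vertices, as.numeric))
    lrange <- max(1L, floor(min(v[, 1L]))):min(dims[1L], ceiling(max(v[, 1L])))
    srange <- max(1L, floor(min(v[, 2L]))):min(dims[2L], ceiling(max(v[, 2L])))
    grid <- expand.grid(line = lrange, sample = srange)
    keep <- .pointInPolygon(grid$line, grid$sample, v)
    if (!any(keep))
      .stopf("polygon '%s' covers no pixel centers", p$ooi_id)
    ROI(p$ooi_id, p$category, as.matrix(grid[keep, , drop = FALSE]),
        source = p$source %||% "video_identified")
  })
}
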