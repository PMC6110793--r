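# Raw cube -> smoothed pseudo-reflectance.
#
# The instrument records intensities that mix the target's reflectance with
# the lamp spectrum, illumination geometry and water-column effects. Since
# these cannot be measured independently in a deep-sea deployment, they are
# approximated by a reference spectrum computed from the image data itself;
# dividing each pixel spectrum by its reference yields "pseudo-reflectance"
# (not true reflectance: residual illumination effects remain).

#' Preprocessing configuration
#'
#' @param subsetMinNM,subsetMaxNM inclusive wavelength limits in nm for the
#'   spectral subset (defaults 400 and 710; bands outside this window are
#'   noisy and dropped).
#' @param referenceMode `"column_mean"` (default; one reference spectrum per
#'   cross-track sample, correcting the static lamp-geometry profile) or
#'   `"global_mean"` (a single whole-cube mean spectrum).
#' @param smoothWindowBands odd moving-average window length in bands
#'   (default 11, i.e. ~44 nm at 4 nm resolution).
#' @param edgeMode `"reflect"` (default; symmetric padding so the band count
#'   is preserved) or `"shrink"` (window shrinks near the spectrum ends).
#' @return A named list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(subsetMinNM = 400, subsetMaxNM = 710,
                             referenceMode = c("column_mean", "global_mean"),
                             smoothWindowBands = 11L,
                             edgeMode = c("reflect", "shrink")) {
  referenceMode <- match.arg(referenceMode)
  edgeMode <- match.arg(edgeMode)
  if (subsetMinNM >= subsetMaxNM)
    .stopf("subsetMinNM must be < subsetMaxNM")
  smoothWindowBands <- as.integer(smoothWindowBands)
  if (smoothWindowBands < 1L || smoothWindowBands %% 2L == 0L)
    .stopf("smoothWindowBands must be an odd integer >= 1")
  structure(list(subsetMinNM = subsetMinNM, subsetMaxNM = subsetMaxNM,
                 referenceMode = referenceMode,
                 smoothWindowBands = smoothWindowBands,
                 edgeMode = edgeMode),
            class = "PreprocessConfig")
}

#' Spectral subsetting
#'
#' Retains exactly the bands whose centers lie in `[minNM, maxNM]`
#' (inclusive on both ends), in their original order. On the default
#' 112-band grid the default window keeps the 83 bands between 400 and
#' 710 nm.
#'
#' @param cube a [HyperCube-class].
#' @param minNM,maxNM inclusive wavelength limits in nm.
#' @return The subsetted [HyperCube-class]; errors if no band falls inside
#'   the window.
#' @export
spectralSubset <- function(cube, minNM = 400, maxNM = 710) {
  stopifnot(is(cube, "HyperCube"))
  keep <- which(cube@wavelengths >= minNM & cube@wavelengths <= maxNM)
  if (!length(keep))
    .stopf("no band centers inside [%.1f, %.1f] nm", minNM, maxNM)
  initialize(cube,
             values = cube@values[, , keep, drop = FALSE],
             wavelengths = cube@wavelengths[keep])
}

#' Compute the scene-derived reference field
#'
#' `column_mean` averages all along-track lines separately for each
#' cross-track sample, capturing the static cross-track illumination profile
#' of the lamp array; `global_mean` averages over every pixel.
#'
#' @param cube a [HyperCube-class] at stage `"raw"` or `"radiance"`.
#' @param mode `"column_mean"` or `"global_mean"`.
#' @return A [ReferenceField-class]. Entries that are not strictly positive
#'   are flagged invalid; a band whose reference is invalid in every column
#'   is an error (it can never be divided out).
#' @export
computeReference <- function(cube, mode = c("column_mean", "global_mean")) {
  stopifnot(is(cube, "HyperCube"))
  mode <- match.arg(mode)
  if (!cube@stage %in% c("raw", "radiance"))
    .stopf("reference spectra are computed from raw or radiance cubes, not '%s'",
           cube@stage)
  d <- dim(cube@values)
  if (mode == "column_mean") {
    spectra <- colMeans(cube@values, dims = 1L)        # samples x bands
  } else {
    spectra <- matrix(colMeans(.cubeMatrix(cube)), nrow = 1L)
  }
  valid <- is.finite(spectra) & spectra > 0
  badBand <- which(colSums(valid) == 0L)
  if (length(badBand))
    .stopf("reference is nonpositive in every column for band(s) %s (%.1f nm, ...)",
           paste(badBand, collapse = ", "), cube@wavelengths[badBand[1L]])
  new("ReferenceField", mode = mode, spectra = spectra, validMask = valid,
      wavelengths = cube@wavelengths)
}

#' Divide a cube by its reference field (pseudo-reflectance)
#'
#' Each pixel spectrum is divided elementwise by its reference spectrum
#' (the spectrum of its cross-track column for `column_mean`, the global
#' mean for `global_mean`). The result approximates reflectance up to
#' residual illumination effects and is tagged `"pseudo_reflectance"`.
#'
#' @param cube a [HyperCube-class] on the same band grid as `ref`.
#' @param ref a [ReferenceField-class] from [computeReference()].
#' @return A [HyperCube-class] at stage `"pseudo_reflectance"`. Using an
#'   invalid (nonpositive) reference entry is an error rather than a silent
#'   NaN.
#' @export
pseudoReflectance <- function(cube, ref) {
  stopifnot(is(cube, "HyperCube"), is(ref, "ReferenceField"))
  d <- dim(cube@values)
  if (ncol(ref@spectra) != d[3L])
    .stopf("reference has %d bands but cube has %d", ncol(ref@spectra), d[3L])
  if (ref@mode == "column_mean" && nrow(ref@spectra) != d[2L])
    .stopf("column_mean reference has %d columns but cube has %d samples",
           nrow(ref@spectra), d[2L])
  if (!all(ref@validMask))
    .stopf("%d invalid (nonpositive) reference entr%s would be used as divisors",
           sum(!ref@validMask), if (sum(!ref@validMask) == 1L) "y" else "ies")
  vals <- cube@values
  if (ref@mode == "global_mean") {
    for (b in seq_len(d[3L])) vals[, , b] <- vals[, , b] / ref@spectra[1L, b]
  } else {
    for (b in seq_len(d[3L]))
      vals[, , b] <- vals[, , b] / rep(ref@spectra[, b], each = d[1L])
  }
  initialize(cube, values = vals, stage = "pseudo_reflectance")
}

# moving-average matrix core: X [n x bands] -> smoothed [n x bands]
.movingAverage <- function(X, window, edgeMode) {
  B <- ncol(X)
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(X)
  if (edgeMode == "reflect") {
    # symmetric padding including the edge sample: (x_h..x_1 | x | x_B..x_{B-h+1})
    idx <- c(rev(seq_len(h)), seq_len(B), seq(B, B - h + 1L))
    Xp <- X[, idx, drop = FALSE]
    denom <- rep(window, B)
  } else {
    Xp <- cbind(matrix(0, nrow(X), h), X, matrix(0, nrow(X), h))
    avail <- c(rep(0, h), rep(1, B), rep(0, h))
    denom <- vapply(seq_len(B),
                    function(j) sum(avail[j:(j + 2L * h)]), numeric(1))
  }
  # band-limited ones matrix: column j sums padded columns j..j+2h
  W <- matrix(0, B + 2L * h, B)
  for (j in seq_len(B)) W[j:(j + 2L * h), j] <- 1
  sweep(Xp %*% W, 2L, denom, "/")
}

#' Moving-average spectral smoothing
#'
#' Centered moving average along the band axis of every pixel spectrum.
#' With the default `"reflect"` edge handling the band count is preserved.
#'
#' @param cube a [HyperCube-class].
#' @param window odd window length in bands (default 11), at most the band
#'   count.
#' @param edgeMode `"reflect"` or `"shrink"`.
#' @return A [HyperCube-class] at stage `"smoothed"`.
#' @export
smoothSpectra <- function(cube, window = 11L,
                          edgeMode = c("reflect", "shrink")) {
  stopifnot(is(cube, "HyperCube"))
  edgeMode <- match.arg(edgeMode)
  window <- as.integer(window)
  d <- dim(cube@values)
  if (window %% 2L == 0L) .stopf("smoothing window must be odd, got %d", window)
  if (window > d[3L])
    .stopf("smoothing window (%d) exceeds band count (%d)", window, d[3L])
  X <- .movingAverage(.cubeMatrix(cube), window, edgeMode)
  initialize(cube, values = .matrixCube(X, d[1L], d[2L]), stage = "smoothed")
}

#' Full preprocessing chain: subset, divide by reference, smooth
#'
#' Applies, in order: spectral subsetting to the configured window,
#' reference-spectrum division (pseudo-reflectance) and moving-average
#' smoothing. This is the standard conversion of a raw track cube into the
#' smoothed pseudo-reflectance cube all downstream analysis uses.
#'
#' @param cube a raw or radiance [HyperCube-class].
#' @param config a [preprocessConfig()].
#' @return A smoothed pseudo-reflectance [HyperCube-class].
#' @examples
#' cfg <- sceneConfig(lines = 80, samples = 100, nPerCategory = 1,
#'                    nNodules = 5, faunaDiamCM = c(1, 2.5), seed = 1)
#' pre <- preprocessCube(generateScene(cfg)$cube, preprocessConfig())
#' stage(pre)
#' @export
preprocessCube <- function(cube, config = preprocessConfig()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  cube <- spectralSubset(cube, config$subsetMinNM, config$subsetMaxNM)
  ref <- computeReference(cube, config$referenceMode)
  cube <- pseudoReflectance(cube, ref)
  smoothSpectra(cube, config$smoothWindowBands, config$edgeMode)
}
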