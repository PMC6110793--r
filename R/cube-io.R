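# ENVI-style cube reader/writer.  The dialect is the de facto hyperspectral
# remote-sensing container: a "key = value" text header next to a flat binary
# payload in band-sequential (BSQ), band-interleaved-by-line (BIL) or
# band-interleaved-by-pixel (BIP) order.

.ENVI_RTYPES <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# locate the header file belonging to a data path (or vice versa)
.enviPaths <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    hdr <- path
    dat <- sub("\\.hdr$", "", path, ignore.case = TRUE)
    if (!file.exists(dat)) {
      # header may be data-with-extension-swapped
      cand <- list.files(dirname(path),
                         pattern = paste0("^", gsub("([.\\\\+*?^$(){}|\\[\\]])",
                                                    "\\\\\\1",
                                                    sub("\\.hdr$", "",
                                                        basename(path))),
                                          "\\.(bsq|bil|bip|img|dat)$"),
                         full.names = TRUE)
      if (length(cand)) dat <- cand[1L]
    }
  } else {
    dat <- path
    hdr <- paste0(path, ".hdr")
    if (!file.exists(hdr))
      hdr <- paste0(tools::file_path_sans_ext(path), ".hdr")
  }
  list(hdr = hdr, dat = dat)
}

# parse the header into a named list; brace-delimited values may span lines
.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    .stopf("'%s' is not an ENVI-style header (missing ENVI magic)", hdrPath)
  txt <- sub("^\\s*ENVI\\s*\n", "", txt)
  pat <- "(?m)^[ \t]*([A-Za-z][A-Za-z0-9 _]*?)[ \t]*=[ \t]*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) .stopf("no key = value entries found in '%s'", hdrPath)
  starts <- m
  lens <- attr(m, "match.length")
  out <- list()
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    out[[key]] <- val
  }
  out
}

.hdrNumeric <- function(hdr, key, path) {
  if (is.null(hdr[[key]]))
    .stopf("header '%s' is missing required field '%s'", path, key)
  v <- suppressWarnings(as.numeric(hdr[[key]]))
  if (is.na(v))
    .stopf("header field '%s' is not numeric ('%s')", key, hdr[[key]])
  v
}

.hdrList <- function(hdr, key) {
  v <- hdr[[key]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(strsplit(v, ",")[[1L]])
}

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a header + flat-binary cube in any of the three standard interleaves
#' (BSQ, BIL, BIP) and returns it in the package's canonical band-last layout
#' (lines x samples x bands). Wavelengths are taken from the header's
#' `wavelength` block.
#'
#' @param path path to the binary payload, or to the `.hdr` header.
#' @return A [HyperCube-class]. The processing stage is taken from the
#'   nonstandard `stage` header key when present, else `"raw"`.
#' @seealso [writeCube()]
#' @export
readCube <- function(path) {
  p <- .enviPaths(path)
  if (!file.exists(p$hdr)) .stopf("header file not found for '%s'", path)
  if (!file.exists(p$dat)) .stopf("binary payload not found for '%s'", path)
  hdr <- .parseEnviHeader(p$hdr)

  samples <- as.integer(.hdrNumeric(hdr, "samples", p$hdr))
  lines <- as.integer(.hdrNumeric(hdr, "lines", p$hdr))
  bands <- as.integer(.hdrNumeric(hdr, "bands", p$hdr))
  if (samples < 1L || lines < 1L || bands < 1L)
    .stopf("header declares non-positive dimensions (%d x %d x %d)",
           lines, samples, bands)
  dtype <- as.character(as.integer(.hdrNumeric(hdr, "data type", p$hdr)))
  if (!dtype %in% names(.ENVI_RTYPES))
    .stopf("unsupported data type %s in '%s'", dtype, p$hdr)
  rt <- .ENVI_RTYPES[[dtype]]
  interleave <- tolower(trimws(hdr[["interleave"]] %||% "bsq"))
  if (!interleave %in% c("bsq", "bil", "bip"))
    .stopf("unsupported interleave '%s'", interleave)
  byteOrder <- if (is.null(hdr[["byte order"]])) 0L else
    as.integer(.hdrNumeric(hdr, "byte order", p$hdr))
  endian <- if (byteOrder == 0L) "little" else "big"
  offset <- if (is.null(hdr[["header offset"]])) 0L else
    as.integer(.hdrNumeric(hdr, "header offset", p$hdr))

  wl <- .hdrList(hdr, "wavelength")
  if (is.null(wl)) .stopf("header '%s' has no wavelength block", p$hdr)
  if (length(wl) != bands)
    .stopf("header declares %d wavelengths but bands = %d",
           length(wl), bands)

  n <- as.double(samples) * lines * bands
  expect <- offset + n * rt$size
  if (file.size(p$dat) < expect)
    .stopf("binary payload '%s' is smaller than the header implies (%d < %d bytes)",
           p$dat, file.size(p$dat), expect)
  con <- file(p$dat, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  vec <- readBin(con, what = rt$what, n = n, size = rt$size,
                 signed = rt$signed, endian = endian)
  vec <- as.double(vec)

  # normalize any interleave to band-last [lines x samples x bands]
  arr <- switch(interleave,
    bsq = aperm(array(vec, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vec, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(vec, c(bands, samples, lines)), c(3L, 2L, 1L))
  )

  pxmm <- if (!is.null(hdr[["pixel size mm"]]))
    .hdrNumeric(hdr, "pixel size mm", p$hdr) else 1.0
  stg <- trimws(hdr[["stage"]] %||% "raw")
  if (!stg %in% .CUBE_STAGES) stg <- "raw"
  trk <- trimws(hdr[["track id"]] %||% "")

  HyperCube(arr, wl, pixelSizeMM = pxmm, stage = stg, trackID = trk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hyperspectral cube in the ENVI-style container
#'
#' Writes the binary payload (32-bit IEEE floats, little endian) and a
#' matching text header. Wavelengths are serialized with 4 decimal places.
#'
#' @param cube a [HyperCube-class].
#' @param path output path for the binary payload; `.bsq` is appended when
#'   the path has no extension. The header is written at `<path>.hdr`.
#' @param interleave one of "bsq", "bil", "bip" (default "bsq").
#' @return Invisibly, the path of the binary payload.
#' @export
writeCube <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  if (tools::file_ext(path) == "") path <- paste0(path, ".", interleave)
  d <- dim(cube@values)
  lines <- d[1L]; samples <- d[2L]; bands <- d[3L]

  arr <- switch(interleave,
    bsq = aperm(cube@values, c(2L, 1L, 3L)),
    bil = aperm(cube@values, c(2L, 3L, 1L)),
    bip = aperm(cube@values, c(3L, 2L, 1L))
  )
  con <- tryCatch(file(path, "wb"),
                  error = function(e) .stopf("cannot write '%s': %s",
                                             path, conditionMessage(e)))
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  close(con)

  hdr <- c(
    "ENVI",
    "description = {benthospec hyperspectral cube}",
    sprintf("samples = %d", samples),
    sprintf("lines = %d", lines),
    sprintf("bands = %d", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("pixel size mm = %.6f", cube@pixelSizeMM),
    sprintf("stage = %s", cube@stage),
    sprintf("track id = %s", cube@trackID),
    paste0("wavelength = { ",
           paste(sprintf("%.4f", cube@wavelengths), collapse = ", "),
           " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Render a pseudo-RGB image from three bands of a cube
#'
#' Selects, for each channel, the band whose center is nearest the requested
#' wavelength (ties resolved toward the lower wavelength) and rescales each
#' channel independently to \[0, 1\] by a percentile stretch. The defaults
#' (R 645 nm, G 571 nm, B 473 nm) are the rendering used for visual review
#' of seafloor transects.
#'
#' @param cube a [HyperCube-class] with at least 3 bands.
#' @param rNM,gNM,bNM requested channel wavelengths in nm; each must lie
#'   within the covered wavelength range extended by one band spacing.
#' @param stretch length-2 percentile pair for the contrast stretch
#'   (default `c(0.02, 0.98)`).
#' @return numeric array lines x samples x 3 with values in \[0, 1\];
#'   attribute `"bands"` records the selected band indices. A constant cube
#'   renders as uniform mid-gray.
#' @export
pseudoRGB <- function(cube, rNM = 645, gNM = 571, bNM = 473,
                      stretch = c(0.02, 0.98)) {
  stopifnot(is(cube, "HyperCube"))
  wl <- cube@wavelengths
  if (length(wl) < 3L) .stopf("pseudo-RGB needs a cube with >= 3 bands")
  sp <- .bandSpacing(wl)
  idx <- integer(3L)
  req <- c(rNM, gNM, bNM)
  for (i in 1:3) {
    if (req[i] < min(wl) - sp || req[i] > max(wl) + sp)
      .stopf("requested wavelength %.1f nm outside covered range [%.1f, %.1f] nm",
             req[i], min(wl), max(wl))
    idx[i] <- .nearestBand(wl, req[i])
  }
  d <- dim(cube@values)
  out <- array(0, c(d[1L], d[2L], 3L))
  for (i in 1:3) {
    ch <- cube@values[, , idx[i]]
    q <- stats::quantile(ch, stretch, names = FALSE)
    if (q[2L] - q[1L] <= 0) {
      out[, , i] <- 0.5
    } else {
      out[, , i] <- pmin(pmax((ch - q[1L]) / (q[2L] - q[1L]), 0), 1)
    }
  }
  attr(out, "bands") <- idx
  attr(out, "bandWavelengths") <- wl[idx]
  out
}

#' Export a pseudo-RGB rendering to PNG
#'
#' @inheritParams pseudoRGB
#' @param path output PNG path.
#' @param ... passed on to [pseudoRGB()].
#' @return Invisibly, `path`.
#' @export
writePseudoRGB <- function(cube, path, ...) {
  img <- pseudoRGB(cube, ...)
  attributes(img)[c("bands", "bandWavelengths")] <- NULL
  png::writePNG(img, target = path)
  invisible(path)
}
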