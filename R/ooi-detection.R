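# Object-of-interest detection: group non-background pixels of a
# classification map into connected components, label each component by
# majority vote over its pixel categories, filter by size, and summarise
# counts and densities per survey.

# connected-component labelling by iterative minimum-label propagation.
# mask: logical matrix; returns an integer matrix with 0 outside the mask
# and components numbered 1..k inside.
.labelComponents <- function(mask, connectivity = 8L) {
  L <- nrow(mask); S <- ncol(mask)
  lab <- matrix(Inf, L, S)
  lab[mask] <- which(mask)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  shift <- function(m, dl, ds) {
    out <- matrix(Inf, L, S)
    lsrc <- max(1L, 1L - dl):min(L, L - dl)
    ssrc <- max(1L, 1L - ds):min(S, S - ds)
    out[lsrc + dl, ssrc + ds] <- m[lsrc, ssrc]
    out
  }
  repeat {
    new <- lab
    for (sh in shifts) new <- pmin(new, shift(lab, sh[1L], sh[2L]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, L, S)
  if (any(mask)) {
    roots <- lab[mask]
    out[mask] <- as.integer(factor(roots, levels = sort(unique(roots))))
  }
  out
}

#' Detect objects of interest in a classification map
#'
#' Background pixels (sediment, manganese nodule) are masked out; the
#' remaining pixels are grouped into connected components regardless of
#' category, so an organism whose rim pixels were misclassified as a
#' similar category still forms a single object. Each component is labelled
#' by the majority category of its pixels (ties resolved alphabetically
#' with a warning), and components smaller than `minSizePx` are discarded.
#'
#' @param cmap a [ClassificationMap-class] whose legend contains at least
#'   one background class (or set `noBackground = TRUE`).
#' @param minSizePx minimum component size in pixels (default 20, i.e.
#'   2 cm^2 at 1 mm pixels — below the smallest organisms reported but
#'   above single-pixel noise).
#' @param connectivity 4 or 8 (default 8: diagonally touching pixels merge,
#'   since organisms are contiguous bodies).
#' @param pixelSizeMM pixel size in mm for the area conversions.
#' @param noBackground set TRUE to treat every category as foreground.
#' @return data.frame with one row per OOI: `ooi_id`, `category`,
#'   `pixel_area`, `area_cm2`, `equiv_diam_cm` (diameter of the equal-area
#'   disc), `centroid_line`, `centroid_sample`, `bbox_*`, and `purity`
#'   (fraction of pixels carrying the majority label). Attributes
#'   `n_background_px` and `n_filtered_px` allow pixel-conservation
#'   checks, and `component_map` is an integer raster assigning each kept
#'   component's pixels the row number of its OOI (0 elsewhere).
#' @export
detectOOIs <- function(cmap, minSizePx = 20L, connectivity = c(8L, 4L),
                       pixelSizeMM = 1.0, noBackground = FALSE) {
  stopifnot(is(cmap, "ClassificationMap"))
  connectivity <- as.integer(connectivity)[1L]
  if (!connectivity %in% c(4L, 8L))
    .stopf("connectivity must be 4 or 8")
  legend <- cmap@legend
  bgCats <- if (noBackground) character(0) else cmap@background
  if (!noBackground && !length(intersect(bgCats, legend)))
    .stopf("legend has no background class; pass noBackground = TRUE to treat all categories as foreground")
  bgCodes <- as.integer(names(legend)[legend %in% bgCats])
  mask <- !(cmap@labels %in% bgCodes)
  dim(mask) <- dim(cmap@labels)
  comp <- .labelComponents(mask, connectivity)
  nBg <- sum(!mask)
  k <- max(comp)
  rows <- list()
  nFiltered <- 0L
  cmPerPx2 <- (pixelSizeMM / 10)^2
  ord <- order(comp[comp > 0L])
  pixIdx <- which(comp > 0L)[ord]
  compID <- comp[pixIdx]
  byComp <- split(pixIdx, compID)
  L <- nrow(cmap@labels)
  compMap <- matrix(0L, nrow(cmap@labels), ncol(cmap@labels))
  for (ci in seq_along(byComp)) {
    px <- byComp[[ci]]
    area <- length(px)
    if (area < minSizePx) {
      nFiltered <- nFiltered + area
      next
    }
    compMap[px] <- length(rows) + 1L
    cats <- legend[as.character(cmap@labels[px])]
    tab <- sort(table(cats), decreasing = TRUE)
    topCount <- tab[1L]
    tiedNames <- sort(names(tab)[tab == topCount])
    if (length(tiedNames) > 1L)
      .warnf("OOI component of %d px: categories %s tie at %d px each; using '%s' (alphabetical)",
             area, paste(tiedNames, collapse = ", "), topCount, tiedNames[1L])
    majority <- tiedNames[1L]
    lines <- ((px - 1L) %% L) + 1L
    samps <- ((px - 1L) %/% L) + 1L
    areaCM2 <- area * cmPerPx2
    rows[[length(rows) + 1L]] <- data.frame(
      ooi_id = NA_character_, category = majority,
      pixel_area = area, area_cm2 = areaCM2,
      equiv_diam_cm = 2 * sqrt(areaCM2 / pi),
      centroid_line = mean(lines), centroid_sample = mean(samps),
      bbox_line_min = min(lines), bbox_line_max = max(lines),
      bbox_sample_min = min(samps), bbox_sample_max = max(samps),
      purity = as.numeric(topCount) / area,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ooi_id = character(0), category = character(0),
    pixel_area = integer(0), area_cm2 = numeric(0),
    equiv_diam_cm = numeric(0), centroid_line = numeric(0),
    centroid_sample = numeric(0), bbox_line_min = integer(0),
    bbox_line_max = integer(0), bbox_sample_min = integer(0),
    bbox_sample_max = integer(0), purity = numeric(0),
    stringsAsFactors = FALSE)
  if (nrow(out)) out$ooi_id <- sprintf("ooi_%03d", seq_len(nrow(out)))
  attr(out, "n_background_px") <- nBg
  attr(out, "n_filtered_px") <- nFiltered
  attr(out, "component_map") <- compMap
  out
}

#' Density of OOIs per square metre
#'
#' @param count number of individuals.
#' @param areaM2 surveyed area in square metres (> 0).
#' @return individuals per square metre, at full precision (round to 2
#'   decimals only when reporting).
#' @examples
#' round(computeDensity(39, 72.3), 2)  # 0.54
#' @export
computeDensity <- function(count, areaM2) {
  if (!is.finite(areaM2) || areaM2 <= 0)
    .stopf("surveyed area must be positive, got %s", format(areaM2))
  count / areaM2
}

#' Summarise a survey's OOIs
#'
#' Per-category counts and densities over the surveyed area, across one or
#' several transects.
#'
#' @param oois data.frame of detected OOIs (as from [detectOOIs()],
#'   possibly row-bound over transects), or a list of such data.frames.
#' @param areaM2 total surveyed area in square metres.
#' @param categories optional category vocabulary fixing the rows of the
#'   summary (defaults to the categories present).
#' @return A [SurveySummary-class].
#' @export
summarizeSurvey <- function(oois, areaM2, categories = NULL) {
  if (is.list(oois) && !is.data.frame(oois))
    oois <- do.call(rbind, oois)
  cats <- if (nrow(oois)) oois$category else character(0)
  if (is.null(categories)) categories <- sort(unique(cats))
  counts <- table(factor(cats, levels = categories))
  counts <- stats::setNames(as.integer(counts), categories)
  dens <- vapply(counts, computeDensity, numeric(1), areaM2 = areaM2)
  new("SurveySummary", counts = counts, densities = dens,
      total = sum(counts), areaM2 = areaM2)
}

#' Tabulate a survey summary
#'
#' @param summary a [SurveySummary-class].
#' @param digits decimal places for the reported densities (default 2, the
#'   conventional reporting precision).
#' @return data.frame with columns `category`, `count`,
#'   `density_per_m2`.
#' @export
summaryToDataFrame <- function(summary, digits = 2L) {
  data.frame(category = names(summary@counts),
             count = unname(summary@counts),
             density_per_m2 = round(unname(summary@densities), digits),
             stringsAsFactors = FALSE)
}
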