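# Synthetic seafloor-scene generator.  Produces raw cubes with ground truth
# by inverting the correction chain the pipeline applies:
#   pixel value = material_reflectance(lambda) * illumination(line, sample)
#                 * lamp_spectrum(lambda) + noise,
# with abyssal sediment + manganese-nodule background, disc-shaped fauna
# and anomaly objects, a multiplicative cross-track illumination profile,
# an along-track gain drift, and band-dependent Gaussian noise that is
# inflated outside the 400-710 nm window (emulating the noisy spectral
# margins that motivate subsetting).

#' Make a regular band grid
#'
#' The default emulates the imager's 112-band configuration: centers at
#' `start + k * spacing`. The default 3.75 nm spacing from 378 nm is chosen
#' so that inclusive subsetting to \[400, 710\] nm retains exactly 83 bands,
#' matching the instrument's processed band counts; the true instrument
#' grid can be supplied when known.
#'
#' @param n number of bands (default 112, >= 2).
#' @param startNM first band center in nm (default 378).
#' @param spacingNM band spacing in nm (default 3.75, > 0).
#' @return numeric vector of band centers in nm.
#' @export
makeBandGrid <- function(n = 112L, startNM = 378.0, spacingNM = 3.75) {
  n <- as.integer(n)
  if (n < 2L) .stopf("a band grid needs at least 2 bands")
  if (spacingNM <= 0) .stopf("band spacing must be positive")
  startNM + (seq_len(n) - 1L) * spacingNM
}

# gaussian bump on the wavelength axis
.gauss <- function(wl, center, width) exp(-((wl - center)^2) / (2 * width^2))

# baseline + feature parameters per category.  Baselines are gentle
# functions of wavelength; each fauna category carries 1-3 positive
# Gaussian reflectance features at category-specific centers so that all
# catalog spectra are pairwise separated in spectral contrast angle.
.materialParams <- list(
  sediment   = list(b0 = 0.35, b1 = 0.10, g = list()),
  nodule     = list(b0 = 0.07, b1 = -0.025, g = list()),
  white_exposed_sediment = list(b0 = 0.60, b1 = -0.04,
                                g = list(c(470, 60, 0.08))),
  sponge_round = list(b0 = 0.30, b1 = 0.00, g = list(c(440, 30, 0.20))),
  sponge_disc  = list(b0 = 0.30, b1 = 0.00,
                      g = list(c(460, 25, 0.18), c(600, 40, 0.14))),
  glass_sponge = list(b0 = 0.45, b1 = 0.12, g = list(c(420, 25, 0.22))),
  coral_white  = list(b0 = 0.58, b1 = 0.00, g = list(c(640, 60, 0.12))),
  coral_yellow = list(b0 = 0.25, b1 = 0.00, g = list(c(580, 40, 0.30))),
  coral_green  = list(b0 = 0.20, b1 = 0.00, g = list(c(550, 30, 0.28))),
  holothurian_synallactidae = list(b0 = 0.28, b1 = 0.00,
                                   g = list(c(630, 25, 0.25))),
  holothurian_paelopatides  = list(b0 = 0.28, b1 = 0.00,
                                   g = list(c(690, 30, 0.22))),
  ophiuroid_white = list(b0 = 0.45, b1 = 0.00,
                         g = list(c(500, 40, 0.18), c(680, 25, 0.10))),
  ophiuroid_red   = list(b0 = 0.22, b1 = 0.00, g = list(c(650, 45, 0.30))),
  crustacean = list(b0 = 0.30, b1 = 0.00,
                    g = list(c(585, 60, 0.22), c(450, 25, 0.10))),
  salp_dead  = list(b0 = 0.42, b1 = -0.10, g = list(c(490, 40, 0.18))),
  polychaete = list(b0 = 0.26, b1 = 0.00,
                    g = list(c(480, 35, 0.18), c(640, 30, 0.12))),
  crinoid    = list(b0 = 0.24, b1 = 0.00,
                    g = list(c(530, 25, 0.22), c(590, 25, 0.14))),
  isopod     = list(b0 = 0.33, b1 = 0.06, g = list(c(560, 45, 0.20))),
  bony_fish  = list(b0 = 0.44, b1 = 0.00,
                    g = list(c(460, 35, 0.10), c(700, 40, 0.12)))
)

.materialSpectrum <- function(category, wl) {
  sedBase <- function(w) {
    p <- .materialParams$sediment
    p$b0 + p$b1 * (w - 400) / 310
  }
  if (category == "green_spot" || category == "white_spot") {
    # sediment baseline carved by a chlorophyll-a-like absorption dip at
    # 675 nm; white spots are shallower and slightly brighter in the red
    depth <- if (category == "green_spot") 0.5 else 0.35
    r <- sedBase(wl) * (1 - depth * .gauss(wl, 675, 8))
    if (category == "white_spot")
      r <- r * (1 + 0.15 / (1 + exp(-(wl - 650) / 5)))
    return(r)
  }
  p <- .materialParams[[category]]
  if (is.null(p)) .stopf("no material model for category '%s'", category)
  r <- p$b0 + p$b1 * (wl - 400) / 310
  for (g in p$g) r <- r + g[3L] * .gauss(wl, g[1L], g[2L])
  r
}

#' True-reflectance catalog of scene materials
#'
#' Builds the reflectance spectrum of each category on a band grid:
#' a smooth bright baseline for sediment, a dark flat baseline for
#' manganese nodules, baseline + 1-3 positive Gaussian features at
#' category-specific centers for fauna, and a sediment baseline carved by
#' a chlorophyll-a-like absorption dip (center 675 nm, sigma 8 nm; depth
#' 0.5 for green spots, 0.35 for white spots, with white spots brightened
#' by a factor 1.15 above 650 nm). All spectra lie in (0, 1\] and every
#' pair of *fauna* spectra is separated by at least `minAngleDeg` of
#' spectral contrast angle; a catalog violating either constraint is an
#' error. The anomaly and background spectra are exempt from the strict
#' separation check because their shapes are pinned by the phenomenology
#' above — green and white spots in particular are deliberately
#' similar in shape (they differ mainly in dip depth and red-end
#' intensity, which is what distinguishes them in the field data too).
#'
#' The dip parameters are phenomenological descriptions of the anomaly
#' spectra's qualitative shape, not claims about organism pigments.
#'
#' @param wavelengths band grid in nm.
#' @param categoriesNames character vector of categories (defaults to the
#'   full vocabulary plus backgrounds).
#' @param minAngleDeg minimum pairwise spectral contrast angle enforced at
#'   build time (default 5).
#' @return numeric matrix, one row per category (rownames = categories).
#' @export
materialCatalog <- function(wavelengths,
                            categoriesNames = defaultCategories(background = TRUE),
                            minAngleDeg = 5) {
  M <- do.call(rbind, lapply(categoriesNames, .materialSpectrum,
                             wl = wavelengths))
  rownames(M) <- categoriesNames
  if (any(M <= 0) || any(M > 1))
    .stopf("material catalog outside (0, 1]: check category parameters")
  fauna <- which(categoriesNames %in% defaultCategories()[1:16])
  if (length(fauna) > 1L) {
    for (i in fauna[-length(fauna)]) for (j in fauna[fauna > i]) {
      ang <- spectralContrastAngle(M[i, ], M[j, ])
      if (ang < minAngleDeg)
        .stopf("catalog spectra '%s' and '%s' are only %.2f deg apart (< %.1f deg)",
               categoriesNames[i], categoriesNames[j], ang, minAngleDeg)
    }
  }
  M
}

#' Scene configuration for the synthetic generator
#'
#' Defaults emulate the study conditions: 1 mm pixels, a 112-band grid
#' spanning ~378-794 nm, noisy bands outside 400-710 nm (noise inflated
#' x5 there), a multiplicative cross-track illumination profile (cosine
#' falloff to 0.6 at the swath edges) with a +/-5 percent along-track gain
#' drift, sediment + manganese-nodule background, disc-shaped fauna of
#' 1.5-6 cm diameter and circular anomaly spots of 0.8-2 cm.
#'
#' @param lines,samples scene size in pixels (defaults 300 x 400).
#' @param pixelSizeMM pixel size in mm (default 1).
#' @param nBands,startNM,spacingNM band grid (see [makeBandGrid()]).
#' @param categoriesNames object categories planted in the scene (default: six
#'   fauna/anomaly categories).
#' @param nPerCategory objects planted per category (default 5).
#' @param faunaDiamCM diameter range in cm for fauna/anomaly objects other
#'   than spots.
#' @param spotDiamCM diameter range in cm for green/white spots (field
#'   reports put them at or below 2 cm).
#' @param nNodules number of background manganese-nodule discs.
#' @param noduleDiamCM nodule diameter range in cm.
#' @param clearancePx clear-sediment margin in pixels kept around every
#'   planted fauna/anomaly object (default 10, i.e. 1 cm at 1 mm pixels:
#'   distinct organisms are rendered as separate bodies, not touching);
#'   background nodules use a fixed 2 px margin.
#' @param illumEdgeFactor cross-track illumination at the swath edge
#'   relative to the center (1 = flat field).
#' @param illumDriftFrac along-track sinusoidal gain drift amplitude.
#' @param noiseFrac Gaussian noise standard deviation as a fraction of the
#'   signal (0 disables noise).
#' @param noiseInflate noise multiplier outside `noiseWindowNM`.
#' @param noiseWindowNM low-noise wavelength window in nm.
#' @param lampScale overall lamp intensity scale (arbitrary counts).
#' @param seed integer seed governing placement and noise.
#' @param trackID track identifier stamped on the cube.
#' @param maxPlacementTries rejection-sampling budget per object.
#' @return named list of class `"SceneConfig"`.
#' @export
sceneConfig <- function(lines = 300L, samples = 400L, pixelSizeMM = 1.0,
                        nBands = 112L, startNM = 378.0, spacingNM = 3.75,
                        categoriesNames = c("coral_white", "sponge_round",
                                            "ophiuroid_red", "polychaete",
                                            "green_spot", "white_spot"),
                        nPerCategory = 5L,
                        faunaDiamCM = c(1.5, 6), spotDiamCM = c(0.8, 2),
                        nNodules = 40L, noduleDiamCM = c(1, 3),
                        clearancePx = 10L,
                        illumEdgeFactor = 0.6, illumDriftFrac = 0.05,
                        noiseFrac = 0.01, noiseInflate = 5,
                        noiseWindowNM = c(400, 710),
                        lampScale = 1000, seed = 1L,
                        trackID = "synthetic",
                        maxPlacementTries = 2000L) {
  stopifnot(lines > 0, samples > 0, pixelSizeMM > 0,
            all(faunaDiamCM > 0), all(spotDiamCM > 0),
            nPerCategory >= 1, illumEdgeFactor > 0, noiseFrac >= 0)
  structure(as.list(environment()), class = "SceneConfig")
}

.spotCategories <- c("green_spot", "white_spot")

# place a disc of radius r (pixels) on free sediment, keeping `clear` px of
# sediment margin around it; returns pixel indices (column-major over
# lines x samples) or NULL if no free spot found
.placeDisc <- function(labels, sedimentCode, r, L, S, tries, clear = 0L) {
  rI <- ceiling(r)
  rC <- rI + clear
  if (L - 2L * rC < 1L || S - 2L * rC < 1L)
    .stopf("a disc of radius %d px (+%d px clearance) does not fit in a %d x %d scene",
           rI, clear, L, S)
  for (t in seq_len(tries)) {
    cl <- sample.int(L - 2L * rC, 1L) + rC
    cs <- sample.int(S - 2L * rC, 1L) + rC
    ll <- (cl - rC):(cl + rC)
    ss <- (cs - rC):(cs + rC)
    grid <- expand.grid(l = ll, s = ss)
    inClear <- (grid$l - cl)^2 + (grid$s - cs)^2 <= (r + clear)^2
    pxClear <- grid$l[inClear] + (grid$s[inClear] - 1L) * L
    if (all(labels[pxClear] == sedimentCode)) {
      keep <- (grid$l - cl)^2 + (grid$s - cs)^2 <= r^2
      px <- grid$l[keep] + (grid$s[keep] - 1L) * L
      return(list(px = px, center = c(cl, cs)))
    }
  }
  NULL
}

#' Generate a synthetic raw scene with ground truth
#'
#' Renders the configured objects as discs on a sediment background with
#' scattered manganese nodules, then forms the raw cube as
#' `reflectance * illumination * lamp + noise` (noise clamped so values
#' stay nonnegative). The run is fully reproducible from the config's
#' seed: placement, and noise all flow from one generator.
#'
#' @param cfg a [sceneConfig()].
#' @return list with elements `cube` (a raw [HyperCube-class]) and `truth`
#'   (a [SceneTruth-class]: label raster, per-object id raster, object
#'   table, true material spectra and the illumination field).
#' @examples
#' cfg <- sceneConfig(lines = 80, samples = 100, nPerCategory = 1,
#'                    nNodules = 5, faunaDiamCM = c(1, 2.5), seed = 7)
#' sc <- generateScene(cfg)
#' sc$truth
#' @export
generateScene <- function(cfg = sceneConfig()) {
  stopifnot(inherits(cfg, "SceneConfig"))
  set.seed(cfg$seed)
  L <- as.integer(cfg$lines); S <- as.integer(cfg$samples)
  wl <- makeBandGrid(cfg$nBands, cfg$startNM, cfg$spacingNM)
  allCats <- c("sediment", "nodule", cfg$categoriesNames)
  materials <- materialCatalog(wl, allCats)
  legend <- stats::setNames(allCats, seq_along(allCats))

  labels <- matrix(1L, L, S)                 # 1 = sediment
  objectIDs <- matrix(0L, L, S)
  objRows <- list()

  plant <- function(category, diamCM, background) {
    r <- diamCM * 10 / cfg$pixelSizeMM / 2   # radius in pixels
    clear <- if (background) 2L else as.integer(cfg$clearancePx)
    disc <- .placeDisc(labels, 1L, r, L, S, cfg$maxPlacementTries,
                       clear = clear)
    if (is.null(disc))
      .stopf("could not place a %.1f cm '%s' without overlap after %d tries",
             diamCM, category, cfg$maxPlacementTries)
    code <- which(allCats == category)
    labels[disc$px] <<- code
    id <- length(objRows) + 1L
    objectIDs[disc$px] <<- id
    objRows[[id]] <<- data.frame(
      id = id, category = category,
      centerLine = disc$center[1L], centerSample = disc$center[2L],
      diameterCM = diamCM, nPixels = length(disc$px),
      background = background, stringsAsFactors = FALSE)
  }

  # draw all object specs first, then place largest-first (fauna/anomalies
  # before nodules) so big discs are not squeezed out of a crowded scene
  specs <- list()
  for (category in cfg$categoriesNames) {
    rng <- if (category %in% .spotCategories) cfg$spotDiamCM else cfg$faunaDiamCM
    for (i in seq_len(cfg$nPerCategory))
      specs[[length(specs) + 1L]] <- list(
        category = category, diamCM = stats::runif(1, rng[1L], rng[2L]),
        background = FALSE)
  }
  nodSpecs <- lapply(seq_len(cfg$nNodules), function(i) list(
    category = "nodule",
    diamCM = stats::runif(1, cfg$noduleDiamCM[1L], cfg$noduleDiamCM[2L]),
    background = TRUE))
  bySize <- function(sp) sp[order(-vapply(sp, `[[`, numeric(1), "diamCM"))]
  for (sp in c(bySize(specs), bySize(nodSpecs)))
    plant(sp$category, sp$diamCM, sp$background)
  objects <- do.call(rbind, objRows)

  # multiplicative illumination: static cross-track cosine profile times a
  # +/- drift along track
  xs <- if (S > 1L) seq(-1, 1, length.out = S) else 0
  cross <- cfg$illumEdgeFactor + (1 - cfg$illumEdgeFactor) * cospi(xs / 2)
  gain <- 1 + cfg$illumDriftFrac * sin(2 * pi * seq_len(L) / L)
  illum <- outer(gain, cross)

  lamp <- cfg$lampScale * (0.35 + 0.65 * .gauss(wl, 560, 130))
  noiseF <- cfg$noiseFrac *
    ifelse(wl >= cfg$noiseWindowNM[1L] & wl <= cfg$noiseWindowNM[2L],
           1, cfg$noiseInflate)

  refl <- materials[as.vector(labels), , drop = FALSE]   # pixels x bands
  illumVec <- as.vector(illum)
  npix <- L * S
  vals <- matrix(0, npix, length(wl))
  for (b in seq_along(wl)) {
    sig <- refl[, b] * illumVec * lamp[b]
    if (noiseF[b] > 0)
      sig <- pmax(sig * (1 + stats::rnorm(npix) * noiseF[b]), 0)
    vals[, b] <- sig
  }

  cube <- HyperCube(.matrixCube(vals, L, S), wl,
                    pixelSizeMM = cfg$pixelSizeMM, stage = "raw",
                    trackID = cfg$trackID)
  truth <- new("SceneTruth", labels = labels, legend = legend,
               objectIDs = objectIDs, objects = objects,
               materials = materials, wavelengths = wl,
               illumination = illum)
  list(cube = cube, truth = truth)
}

#' ROIs for planted objects from scene ground truth
#'
#' @param truth a [SceneTruth-class].
#' @param ids object ids to extract (default: all non-background objects).
#' @param source provenance recorded on the ROIs.
#' @return list of [ROI-class] whose pixels are each object's true pixels.
#' @export
truthROIs <- function(truth, ids = NULL, source = "video_identified") {
  stopifnot(is(truth, "SceneTruth"))
  if (is.null(ids))
    ids <- truth@objects$id[!truth@objects$background]
  lapply(ids, function(i) {
    ROI(sprintf("truth_%03d", i), truth@objects$category[i],
        which(truth@objectIDs == i, arr.ind = TRUE), source = source)
  })
}

#' Background training ROIs from scene ground truth
#'
#' Deterministically selects pure-sediment square patches (scanning the
#' scene on a regular grid) and the largest planted nodules, for use as
#' background training regions.
#'
#' @param truth a [SceneTruth-class].
#' @param nSediment number of sediment patches (default 24); candidate
#'   patches are scanned over the whole frame and subsampled evenly so the
#'   selection spans the swath (and hence the cross-track illumination
#'   conditions).
#' @param patchPx side length of each sediment patch in pixels (default 10).
#' @param nNodules number of nodule ROIs (default 5).
#' @return list of [ROI-class] with categories `"sediment"` / `"nodule"`.
#' @export
backgroundROIs <- function(truth, nSediment = 24L, patchPx = 10L,
                           nNodules = 5L) {
  stopifnot(is(truth, "SceneTruth"))
  L <- nrow(truth@labels); S <- ncol(truth@labels)
  rois <- list()
  sedCode <- which(truth@legend == "sediment")
  step <- patchPx + 5L
  cand <- list()
  for (s0 in seq(1L, S - patchPx, by = step)) {
    for (l0 in seq(1L, L - patchPx, by = step)) {
      block <- truth@labels[l0:(l0 + patchPx - 1L), s0:(s0 + patchPx - 1L)]
      if (all(block == sedCode))
        cand[[length(cand) + 1L]] <- c(l0, s0)
    }
  }
  if (length(cand) < nSediment)
    .warnf("only %d pure sediment patches found (asked for %d)",
           length(cand), nSediment)
  for (ci in .evenSubsample(length(cand), nSediment)) {
    l0 <- cand[[ci]][1L]; s0 <- cand[[ci]][2L]
    grid <- expand.grid(line = l0:(l0 + patchPx - 1L),
                        sample = s0:(s0 + patchPx - 1L))
    rois[[length(rois) + 1L]] <-
      ROI(sprintf("bg_sed_%02d", length(rois) + 1L), "sediment",
          as.matrix(grid))
  }
  nod <- truth@objects[truth@objects$background &
                         truth@objects$category == "nodule", ]
  nod <- nod[order(-nod$nPixels), ]
  for (i in seq_len(min(nNodules, nrow(nod)))) {
    id <- nod$id[i]
    rois[[length(rois) + 1L]] <-
      ROI(sprintf("bg_nod_%02d", i), "nodule",
          which(truth@objectIDs == id, arr.ind = TRUE))
  }
  rois
}

#' Match detected OOIs against scene ground truth
#'
#' For every planted non-background object, checks whether a detected OOI
#' overlaps its true pixels and carries its true category.
#'
#' @param truth a [SceneTruth-class].
#' @param oois a detection table from [detectOOIs()] (its `component_map`
#'   attribute is used for the overlap test).
#' @return data.frame with one row per planted object: `id`, `category`,
#'   `nPixels`, `recovered` (a detected OOI overlaps it) and
#'   `recoveredCorrect` (the overlapping OOI carries the true category).
#' @export
matchDetectionsToTruth <- function(truth, oois) {
  stopifnot(is(truth, "SceneTruth"))
  compMap <- attr(oois, "component_map")
  if (is.null(compMap))
    .stopf("the detection table has no component_map attribute")
  objs <- truth@objects[!truth@objects$background, , drop = FALSE]
  res <- lapply(seq_len(nrow(objs)), function(k) {
    id <- objs$id[k]
    hits <- unique(compMap[truth@objectIDs == id])
    hits <- hits[hits > 0L]
    correct <- length(hits) > 0L &&
      any(oois$category[hits] == objs$category[k])
    data.frame(id = id, category = objs$category[k],
               nPixels = objs$nPixels[k],
               recovered = length(hits) > 0L,
               recoveredCorrect = correct, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
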