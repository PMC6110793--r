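# End-to-end orchestration: preprocess -> reference library from
# video-identified ROIs -> angle-match unidentified ROIs -> expand the
# library -> SVM train/classify -> detect OOIs -> survey summary.

#' Surveyed seafloor area of a set of cubes
#'
#' @param cubes list of [HyperCube-class] (one per survey track).
#' @return total area in square metres:
#'   sum of lines x samples x (pixel size in m)^2.
#' @examples
#' cube <- HyperCube(array(1, c(1000, 1000, 3)), c(450, 550, 650))
#' computeSurveyedArea(list(cube))  # 1 m2 at 1 mm pixels
#' @export
computeSurveyedArea <- function(cubes) {
  if (!length(cubes)) return(0)
  sum(vapply(cubes, function(cube) {
    d <- dim(cube@values)
    d[1L] * d[2L] * (cube@pixelSizeMM / 1000)^2
  }, numeric(1)))
}

#' Run the full analysis pipeline on one cube
#'
#' Executes the workflow in order: preprocessing (subset, pseudo-reflectance,
#' smoothing); reference-library construction from the video-identified
#' ROIs; spectral contrast angle matching of the unidentified ROIs, each
#' assigned the category of its smallest-angle library entry; library
#' expansion with those newly identified OOIs; SVM training on the expanded
#' ROI set and per-pixel classification; connected-component OOI detection;
#' and a survey summary with counts and densities. Each stage's parameters
#' and outcome are appended to a run log, and any stage error is re-raised
#' with the stage name.
#'
#' @param cube a raw [HyperCube-class].
#' @param videoROIs list of category-labelled [ROI-class] identified from
#'   video/sampling, including background (sediment/nodule) patches.
#' @param unknownROIs list of [ROI-class] of unidentified spectral
#'   anomalies (categories ignored; assigned by angle matching).
#' @param preprocess a [preprocessConfig()].
#' @param trainingMode `"roi_pixels"` (default) or `"avg_spectra"`.
#' @param gamma,cost SVM hyperparameters (see [trainClassifier()]).
#' @param minSizePx,connectivity detection parameters (see [detectOOIs()]).
#' @param thetaMax optional angle-matching reject threshold in degrees.
#' @param areaM2 surveyed area; computed from the cube when `NULL`.
#' @return list of class `"benthospecPipelineResult"`: `preprocessed`,
#'   `library` (expanded [SpectralLibrary-class]), `matches`,
#'   `classification` ([ClassificationMap-class]), `oois` (data.frame),
#'   `summary` ([SurveySummary-class]) and `log` (character).
#' @export
runPipeline <- function(cube, videoROIs, unknownROIs = list(),
                        preprocess = preprocessConfig(),
                        trainingMode = c("roi_pixels", "avg_spectra"),
                        gamma = NULL, cost = 100,
                        minSizePx = 20L, connectivity = 8L,
                        thetaMax = NULL, areaM2 = NULL) {
  trainingMode <- match.arg(trainingMode)
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  note("preprocess: subset [%g, %g] nm, reference %s, window %d bands",
       preprocess$subsetMinNM, preprocess$subsetMaxNM,
       preprocess$referenceMode, preprocess$smoothWindowBands)
  pre <- stage("preprocess", preprocessCube(cube, preprocess))

  if (!length(videoROIs))
    .stopf("pipeline stage 'library' failed: no video-identified ROIs supplied")
  libROIs <- Filter(function(r) !r@category %in% backgroundClasses(),
                    videoROIs)
  lib <- stage("library", buildLibrary(pre, libROIs))
  note("library: %d video-identified reference spectra", length(lib))

  matches <- list()
  identifiedROIs <- videoROIs
  if (length(unknownROIs)) {
    matches <- stage("match", matchROIs(pre, unknownROIs, lib,
                                        thetaMax = thetaMax))
    for (i in seq_along(unknownROIs)) {
      m <- matches[[i]]
      note("match: '%s' -> %s (theta_min %.2f deg)",
           m@queryID, m@bestCategory, m@thetaMin)
      if (m@bestCategory == "unassigned") next
      roi <- unknownROIs[[i]]
      roi@category <- m@bestCategory
      roi@source <- "spectral_anomaly"
      identifiedROIs <- c(identifiedROIs, roi)
      lib <- stage("expand-library",
                   addEntry(lib, extractROISpectrum(pre, roi)))
    }
    note("expand-library: %d entries after expansion", length(lib))
  }

  ts <- stage("training", assembleTraining(pre, identifiedROIs,
                                           mode = trainingMode))
  note("training: %d samples, %d categories, mode %s",
       nrow(ts@samples), nlevels(droplevels(ts@labels)), trainingMode)
  model <- stage("training", trainClassifier(ts, gamma = gamma, cost = cost))
  cmap <- stage("classify", classifyCube(pre, model))
  oois <- stage("detect", detectOOIs(cmap, minSizePx = minSizePx,
                                     connectivity = connectivity,
                                     pixelSizeMM = pixelSizeMM(cube)))
  note("detect: %d OOIs (min size %d px, connectivity %d)",
       nrow(oois), minSizePx, connectivity)
  if (is.null(areaM2)) areaM2 <- computeSurveyedArea(list(cube))
  summary <- stage("summary", summarizeSurvey(oois, areaM2))
  note("summary: %d OOIs over %.3f m2", summary@total, areaM2)

  structure(list(preprocessed = pre, library = lib, matches = matches,
                 classification = cmap, oois = oois, summary = summary,
                 log = log),
            class = "benthospecPipelineResult")
}

#' @export
print.benthospecPipelineResult <- function(x, ...) {
  cat("benthospec pipeline result\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Benchmark the full pipeline on synthetic scenes
#'
#' The standard validation protocol: for each seed, generate a default
#' synthetic scene, preprocess it, build training ROIs from half of the
#' planted objects per category plus background patches, train the SVM,
#' classify every pixel, detect OOIs, and score the result against the
#' scene's ground truth.
#'
#' @param seeds integer vector of scene seeds.
#' @param config a [sceneConfig()] whose `seed` is replaced per run.
#' @param trainingMode passed to [assembleTraining()].
#' @param minSizePx,connectivity passed to [detectOOIs()].
#' @return data.frame with one row per seed: `seed`, `pixelAccuracy`
#'   (fraction of pixels whose predicted category equals the truth),
#'   `objectRecovery` (fraction of planted objects overlapped by a
#'   detected OOI of the correct category), `nPlanted`, `nDetected`.
#' @export
syntheticBenchmark <- function(seeds = c(101L, 202L, 303L, 404L, 505L),
                               config = sceneConfig(),
                               trainingMode = "roi_pixels",
                               minSizePx = 20L, connectivity = 8L) {
  rows <- lapply(seeds, function(sd) {
    cfg <- config
    cfg$seed <- sd
    sc <- generateScene(cfg)
    pre <- preprocessCube(sc$cube, preprocessConfig())
    truth <- sc$truth
    objs <- truth@objects[!truth@objects$background, ]
    trainIDs <- unlist(lapply(split(objs$id, objs$category),
                              function(ids) ids[seq_len(ceiling(length(ids) / 2))]))
    rois <- c(suppressWarnings(truthROIs(truth, ids = trainIDs)),
              backgroundROIs(truth))
    ts <- suppressWarnings(assembleTraining(pre, rois, mode = trainingMode))
    model <- trainClassifier(ts)
    cmap <- suppressMessages(classifyCube(pre, model))
    predCats <- cmap@legend[as.character(cmap@labels)]
    trueCats <- truth@legend[as.character(truth@labels)]
    oois <- suppressWarnings(detectOOIs(cmap, minSizePx = minSizePx,
                                        connectivity = connectivity,
                                        pixelSizeMM = pixelSizeMM(sc$cube)))
    md <- matchDetectionsToTruth(truth, oois)
    data.frame(seed = sd,
               pixelAccuracy = mean(predCats == trueCats),
               objectRecovery = mean(md$recoveredCorrect),
               nPlanted = nrow(md), nDetected = nrow(oois))
  })
  do.call(rbind, rows)
}
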