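# Supervised per-pixel classification.  A multi-class (one-vs-one) support
# vector machine with a radial-basis kernel is fitted to labelled spectra
# from annotated ROIs and applied to every pixel of a preprocessed cube.

#' Assemble an SVM training set from ROIs
#'
#' Two training modes are supported. `"roi_pixels"` (the default) takes
#' individual pixel spectra from each ROI, subsampled deterministically to
#' at most `maxPixelsPerROI` per ROI so the fitted model stays compact;
#' `"avg_spectra"` takes one sample per OOI, its mean spectrum (the
#' procedure used when each identified OOI contributes a single reference
#' spectrum). Background ROIs (categories `"sediment"` and `"nodule"`) are
#' expected so the classifier can label non-OOI pixels; when absent a
#' warning flags the degraded OOI-only mode.
#'
#' @param cube a preprocessed [HyperCube-class].
#' @param rois list of category-labelled [ROI-class] (OOIs plus background
#'   patches).
#' @param mode `"roi_pixels"` or `"avg_spectra"`.
#' @param maxPixelsPerROI cap on pixels drawn per ROI in `"roi_pixels"`
#'   mode (evenly spaced, no randomness; default 150).
#' @return A [TrainingSet-class]; fewer than 2 distinct categories is an
#'   error.
#' @export
assembleTraining <- function(cube, rois,
                             mode = c("roi_pixels", "avg_spectra"),
                             maxPixelsPerROI = 150L) {
  stopifnot(is(cube, "HyperCube"))
  mode <- match.arg(mode)
  cats <- vapply(rois, function(r) r@category, character(1))
  if (length(unique(cats)) < 2L)
    .stopf("training needs at least 2 distinct categories, got %s",
           paste(unique(cats), collapse = ", "))
  bgPresent <- any(cats %in% backgroundClasses())
  if (!bgPresent)
    .warnf("no background (sediment/nodule) ROIs: classifier will run in degraded OOI-only mode")
  d <- dim(cube@values)
  flat <- .cubeMatrix(cube)
  X <- list(); y <- character(0); ids <- character(0)
  for (roi in rois) {
    px <- roi@pixels
    if (any(px[, 1L] > d[1L]) || any(px[, 2L] > d[2L]))
      .stopf("ROI '%s' has pixels outside the cube", roi@ooiID)
    rows <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
    if (mode == "avg_spectra") {
      X[[length(X) + 1L]] <- matrix(colMeans(flat[rows, , drop = FALSE]),
                                    nrow = 1L)
      y <- c(y, roi@category)
      ids <- c(ids, roi@ooiID)
    } else {
      rows <- rows[.evenSubsample(length(rows), maxPixelsPerROI)]
      X[[length(X) + 1L]] <- flat[rows, , drop = FALSE]
      y <- c(y, rep(roi@category, length(rows)))
      ids <- c(ids, rep(roi@ooiID, length(rows)))
    }
  }
  new("TrainingSet", samples = do.call(rbind, X),
      labels = factor(y, levels = sort(unique(y))),
      ooiIDs = ids, wavelengths = cube@wavelengths, mode = mode,
      backgroundPresent = bgPresent)
}

#' Train the SVM pixel classifier
#'
#' Fits a multi-class (one-vs-one) support vector machine with a
#' radial-basis kernel. Defaults: `gamma = 1 / n_bands`, penalty
#' `cost = 100`. The fit is deterministic for a given training set and is
#' insensitive to the ordering of training samples.
#'
#' @param ts a [TrainingSet-class].
#' @param gamma RBF kernel width (default `1 / ncol(samples)`).
#' @param cost soft-margin penalty C (default 100).
#' @return A fitted classifier (class `"benthospecSVM"`) usable with
#'   [classifyCube()] and [stats::predict()]. Identical spectra labelled
#'   with different categories are an error (the classes are inseparable by
#'   construction); the error lists the colliding OOIs.
#' @export
trainClassifier <- function(ts, gamma = NULL, cost = 100) {
  stopifnot(is(ts, "TrainingSet"))
  if (is.null(gamma)) gamma <- 1 / ncol(ts@samples)
  key <- apply(ts@samples, 1L, function(r) paste(signif(r, 12), collapse = ","))
  split_lab <- split(as.character(ts@labels), key)
  split_ids <- split(ts@ooiIDs, key)
  bad <- which(vapply(split_lab, function(l) length(unique(l)) > 1L, logical(1)))
  if (length(bad))
    .stopf("identical training spectra carry different categories: %s",
           paste(vapply(bad, function(i)
             paste(unique(split_ids[[i]]), collapse = "/"), character(1)),
             collapse = "; "))
  labels <- droplevels(ts@labels)
  # sort into a canonical order so the fit is invariant to sample ordering
  ord <- order(as.integer(labels), key)
  model <- e1071::svm(x = ts@samples[ord, , drop = FALSE],
                      y = labels[ord],
                      type = "C-classification", kernel = "radial",
                      gamma = gamma, cost = cost, scale = FALSE)
  structure(list(model = model, wavelengths = ts@wavelengths,
                 levels = levels(labels), mode = ts@mode,
                 gamma = gamma, cost = cost),
            class = "benthospecSVM")
}

#' @export
print.benthospecSVM <- function(x, ...) {
  cat(sprintf("benthospec SVM: %d categories, %d bands, gamma = %.4g, cost = %g, %d support vectors\n",
              length(x$levels), length(x$wavelengths), x$gamma, x$cost,
              x$model$tot.nSV))
  invisible(x)
}

#' @export
predict.benthospecSVM <- function(object, newdata, ...) {
  stats::predict(object$model, newdata, ...)
}

#' Classify every pixel of a cube
#'
#' Applies a trained classifier to each pixel spectrum and returns the
#' per-pixel category raster. Per-category pixel counts are reported via
#' `message()` as the run log.
#'
#' @param cube a preprocessed [HyperCube-class] on the training band grid.
#' @param model a `"benthospecSVM"` from [trainClassifier()].
#' @param chunkSize pixels predicted per block (memory control).
#' @param background categories to mark as seafloor background in the map.
#' @return A [ClassificationMap-class].
#' @export
classifyCube <- function(cube, model, chunkSize = 50000L,
                         background = backgroundClasses()) {
  stopifnot(is(cube, "HyperCube"), inherits(model, "benthospecSVM"))
  d <- dim(cube@values)
  if (d[3L] != length(model$wavelengths))
    .stopf("cube has %d bands but the model was trained on %d",
           d[3L], length(model$wavelengths))
  flat <- .cubeMatrix(cube)
  n <- nrow(flat)
  pred <- integer(n)
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    pred[idx] <- as.integer(stats::predict(model$model,
                                           flat[idx, , drop = FALSE]))
  }
  legend <- model$levels
  names(legend) <- seq_along(legend)
  counts <- table(factor(legend[pred], levels = legend))
  message("classifyCube: per-category pixel counts — ",
          paste(sprintf("%s: %d", names(counts), counts), collapse = ", "))
  new("ClassificationMap",
      labels = matrix(pred, d[1L], d[2L]),
      legend = legend,
      background = intersect(background, legend))
}
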