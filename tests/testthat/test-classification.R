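# SVM training-set assembly, fitting and per-pixel prediction

test_that("avg_spectra mode yields one sample per OOI (78 OOIs -> 78 samples)", {
  cube <- makeTestCube(60, 60, 5, stage = "smoothed", seed = 4)
  cats <- rep(c("coral_white", "polychaete", "white_spot"), length.out = 78)
  rois <- lapply(1:78, function(i) {
    l0 <- ((i - 1) %% 13) * 4 + 1
    s0 <- ((i - 1) %/% 13) * 9 + 1
    rectROI(sprintf("ooi_%02d", i), cats[i], l0:(l0 + 2), s0:(s0 + 2))
  })
  expect_warning(ts <- assembleTraining(cube, rois, mode = "avg_spectra"),
                 "background")
  expect_identical(nrow(ts@samples), 78L)
  expect_identical(ts@mode, "avg_spectra")
  expect_false(ts@backgroundPresent)
})

test_that("roi_pixels mode yields one sample per pixel, capped per ROI", {
  cube <- makeTestCube(30, 30, 4, stage = "smoothed", seed = 5)
  rois <- list(rectROI("a", "crustacean", 1:5, 1:10),   # 50 px
               rectROI("bg", "sediment", 20:29, 20:29)) # 100 px
  ts <- assembleTraining(cube, rois, mode = "roi_pixels")
  expect_identical(sum(ts@ooiIDs == "a"), 50L)
  expect_true(ts@backgroundPresent)

  capped <- assembleTraining(cube, rois, mode = "roi_pixels",
                             maxPixelsPerROI = 20L)
  expect_lte(sum(capped@ooiIDs == "a"), 20L)

  expect_error(assembleTraining(cube, list(rois[[1]]), mode = "roi_pixels"),
               "2 distinct categories")
})

test_that("well-separated classes are fit to 100% training accuracy", {
  set.seed(31)
  wl <- seq(400, 700, length.out = 10)
  n <- 40
  a <- matrix(rep(c(rep(1, 5), rep(0.2, 5)), n), n, byrow = TRUE) +
    matrix(rnorm(10 * n, sd = 0.02), n)
  b <- matrix(rep(c(rep(0.2, 5), rep(1, 5)), n), n, byrow = TRUE) +
    matrix(rnorm(10 * n, sd = 0.02), n)
  ts <- new("TrainingSet", samples = rbind(a, b),
            labels = factor(rep(c("x", "y"), each = n)),
            ooiIDs = rep(c("ax", "by"), each = n),
            wavelengths = wl, mode = "roi_pixels",
            backgroundPresent = FALSE)
  model <- trainClassifier(ts)
  expect_identical(as.character(predict(model, rbind(a, b))),
                   rep(c("x", "y"), each = n))
})

test_that("a single sample per class classifies itself", {
  wl <- c(400, 500, 600)
  ts <- new("TrainingSet",
            samples = rbind(c(1, 0.2, 0.2), c(0.2, 0.2, 1)),
            labels = factor(c("p", "q")), ooiIDs = c("p1", "q1"),
            wavelengths = wl, mode = "avg_spectra",
            backgroundPresent = FALSE)
  model <- trainClassifier(ts)
  expect_identical(as.character(predict(model, rbind(c(1, 0.2, 0.2)))), "p")
  expect_identical(as.character(predict(model, rbind(c(0.2, 0.2, 1)))), "q")
})

test_that("identical spectra with conflicting labels are rejected with the colliding OOIs", {
  wl <- c(400, 500)
  ts <- new("TrainingSet",
            samples = rbind(c(1, 2), c(1, 2), c(3, 1)),
            labels = factor(c("x", "y", "y")),
            ooiIDs = c("first", "second", "third"),
            wavelengths = wl, mode = "roi_pixels",
            backgroundPresent = FALSE)
  expect_error(trainClassifier(ts), "first/second")
})

test_that("training on the simulator fixture covers every planted class", {
  cfg <- smallSceneConfig(seed = 41)
  sc <- generateScene(cfg)
  pre <- preprocessCube(sc$cube, preprocessConfig())
  rois <- c(suppressWarnings(truthROIs(sc$truth)), backgroundROIs(sc$truth))
  ts <- suppressWarnings(assembleTraining(pre, rois))
  model <- trainClassifier(ts)
  expect_setequal(model$levels,
                  c(cfg$categoriesNames, "sediment", "nodule"))
})

test_that("predictions are invariant to training-sample order", {
  cube <- makeTestCube(20, 20, 5, stage = "smoothed", seed = 6)
  rois <- list(rectROI("a", "coral_white", 1:6, 1:6),
               rectROI("b", "ophiuroid_red", 10:15, 10:15),
               rectROI("bg", "sediment", 1:6, 12:17))
  ts <- assembleTraining(cube, rois)
  perm <- sample(nrow(ts@samples))
  tsPerm <- new("TrainingSet", samples = ts@samples[perm, ],
                labels = ts@labels[perm], ooiIDs = ts@ooiIDs[perm],
                wavelengths = ts@wavelengths, mode = ts@mode,
                backgroundPresent = ts@backgroundPresent)
  m1 <- trainClassifier(ts)
  m2 <- trainClassifier(tsPerm)
  query <- matrix(runif(50 * 5), 50, 5)
  expect_identical(as.character(predict(m1, query)),
                   as.character(predict(m2, query)))
})

test_that("classifying copies of training spectra returns their labels", {
  wl <- seq(400, 600, length.out = 6)
  protos <- rbind(sediment = rep(1, 6),
                  coral_white = c(2, 2, 2, 1.5, 1.5, 1.5),
                  green_spot = c(1, 1, 1, 0.4, 1, 1))
  ts <- new("TrainingSet", samples = protos,
            labels = factor(rownames(protos)),
            ooiIDs = rownames(protos), wavelengths = wl,
            mode = "avg_spectra", backgroundPresent = TRUE)
  model <- trainClassifier(ts)
  # a cube tiled from the training spectra is labelled exactly like them
  pick <- c(1, 2, 3, 2, 1, 3, 1, 1, 2, 3, 3, 1)
  vals <- array(0, c(3, 4, 6))
  for (i in seq_along(pick))
    vals[((i - 1) %% 3) + 1, ((i - 1) %/% 3) + 1, ] <- protos[pick[i], ]
  cube <- HyperCube(vals, wl, stage = "smoothed")
  cmap <- suppressMessages(classifyCube(cube, model))
  got <- cmap@legend[as.character(cmap@labels)]
  expect_identical(unname(got), rownames(protos)[pick])

  # a constant background cube is uniformly background
  flat <- HyperCube(array(1, c(4, 4, 6)), wl, stage = "smoothed")
  cflat <- suppressMessages(classifyCube(flat, model))
  expect_true(all(cflat@legend[as.character(cflat@labels)] == "sediment"))

  # band-count mismatch is an error
  expect_error(classifyCube(makeTestCube(2, 2, 4), model), "bands")
})

test_that("library expansion increases detected OOI pixels on the standard fixture", {
  cfg <- smallSceneConfig(seed = 43)
  sc <- generateScene(cfg)
  pre <- preprocessCube(sc$cube, preprocessConfig())
  truth <- sc$truth
  objs <- truth@objects[!truth@objects$background, ]
  # "video-identified": fauna only; the spot anomalies are discovered later
  videoIDs <- objs$id[!objs$category %in% c("green_spot", "white_spot")]
  bg <- backgroundROIs(truth)
  roisVideo <- c(suppressWarnings(truthROIs(truth, ids = videoIDs)), bg)
  roisAll <- c(suppressWarnings(truthROIs(truth)), bg)
  onPlanted <- truth@objectIDs > 0 &
    !(truth@labels %in% which(truth@legend %in% c("sediment", "nodule")))
  countDetected <- function(rois) {
    model <- trainClassifier(suppressWarnings(assembleTraining(pre, rois)))
    cmap <- suppressMessages(classifyCube(pre, model))
    fg <- !(cmap@legend[as.character(cmap@labels)] %in%
              c("sediment", "nodule"))
    sum(fg & as.vector(onPlanted))
  }
  nVideo <- countDetected(roisVideo)
  nExpanded <- countDetected(roisAll)
  expect_lt(nVideo, nExpanded)
})
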