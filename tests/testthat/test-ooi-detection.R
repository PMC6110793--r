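# connected components, majority voting, size filtering, densities

test_that("an isolated block becomes one pure OOI with the right geometry", {
  cats <- matrix("sediment", 30, 30)
  cats[5:14, 8:17] <- "coral_white"           # 10 x 10 block
  oois <- detectOOIs(mapFromCategories(cats))
  expect_identical(nrow(oois), 1L)
  expect_identical(oois$category, "coral_white")
  expect_identical(oois$pixel_area, 100L)
  expect_equal(oois$purity, 1)
  expect_equal(oois$area_cm2, 1)               # 100 px at 1 mm = 1 cm2
  expect_equal(oois$centroid_line, 9.5)
  expect_equal(oois$centroid_sample, 12.5)
})

test_that("majority vote labels a 70/30 mixed object by its dominant class", {
  cats <- matrix("sediment", 30, 30)
  cats[5:16, 5:16] <- "coral_white"            # 12 x 12 = 144 px
  rim <- which(row(cats) %in% 5:16 & col(cats) %in% 5:16)
  rimIdx <- rim[1:43]                          # ~30% of the block
  cats[rimIdx] <- "sponge_round"
  oois <- detectOOIs(mapFromCategories(cats))
  expect_identical(nrow(oois), 1L)
  expect_identical(oois$category, "coral_white")
  expect_equal(oois$purity, 101 / 144)
})

test_that("components below the minimum size are discarded but conserved", {
  cats <- matrix("sediment", 20, 20)
  cats[2:3, 2:3] <- "polychaete"               # 4 px, below min 20
  cats[10:16, 10:16] <- "crinoid"              # 49 px
  oois <- detectOOIs(mapFromCategories(cats), minSizePx = 20)
  expect_identical(nrow(oois), 1L)
  expect_identical(oois$category, "crinoid")
  expect_identical(attr(oois, "n_filtered_px"), 4L)
  # pixel conservation: OOIs + background + filtered = all pixels
  expect_identical(sum(oois$pixel_area) + attr(oois, "n_background_px") +
                     attr(oois, "n_filtered_px"), 400L)
})

test_that("diagonal adjacency merges under 8- but not 4-connectivity", {
  cats <- matrix("sediment", 20, 20)
  cats[2:6, 2:6] <- "isopod"
  cats[7:11, 7:11] <- "isopod"                 # touches only at the corner
  oois8 <- detectOOIs(mapFromCategories(cats), connectivity = 8,
                      minSizePx = 1)
  oois4 <- detectOOIs(mapFromCategories(cats), connectivity = 4,
                      minSizePx = 1)
  expect_identical(nrow(oois8), 1L)
  expect_identical(nrow(oois4), 2L)
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(55)
  for (rep in 1:8) {
    mask <- matrix(runif(30 * 25) < 0.35, 30, 25)
    for (conn in c(4L, 8L)) {
      mine <- benthospec:::.labelComponents(mask, conn)
      oracle <- floodFillOracle(mask, conn)
      # same partition: component ids must be a relabelling of each other
      expect_identical(mine > 0, oracle > 0)
      key <- paste(mine[mask], oracle[mask])
      expect_identical(length(unique(key)), length(unique(mine[mask])))
      expect_identical(max(mine), max(oracle))
    }
  }
})

test_that("detection is invariant under translation and rotation", {
  cats <- matrix("sediment", 40, 40)
  cats[3:9, 4:12] <- "crustacean"
  cats[20:27, 15:22] <- "white_spot"
  cats[30:35, 30:36] <- "salp_dead"
  base <- detectOOIs(mapFromCategories(cats))
  fingerprint <- function(o)
    o[order(o$category), c("category", "pixel_area", "purity")]

  shifted <- rbind(matrix("sediment", 3, 40), cats[1:37, ])
  expect_equal(fingerprint(detectOOIs(mapFromCategories(shifted))),
               fingerprint(base), ignore_attr = TRUE)

  rotated <- t(cats)[ncol(cats):1, ]           # 90 degree rotation
  expect_equal(fingerprint(detectOOIs(mapFromCategories(rotated))),
               fingerprint(base), ignore_attr = TRUE)
})

test_that("the equivalent diameter of a planted disc matches its configured size", {
  cfg <- sceneConfig(lines = 120, samples = 120,
                     categoriesNames = "coral_white", nPerCategory = 1,
                     nNodules = 0, faunaDiamCM = c(4, 4), noiseFrac = 0,
                     seed = 9)
  truth <- generateScene(cfg)$truth
  cats <- matrix(truth@legend[as.character(truth@labels)],
                 nrow(truth@labels))
  oois <- detectOOIs(mapFromCategories(cats))
  expect_identical(nrow(oois), 1L)
  expect_lt(abs(oois$equiv_diam_cm - 4), 0.1)  # within one 1 mm pixel
})

test_that("legends without background need the explicit override", {
  cats <- matrix("coral_white", 10, 10)
  cats[1:5, ] <- "sponge_round"
  cmap <- mapFromCategories(cats)
  expect_error(detectOOIs(cmap), "background")
  # the two equal halves tie for the majority label, with a warning
  expect_warning(oois <- detectOOIs(cmap, noBackground = TRUE), "tie")
  expect_identical(nrow(oois), 1L)             # all foreground, 8-connected
  expect_identical(attr(oois, "n_background_px"), 0L)
})

test_that("alphabetical tie-breaking warns", {
  cats <- matrix("sediment", 12, 12)
  cats[2:5, 2:5] <- "white_spot"
  cats[6:9, 2:5] <- "green_spot"               # two equal 16-px halves
  expect_warning(oois <- detectOOIs(mapFromCategories(cats), minSizePx = 10),
                 "tie")
  expect_identical(oois$category, "green_spot")
})

test_that("densities reproduce the printed survey arithmetic", {
  expect_equal(round(computeDensity(39, 72.3), 2), 0.54)
  expect_equal(computeDensity(0, 72.3), 0)
  expect_error(computeDensity(5, 0), "positive")
  expect_error(computeDensity(5, -1), "positive")
})

test_that("survey summaries count, total and round only at report time", {
  oois <- data.frame(
    category = c(rep("coral_white", 3), rep("polychaete", 2), "white_spot"),
    pixel_area = rep(30L, 6), stringsAsFactors = FALSE)
  s <- summarizeSurvey(oois, areaM2 = 2.5)
  expect_identical(s@total, 6L)
  expect_identical(unname(s@counts["coral_white"]), 3L)
  expect_equal(unname(s@densities["polychaete"]), 0.8)
  df <- summaryToDataFrame(s)
  expect_identical(names(df), c("category", "count", "density_per_m2"))

  empty <- summarizeSurvey(data.frame(category = character(0)), areaM2 = 1)
  expect_identical(empty@total, 0L)

  # list-of-transects input is row-bound
  s2 <- summarizeSurvey(list(oois, oois), areaM2 = 5)
  expect_identical(s2@total, 12L)
})
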