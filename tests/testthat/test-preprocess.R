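# spectral subsetting, reference division, smoothing

test_that("default grid subsets to the 83 bands between 400 and 710 nm", {
  wl <- makeBandGrid()
  cube <- HyperCube(array(1, c(2, 2, length(wl))), wl)
  sub <- spectralSubset(cube, 400, 710)
  expect_identical(nBands(sub), 83L)
  expect_true(all(wavelengths(sub) >= 400 & wavelengths(sub) <= 710))
  # order preserved, bounds inclusive
  expect_identical(wavelengths(sub),
                   wl[wl >= 400 & wl <= 710])

  # a window covering everything is the identity
  all <- spectralSubset(cube, 0, 1000)
  expect_identical(cubeValues(all), cubeValues(cube))

  expect_error(spectralSubset(cube, 10, 20), "no band")
})

test_that("subsetting bounds are inclusive on both ends", {
  cube <- HyperCube(array(1, c(1, 1, 5)),
                    c(390, 400, 500, 710, 720))
  sub <- spectralSubset(cube, 400, 710)
  expect_identical(wavelengths(sub), c(400, 500, 710))
})

test_that("reference spectra match elementwise-mean oracles", {
  # all pixels equal to spectrum s: reference equals s in every column
  s <- c(2, 5, 9)
  cube <- HyperCube(array(rep(s, each = 12), c(3, 4, 3)),
                    c(400, 500, 600))
  ref <- computeReference(cube, "column_mean")
  expect_equal(dim(ref@spectra), c(4L, 3L))
  for (col in 1:4) expect_equal(unname(ref@spectra[col, ]), s)

  # two-line cube: column 0 spectra (1,1) and (3,3) average to (2,2)
  vals <- array(0, c(2, 1, 2))
  vals[1, 1, ] <- c(1, 1)
  vals[2, 1, ] <- c(3, 3)
  ref2 <- computeReference(HyperCube(vals, c(400, 500)), "column_mean")
  expect_equal(unname(ref2@spectra[1, ]), c(2, 2))

  # global mean of a constant cube is that constant spectrum
  ref3 <- computeReference(cube, "global_mean")
  expect_equal(unname(ref3@spectra[1, ]), s)
})

test_that("reference construction rejects wrong stages and dead bands", {
  cube <- makeTestCube(3, 3, 4, stage = "pseudo_reflectance")
  expect_error(computeReference(cube, "column_mean"), "raw or radiance")

  vals <- array(1, c(2, 2, 3))
  vals[, , 2] <- 0                      # band 2 dead everywhere
  dead <- HyperCube(vals, c(400, 500, 600))
  expect_error(computeReference(dead, "column_mean"), "band\\(s\\) 2")
})

test_that("pseudo-reflectance divides each pixel by its reference", {
  cube <- makeTestCube(4, 4, 5, seed = 7)
  ref <- computeReference(cube, "column_mean")
  pr <- pseudoReflectance(cube, ref)
  expect_identical(stage(pr), "pseudo_reflectance")

  # brute-force division oracle on spot-checked pixels
  for (pick in list(c(1, 1), c(3, 2), c(4, 4))) {
    expect_equal(cubeValues(pr)[pick[1], pick[2], ],
                 cubeValues(cube)[pick[1], pick[2], ] /
                   ref@spectra[pick[2], ])
  }

  # a cube equal to its reference is identically 1; doubling gives 2
  flat <- HyperCube(array(rep(c(2, 4), each = 6), c(2, 3, 2)), c(400, 500))
  reff <- computeReference(flat, "column_mean")
  expect_equal(unname(cubeValues(pseudoReflectance(flat, reff))),
               array(1, c(2, 3, 2)))
  double <- initialize(flat, values = flat@values * 2)
  expect_equal(unname(cubeValues(pseudoReflectance(double, reff))),
               array(2, c(2, 3, 2)))
})

test_that("an invalid reference entry is an error, not a silent NaN", {
  vals <- array(1, c(2, 2, 2))
  vals[, 1, 1] <- 0                      # band 1 dead in column 1 only
  cube <- HyperCube(vals, c(400, 500))
  ref <- computeReference(cube, "column_mean")
  expect_false(all(ref@validMask))
  expect_error(pseudoReflectance(cube, ref), "invalid")
})

test_that("global-mean pseudo-reflectance has unit mean per band", {
  cube <- makeTestCube(6, 7, 5, seed = 9)
  pr <- pseudoReflectance(cube, computeReference(cube, "global_mean"))
  m <- colMeans(matrix(cubeValues(pr), 42, 5))
  expect_equal(m, rep(1, 5), tolerance = 1e-6)
})

test_that("column-mean reference removes a multiplicative cross-track field", {
  # uniform material under a pure cross-track illumination profile
  s <- c(3, 6, 9)
  cross <- seq(0.6, 1, length.out = 8)
  vals <- array(0, c(10, 8, 3))
  for (col in 1:8) vals[, col, ] <- rep(cross[col] * s, each = 10)
  cube <- HyperCube(vals, c(400, 500, 600))
  pr <- pseudoReflectance(cube, computeReference(cube, "column_mean"))
  # constant across samples (and equal to 1 for a noiseless uniform scene)
  expect_equal(unname(cubeValues(pr)), array(1, c(10, 8, 3)))
})

test_that("moving-average smoothing matches analytic cases", {
  # constant spectrum unchanged
  cube <- HyperCube(array(0.4, c(2, 2, 15)), seq(400, 540, by = 10))
  sm <- smoothSpectra(cube, 11)
  expect_equal(cubeValues(sm), cubeValues(cube))
  expect_identical(stage(sm), "smoothed")

  # interior unit impulse spreads to eleven values of 1/11
  vals <- array(0, c(1, 1, 25))
  vals[1, 1, 13] <- 1
  imp <- smoothSpectra(HyperCube(vals, seq(400, length.out = 25, by = 4)), 11)
  spec <- cubeValues(imp)[1, 1, ]
  expect_equal(spec[8:18], rep(1 / 11, 11), tolerance = 1e-12)
  expect_equal(sum(spec != 0), 11L)

  # symmetric window preserves a linear ramp away from the edges
  ramp <- array(seq(1, 25), c(1, 1, 25))
  smr <- smoothSpectra(HyperCube(ramp, seq(400, length.out = 25, by = 4)), 11)
  expect_equal(cubeValues(smr)[1, 1, 6:20], seq(6, 20), tolerance = 1e-9)

  expect_error(smoothSpectra(cube, 4), "odd")
  expect_error(smoothSpectra(cube, 17), "exceeds")
})

test_that("shrink edge mode averages only over available bands", {
  vals <- array(rep(c(1, 2, 3, 4, 5), each = 1), c(1, 1, 5))
  sm <- smoothSpectra(HyperCube(vals, seq(400, 440, 10)), 3,
                      edgeMode = "shrink")
  expect_equal(cubeValues(sm)[1, 1, ],
               c((1 + 2) / 2, 2, 3, 4, (4 + 5) / 2))
})

test_that("smoothing commutes with scalar multiplication", {
  cube <- makeTestCube(3, 3, 12, seed = 21)
  k <- 3.7
  scaled <- initialize(cube, values = cube@values * k)
  expect_equal(cubeValues(smoothSpectra(scaled, 5)),
               cubeValues(smoothSpectra(cube, 5)) * k)
})

test_that("the full preprocessing chain preserves nonnegativity and band count", {
  cfg <- smallSceneConfig(seed = 31)
  sc <- generateScene(cfg)
  pre <- preprocessCube(sc$cube, preprocessConfig())
  expect_identical(nBands(pre), 83L)
  expect_true(all(cubeValues(pre) >= 0))
  expect_identical(stage(pre), "smoothed")
})
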