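# fixtures and independent oracles shared across the suite

# small cube with reproducible values
makeTestCube <- function(lines = 4, samples = 5, bands = 6, seed = 42,
                         stage = "raw", wl = NULL) {
  set.seed(seed)
  if (is.null(wl)) wl <- seq(400, by = 10, length.out = bands)
  HyperCube(array(runif(lines * samples * bands, 0.1, 1),
                  c(lines, samples, bands)),
            wl, stage = stage)
}

# brute-force queue flood fill: the independent connected-component oracle
floodFillOracle <- function(mask, connectivity = 8) {
  L <- nrow(mask); S <- ncol(mask)
  lab <- matrix(0L, L, S)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  k <- 0L
  for (l0 in seq_len(L)) for (s0 in seq_len(S)) {
    if (!mask[l0, s0] || lab[l0, s0] > 0L) next
    k <- k + 1L
    queue <- list(c(l0, s0))
    lab[l0, s0] <- k
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (i in seq_len(nrow(nb))) {
        l <- p[1L] + nb[i, 1L]; s <- p[2L] + nb[i, 2L]
        if (l >= 1 && l <= L && s >= 1 && s <= S &&
            mask[l, s] && lab[l, s] == 0L) {
          lab[l, s] <- k
          queue[[length(queue) + 1L]] <- c(l, s)
        }
      }
    }
  }
  lab
}

# independent angle computation used to cross-check matching
angleOracle <- function(a, b) {
  acos(min(1, max(-1, crossprod(a, b) /
                    sqrt(crossprod(a) * crossprod(b))))) * 180 / pi
}

# a classification map built directly from a category raster
mapFromCategories <- function(catMatrix, background = c("sediment", "nodule")) {
  cats <- sort(unique(as.vector(catMatrix)))
  legend <- stats::setNames(cats, seq_along(cats))
  codes <- match(catMatrix, cats)
  new("ClassificationMap",
      labels = matrix(as.integer(codes), nrow(catMatrix), ncol(catMatrix)),
      legend = legend, background = intersect(background, cats))
}

# rectangular ROI helper
rectROI <- function(id, category, lines, samples, source = "video_identified") {
  ROI(id, category, as.matrix(expand.grid(line = lines, sample = samples)),
      source = source)
}

# a small scene every end-to-end test can share (fits in well under a second)
smallSceneConfig <- function(seed = 5, ...) {
  sceneConfig(lines = 120, samples = 150, nPerCategory = 2,
              categoriesNames = c("coral_white", "ophiuroid_red",
                                  "green_spot", "white_spot"),
              nNodules = 8, noduleDiamCM = c(0.8, 1.8),
              faunaDiamCM = c(1.5, 2.5), seed = seed, ...)
}
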