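# internal helpers shared across modules

# 4-connectivity check on an n x 2 (line, sample) coordinate set; used by the
# ROI validity method.  Breadth-first search over a coordinate hash.
.isConnected4 <- function(px) {
  n <- nrow(px)
  if (n <= 1L) return(TRUE)
  key <- paste(px[, 1L], px[, 2L])
  idx <- seq_len(n)
  names(idx) <- key
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    l <- px[cur, 1L]; s <- px[cur, 2L]
    nb <- c(paste(l - 1L, s), paste(l + 1L, s),
            paste(l, s - 1L), paste(l, s + 1L))
    hit <- idx[nb]
    hit <- hit[!is.na(hit)]
    new <- hit[!seen[hit]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# nearest band index to a target wavelength; ties resolved toward the lower
# wavelength (lower index)
.nearestBand <- function(wavelengths, target) {
  d <- abs(wavelengths - target)
  which(d == min(d))[1L]
}

# typical band spacing (median of successive differences)
.bandSpacing <- function(wavelengths) {
  if (length(wavelengths) < 2L) return(Inf)
  stats::median(diff(wavelengths))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# flatten cube values to a [pixels x bands] matrix; pixel index runs down
# lines first (column-major over the first two array dims)
.cubeMatrix <- function(cube) {
  d <- dim(cube@values)
  matrix(cube@values, d[1L] * d[2L], d[3L])
}

# inverse of .cubeMatrix
.matrixCube <- function(m, lines, samples) {
  array(m, c(lines, samples, ncol(m)))
}

# deterministic subsample of n indices down to k (no RNG): evenly spaced
.evenSubsample <- function(n, k) {
  if (n <= k) return(seq_len(n))
  unique(round(seq(1L, n, length.out = k)))
}
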