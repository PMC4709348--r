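# shared fixture builders

mkGrid <- function(m, cellSize = 30, origin = NULL, nodata = -9999) {
  m <- as.matrix(m)
  if (is.null(origin)) origin <- c(0, nrow(m) * cellSize)
  rasterGrid(m, cellSize = cellSize, origin = origin, nodata = nodata)
}

# reflectance stack from per-band matrices
mkStack <- function(..., date = "2014-100", season = NULL, period = "D",
                    valueKind = "surface_reflectance", cellSize = 30,
                    qa = NULL) {
  mats <- list(...)
  bands <- lapply(mats, mkGrid, cellSize = cellSize)
  bandStack(bands, date, season = season, period = period,
            valueKind = valueKind,
            qa = if (is.null(qa)) NULL else mkGrid(qa, cellSize = cellSize))
}

# single-band stack whose NDVI equals v (red/nir solved from NDVI)
ndviStack <- function(v, bright = 0.5, ...) {
  v <- as.matrix(v)
  mkStack(red = bright * (1 - v) / 2, nir = bright * (1 + v) / 2, ...)
}

# hand-built SegmentLayer with given attributes (one row per segment; the
# label grid gives each segment `n` cells in its own row)
mkSegmentLayer <- function(meanNdviDiff, meanSlope, masked = NULL, n = NULL) {
  k <- length(meanNdviDiff)
  if (is.null(masked)) masked <- rep(FALSE, k)
  if (is.null(n)) n <- rep(1L, k)
  lab <- matrix(rep(seq_len(k), times = n), nrow = 1)
  labGrid <- mkGrid(lab)
  cc <- cellCenters(labGrid)
  tab <- data.frame(id = seq_len(k), n = as.integer(n),
                    perimeter = NA_real_,
                    centroidX = vapply(seq_len(k), function(i)
                      mean(cc$x[lab == i]), numeric(1)),
                    centroidY = vapply(seq_len(k), function(i)
                      mean(cc$y[lab == i]), numeric(1)),
                    meanNdviDiff = meanNdviDiff, meanSlope = meanSlope,
                    masked = masked, class = NA_character_)
  new("SegmentLayer", labels = labGrid, table = tab,
      params = segmentationParams())
}

# one-cell-per-segment layer whose crop presence equals the logical matrix
mkSegmentLayerFromPresence <- function(pres, cellSize = 100) {
  k <- length(pres)
  lab <- matrix(seq_len(k), nrow(pres), ncol(pres))
  labGrid <- mkGrid(lab, cellSize = cellSize)
  cc <- cellCenters(labGrid)
  tab <- data.frame(id = seq_len(k), n = 1L, perimeter = 4 * cellSize,
                    centroidX = as.vector(cc$x), centroidY = as.vector(cc$y),
                    meanNdviDiff = ifelse(as.vector(pres), 0.6, 0),
                    meanSlope = 0, masked = FALSE, class = NA_character_)
  new("SegmentLayer", labels = labGrid, table = tab,
      params = segmentationParams())
}

mkPC <- function(pres, period, cellSize = 100) {
  classifyPeriod(mkSegmentLayerFromPresence(pres, cellSize),
                 defaultThresholds(), period = period)
}
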