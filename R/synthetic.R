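#' Create a synthetic-scene template
#'
#' Parameters of the synthetic multi-period scene generator. The generator
#' emulates the statistical structure the phenology-based crop mapping relies
#' on: winter-cereal fields that are green in spring and senesced after the
#' June harvest (spring-minus-summer NDVI difference drawn around the
#' reference training statistics, mean 0.5713, sd 0.113), grassland confusers
#' concentrated on mountain slopes, evergreen orchard/woodland, bright fallow
#' fields, bare soil, a built-up patch, a water body, haze/cloud patches in
#' spring scenes only, and a DEM with flat plains and a rugged mountain belt.
#'
#' @param nrow,ncol scene size in cells
#' @param cellSize cell size in meters (30 = Landsat-class imagery)
#' @param nSpring,nSummer scenes per period and season (spring needs more
#'   acquisitions in practice because of clouds; the reference catalog has
#'   roughly five spring and four summer scenes per period)
#' @param fieldSize field-block edge length in cells
#' @param coverFractions plains block-cover probabilities (must sum to 1)
#' @param cropDiffMean,cropDiffSd mean/sd of the active-crop spring-minus-summer
#'   NDVI difference
#' @param fallowRate probability that an active field lies fallow in a given
#'   spring year (fields rest or switch crop every second year or so; multi-year
#'   composites are what recovers them)
#' @param periodActiveRate probability a crop field is cultivated at all in a
#'   given period (period-level abandonment drives the overlay categories)
#' @param hazeProb probability that a spring scene carries haze/cloud patches
#' @param hazeNdviDrop NDVI depression inside a haze/cloud patch
#' @param sceneNoiseSd per-scene NDVI jitter of non-crop covers
#' @param seed default RNG seed for \code{\link{generateSceneCollection}}
#' @return a \linkS4class{SceneTemplate}
#' @export
sceneTemplate <- function(nrow = 120, ncol = 120, cellSize = 30,
                          nSpring = 5, nSummer = 4, fieldSize = 10,
                          coverFractions = c(cropland = 0.45, bare = 0.3,
                                             orchard = 0.1, shrub = 0.1,
                                             built_up = 0.05),
                          cropDiffMean = 0.5713, cropDiffSd = 0.113,
                          fallowRate = 0.2, periodActiveRate = 0.85,
                          hazeProb = 0.5, hazeNdviDrop = 0.4,
                          sceneNoiseSd = 0.02, seed = 1) {
  if (abs(sum(coverFractions) - 1) > 1e-8)
    stop("coverFractions must sum to 1", call. = FALSE)
  new("SceneTemplate", nrow = nrow, ncol = ncol, cellSize = cellSize,
      nSpring = nSpring, nSummer = nSummer, fieldSize = fieldSize,
      coverFractions = coverFractions, cropDiffMean = cropDiffMean,
      cropDiffSd = cropDiffSd, fallowRate = fallowRate,
      periodActiveRate = periodActiveRate, hazeProb = hazeProb,
      hazeNdviDrop = hazeNdviDrop, sceneNoiseSd = sceneNoiseSd, seed = seed)
}

#' @describeIn sceneTemplate cover levels used in truth grids
#' @export
coverLevels <- function()
  c("cropland", "grassland", "orchard", "shrub", "woodland", "bare",
    "built_up", "water")

# gaussian-smoothed white noise, unit sd, edge-clamped
smoothNoise <- function(nr, nc, kernelSd = 2.5) {
  half <- ceiling(3 * kernelSd)
  off <- -half:half
  k <- exp(-off^2 / (2 * kernelSd^2))
  raw <- matrix(rnorm(nr * nc), nr, nc)
  sm1 <- matrix(0, nr, nc)
  for (i in seq_along(off)) {
    rows <- pmin(pmax(seq_len(nr) + off[i], 1), nr)
    sm1 <- sm1 + k[i] * raw[rows, , drop = FALSE]
  }
  sm2 <- matrix(0, nr, nc)
  for (i in seq_along(off)) {
    cols <- pmin(pmax(seq_len(nc) + off[i], 1), nc)
    sm2 <- sm2 + k[i] * sm1[, cols, drop = FALSE]
  }
  (sm2 - mean(sm2)) / sd(as.vector(sm2))
}

# NDVI + brightness -> four reflectance bands (red/nir exact, blue/green tied
# to red), clipped to [0, 1]
ndviToBands <- function(v, bright) {
  red <- bright * (1 - v) / 2
  nir <- bright * (1 + v) / 2
  green <- 0.9 * red + 0.02
  blue <- 0.8 * red + 0.01
  lapply(list(blue = blue, green = green, red = red, nir = nir),
         function(b) pmin(pmax(b, 0), 1))
}

coverBright <- c(cropland = 0.50, grassland = 0.48, orchard = 0.50,
                 shrub = 0.50, woodland = 0.45, bare = 0.45,
                 built_up = 0.40, water = 0.08, fallow = 0.62,
                 abandoned = 0.45)

# persistent seasonal NDVI moments per cover (non-crop)
coverNdvi <- list(
  grassland = c(spring = 0.50, springSd = 0.06, summer = 0.27, summerSd = 0.04),
  orchard   = c(spring = 0.62, springSd = 0.05, summer = 0.58, summerSd = 0.05),
  shrub     = c(spring = 0.38, springSd = 0.05, summer = 0.24, summerSd = 0.04),
  woodland  = c(spring = 0.65, springSd = 0.05, summer = 0.60, summerSd = 0.05),
  bare      = c(spring = 0.15, springSd = 0.03, summer = 0.12, summerSd = 0.02),
  built_up  = c(spring = 0.12, springSd = 0.02, summer = 0.11, summerSd = 0.02),
  water     = c(spring = -0.30, springSd = 0.05, summer = -0.30, summerSd = 0.05))

#' Generate a synthetic multi-period scene collection
#'
#' Builds the DEM, cover map, field-activity schedule, per-scene band stacks
#' (with spring haze/cloud patches and QA masks), per-period truth cover maps
#' and true crop areas. Periods are labeled A-D. Fully deterministic given the
#' seed.
#'
#' @param template a \linkS4class{SceneTemplate}
#' @param seed RNG seed (defaults to the template's)
#' @param periods period ids to generate
#' @return a \linkS4class{TruthBundle}
#' @export
generateSceneCollection <- function(template = sceneTemplate(), seed = NULL,
                                    periods = c("A", "B", "C", "D")) {
  if (is.null(seed)) seed <- template@seed
  set.seed(seed)
  thr <- defaultThresholds()
  if (template@cropDiffMean < thr@ndviThreshold)
    warning("template crop NDVI-difference mean is below the classification threshold (degenerate scenario)",
            call. = FALSE)
  nr <- template@nrow; nc <- template@ncol; cs <- template@cellSize
  geom <- rasterGrid(matrix(0, nr, nc), cellSize = cs, origin = c(0, nr * cs))

  # --- terrain: flat tilted plains, rugged mountain belt along the north ---
  rowIdx <- matrix(seq_len(nr), nr, nc)
  taper <- pmax(0, 1 - (rowIdx - 1) / (0.35 * nr))^2
  dem <- 400 + 0.1 * (nr - rowIdx) * cs / 30 +
    taper * (350 + 220 * smoothNoise(nr, nc, 3)) +
    2 * smoothNoise(nr, nc, 6)
  demGrid <- withValues(geom, dem)
  slope <- slopeGrid(demGrid)@values

  # --- cover map -----------------------------------------------------------
  lev <- coverLevels()
  code <- function(x) match(x, lev)
  cover <- matrix(code("grassland"), nr, nc)
  rough <- smoothNoise(nr, nc, 4)
  cover[slope >= 5 & rough > 0.5] <- code("shrub")
  cover[slope >= 5 & rough < -0.7] <- code("woodland")

  plains <- slope < 5 & rowIdx > 0.42 * nr
  fieldRow <- (rowIdx - 1) %/% template@fieldSize
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fieldCol <- (colIdx - 1) %/% template@fieldSize
  blockId <- fieldRow * ceiling(nc / template@fieldSize) + fieldCol + 1
  plainBlocks <- sort(unique(blockId[plains]))
  # a block joins the plains allocation only if almost all its cells qualify
  frac <- tapply(as.vector(plains), as.vector(blockId), mean)
  plainBlocks <- as.integer(names(frac))[frac > 0.9]
  fr <- template@coverFractions
  blockCover <- sample(names(fr), length(plainBlocks), replace = TRUE, prob = fr)
  names(blockCover) <- plainBlocks
  for (b in plainBlocks)
    cover[blockId == b & plains] <- code(blockCover[as.character(b)])

  # lake in the plains (disc), with a matching vector polygon
  lakeR <- 6.5 * cs
  lakeCenter <- c((0.22 * nc) * cs, (nr - 0.80 * nr) * cs)
  cc <- cellCenters(geom)
  inLake <- (cc$x - lakeCenter[1])^2 + (cc$y - lakeCenter[2])^2 <= lakeR^2
  cover[inLake] <- code("water")
  ang <- seq(0, 2 * pi, length.out = 49)
  lakePoly <- cbind(lakeCenter[1] + lakeR * cos(ang),
                    lakeCenter[2] + lakeR * sin(ang))

  cropFields <- as.integer(names(blockCover))[blockCover == "cropland"]
  cropFields <- cropFields[vapply(cropFields, function(b)
    any(blockId == b & cover == code("cropland")), logical(1))]
  nF <- length(cropFields)
  nPer <- length(periods)

  # --- activity schedule ---------------------------------------------------
  activePeriod <- matrix(runif(nF * nPer) < template@periodActiveRate, nF, nPer,
                         dimnames = list(NULL, periods))
  fallow <- array(runif(nF * nPer * template@nSpring) < template@fallowRate,
                  c(nF, nPer, template@nSpring),
                  dimnames = list(NULL, periods, NULL))
  for (f in seq_len(nF)) for (p in seq_len(nPer))
    if (activePeriod[f, p] && all(fallow[f, p, ]))
      fallow[f, p, sample(template@nSpring, 1)] <- FALSE

  # --- persistent per-cell seasonal NDVI -----------------------------------
  covName <- matrix(lev[cover], nr, nc)
  springBase <- matrix(NA_real_, nr, nc)
  summerBase <- matrix(NA_real_, nr, nc)
  for (cvn in names(coverNdvi)) {
    sel <- covName == cvn
    if (!any(sel)) next
    p <- coverNdvi[[cvn]]
    springBase[sel] <- rnorm(sum(sel), p["spring"], p["springSd"])
    summerBase[sel] <- rnorm(sum(sel), p["summer"], p["summerSd"])
  }
  springBase[covName == "water"] <- pmin(springBase[covName == "water"], -0.05)
  summerBase[covName == "water"] <- pmin(summerBase[covName == "water"], -0.05)

  isCropCell <- covName == "cropland"
  # per period: summer base and spring = summer + difference draw
  cropSummer <- lapply(seq_len(nPer), function(p)
    rnorm(sum(isCropCell), 0.21, 0.03))
  cropDiff <- lapply(seq_len(nPer), function(p)
    rnorm(sum(isCropCell), template@cropDiffMean, template@cropDiffSd))

  # --- scenes --------------------------------------------------------------
  scenes <- list(); truth <- list(); trueArea <- numeric(0)
  fieldOfCell <- matrix(match(blockId, cropFields), nr, nc)
  fieldOfCell[!isCropCell] <- NA
  springYearDates <- function(p) sprintf("%d-1%02d", 1984 + (p - 1) * 9,
                                         10 + seq_len(template@nSpring) * 9)
  segScene <- integer(nPer)

  for (p in seq_len(nPer)) {
    per <- periods[p]
    actF <- activePeriod[, p]
    activeCell <- isCropCell & !is.na(fieldOfCell) & actF[fieldOfCell]
    sSummer <- matrix(NA_real_, nr, nc)
    sSummer[isCropCell] <- cropSummer[[p]]
    sSpring <- matrix(NA_real_, nr, nc)
    sSpring[isCropCell] <- cropSummer[[p]] + cropDiff[[p]]
    # truth map for the period
    tru <- cover
    tru[isCropCell & !activeCell] <- match("bare", lev)
    truth[[per]] <- withValues(geom, tru)
    trueArea[per] <- sum(activeCell) * cs^2 / 1e6

    perScenes <- list()
    activeCount <- integer(template@nSpring)
    for (y in seq_len(template@nSpring)) {
      v <- springBase
      grow <- activeCell & !fallow[, p, y][fieldOfCell]
      fal <- isCropCell & !grow
      v[grow] <- sSpring[grow]
      v[fal] <- rnorm(sum(fal), 0.18, 0.02)
      bright <- coverBright[covName]
      bright[fal] <- coverBright["fallow"]
      # non-crop per-scene jitter
      jit <- !isCropCell
      v[jit] <- v[jit] + rnorm(sum(jit), 0, template@sceneNoiseSd)
      qa <- matrix(0, nr, nc)
      if (runif(1) < template@hazeProb) {
        for (h in seq_len(sample(1:3, 1))) {
          hr <- sort(sample(nr, 2)); hc <- sort(sample(nc, 2))
          hr <- hr[1]:min(hr[1] + sample(10:30, 1), hr[2])
          hc <- hc[1]:min(hc[1] + sample(10:30, 1), hc[2])
          patch <- matrix(FALSE, nr, nc); patch[hr, hc] <- TRUE
          v[patch] <- pmax(v[patch] - template@hazeNdviDrop, -0.9)
          qa[patch] <- 1
        }
      }
      bands <- ndviToBands(v, matrix(bright, nr, nc))
      if (any(qa == 1)) {
        bands$blue <- pmin(bands$blue + 0.08 * (qa == 1), 1)
        bands$green <- pmin(bands$green + 0.04 * (qa == 1), 1)
      }
      activeCount[y] <- sum(grow)
      perScenes[[paste0("spring_", y)]] <- bandStack(
        lapply(bands, function(b) withValues(geom, b)),
        springYearDates(p)[y], season = "spring", period = per,
        valueKind = "surface_reflectance",
        qa = if (any(qa == 1)) withValues(geom, qa) else NULL,
        provenance = "synthetic")
    }
    segScene[p] <- which.max(activeCount)
    for (y in seq_len(template@nSummer)) {
      v <- summerBase
      v[isCropCell] <- sSummer[isCropCell]
      v <- v + rnorm(nr * nc, 0, template@sceneNoiseSd)
      bright <- coverBright[covName]
      bands <- ndviToBands(v, matrix(bright, nr, nc))
      perScenes[[paste0("summer_", y)]] <- bandStack(
        lapply(bands, function(b) withValues(geom, b)),
        sprintf("%d-2%02d", 1984 + (p - 1) * 9, 10 + y * 8),
        season = "summer", period = per, valueKind = "surface_reflectance",
        provenance = "synthetic")
    }
    scenes[[per]] <- perScenes
  }
  names(segScene) <- periods

  # --- validation road: zigzag across the southern plains ------------------
  y1 <- (nr - 0.55 * nr) * cs; y2 <- (nr - 0.70 * nr) * cs
  y3 <- (nr - 0.85 * nr) * cs
  road <- cbind(x = c(0.05, 0.95, 0.95, 0.05, 0.05, 0.95) * nc * cs,
                y = c(y1, y1, y2, y2, y3, y3))

  new("TruthBundle", template = template, scenes = scenes, truth = truth,
      coverLevels = lev, dem = demGrid, water = list(lakePoly), road = road,
      trueCropAreaKm2 = trueArea,
      fieldActivity = list(fields = cropFields, activePeriod = activePeriod,
                           fallow = fallow, segScene = segScene))
}

setMethod("show", "TruthBundle", function(object) {
  cat(sprintf("TruthBundle: %d periods, %d x %d cells\n",
              length(object@scenes), nrow(object@dem@values),
              ncol(object@dem@values)))
  cat("  true crop area (km2):",
      paste(sprintf("%s=%.2f", names(object@trueCropAreaKm2),
                    object@trueCropAreaKm2), collapse = ", "), "\n")
})

#' Points along a road transect
#'
#' Walks the polyline and places a point every \code{spacing} meters, offset
#' perpendicular to the direction of travel on the right-hand side.
#'
#' @param road two-column polyline coordinate matrix
#' @param spacing distance between points, meters
#' @param offset perpendicular offset to the right, meters
#' @param n maximum number of points
#' @return data.frame with x, y
#' @export
roadTransectPoints <- function(road, spacing, offset = 0, n = Inf) {
  seg <- diff(road)
  segLen <- sqrt(rowSums(seg^2))
  total <- sum(segLen)
  dAll <- seq(spacing, total, by = spacing)
  if (length(dAll) > n) dAll <- dAll[seq_len(n)]
  cum <- c(0, cumsum(segLen))
  out <- matrix(NA_real_, length(dAll), 2)
  for (i in seq_along(dAll)) {
    j <- findInterval(dAll[i], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(seg))
    t <- (dAll[i] - cum[j]) / segLen[j]
    dir <- seg[j, ] / segLen[j]
    right <- c(dir[2], -dir[1])      # right-hand side of travel direction
    out[i, ] <- road[j, ] + t * seg[j, ] * 1 + right * offset
  }
  data.frame(x = out[, 1], y = out[, 2])
}

#' Draw training and validation sample points for a synthetic bundle
#'
#' Training points are stratified over covers (a fixed cropland count, the
#' remainder allocated over the other covers by their abundance); validation
#' points are laid out along the road transect at fixed spacing, offset to the
#' right-hand side of the direction of travel, mirroring a windshield survey.
#' Reference labels come from the truth map of \code{period} and are the
#' fine cover names (collapse to cropland/other happens in the accuracy
#' stage).
#'
#' @param bundle a \linkS4class{TruthBundle}
#' @param nTrain total training points (default 333)
#' @param nTrainCrop cropland training points among them (default 51)
#' @param nValid validation points (default 240)
#' @param spacing road-point spacing in meters; by default the road length is
#'   divided evenly into nValid steps (the field protocol's fixed 1-km spacing
#'   presumes a full-size study area)
#' @param period period whose truth labels the points carry
#' @param seed RNG seed
#' @return data.frame with x, y, label, role
#' @export
samplePoints <- function(bundle, nTrain = 333, nTrainCrop = 51, nValid = 240,
                         spacing = NULL, period = "D", seed = 1) {
  set.seed(seed)
  tru <- bundle@truth[[period]]
  lev <- bundle@coverLevels
  cc <- cellCenters(tru)
  labs <- lev[tru@values]
  # training: stratified over covers
  cropIdx <- which(labs == "cropland")
  if (length(cropIdx) < nTrainCrop)
    stop("not enough cropland cells for the requested training stratum",
         call. = FALSE)
  others <- setdiff(unique(labs), "cropland")
  counts <- table(labs[labs %in% others])
  alloc <- round((nTrain - nTrainCrop) * counts / sum(counts))
  while (sum(alloc) != nTrain - nTrainCrop) {
    i <- which.max(counts)
    alloc[i] <- alloc[i] + sign(nTrain - nTrainCrop - sum(alloc))
  }
  pick <- c(sample(cropIdx, nTrainCrop),
            unlist(lapply(names(alloc), function(cv)
              sample(which(labs == cv), alloc[cv]))))
  train <- data.frame(x = as.vector(cc$x)[pick], y = as.vector(cc$y)[pick],
                      label = labs[pick], role = "training",
                      stringsAsFactors = FALSE)
  # validation: road transect
  seg <- diff(bundle@road); roadLen <- sum(sqrt(rowSums(seg^2)))
  if (is.null(spacing)) spacing <- roadLen / (nValid + 1)
  pts <- roadTransectPoints(bundle@road, spacing,
                            offset = bundle@template@cellSize, n = nValid)
  if (nrow(pts) < nValid)
    warning(sprintf("road supports only %d of %d requested validation points",
                    nrow(pts), nValid), call. = FALSE)
  vlab <- lev[extractAtXY(tru, pts$x, pts$y)]
  keep <- !is.na(vlab)
  valid <- data.frame(x = pts$x[keep], y = pts$y[keep], label = vlab[keep],
                      role = "validation", stringsAsFactors = FALSE)
  rbind(train, valid)
}
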