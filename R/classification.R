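#' Derive classification thresholds from training samples
#'
#' The lower NDVI-difference threshold is the cropland training mean minus
#' \code{kNdvi} standard deviations (with a normal population this keeps close
#' to 99 percent of cropland above the cut at k = 2.3); the upper slope
#' threshold is the cropland mean slope plus \code{kSlope} standard deviations.
#' A per-cover summary table (n, mean, sd, median of the NDVI difference) is
#' attached for inspection.
#'
#' @param points data.frame of training points with columns x, y, label
#' @param diff spring-minus-summer NDVI difference \linkS4class{RasterGrid}
#' @param slope slope \linkS4class{RasterGrid} (degrees)
#' @param kNdvi NDVI-difference multiplier (default 2.3)
#' @param kSlope slope multiplier (default 2)
#' @param cropLabel label identifying cropland points
#' @return a \linkS4class{TrainingStats}
#' @export
deriveThresholds <- function(points, diff, slope, kNdvi = 2.3, kSlope = 2,
                             cropLabel = "cropland") {
  d <- extractAtXY(diff, points$x, points$y)
  s <- extractAtXY(slope, points$x, points$y)
  crop <- points$label == cropLabel & !is.na(d)
  if (sum(crop) < 2)
    stop("need at least 2 cropland training points with valid data (sd undefined)",
         call. = FALSE)
  mu <- mean(d[crop]); sdd <- sd(d[crop])
  cropS <- points$label == cropLabel & !is.na(s)
  muS <- mean(s[cropS]); sdS <- sd(s[cropS])
  covers <- sort(unique(points$label))
  covTab <- do.call(rbind, lapply(covers, function(cv) {
    dv <- d[points$label == cv & !is.na(d)]
    data.frame(cover = cv, n = length(dv), mean = mean(dv), sd = sd(dv),
               median = median(dv), stringsAsFactors = FALSE)
  }))
  new("TrainingStats", ndviMean = mu, ndviSd = sdd, kNdvi = kNdvi,
      ndviThreshold = mu - kNdvi * sdd, slopeMean = muS, slopeSd = sdS,
      kSlope = kSlope, slopeThreshold = muS + kSlope * sdS,
      coverTable = covTab)
}

#' Published default thresholds
#'
#' The decision constants of the reference Duhok analysis: NDVI-difference
#' threshold 0.30291 (inclusive lower bound) from cropland training statistics
#' mean 0.5713, sd 0.113, k = 2.3, and slope threshold 7.625 degrees
#' (exclusive upper bound, mean + 2 sd). Note the published threshold constant
#' 0.30291 is the analysis' printed decision value and is used as-is.
#'
#' @return a \linkS4class{TrainingStats}
#' @export
defaultThresholds <- function() {
  new("TrainingStats", ndviMean = 0.5713, ndviSd = 0.113, kNdvi = 2.3,
      ndviThreshold = 0.30291, slopeMean = NA_real_, slopeSd = NA_real_,
      kSlope = 2, slopeThreshold = 7.625, coverTable = data.frame())
}

setMethod("show", "TrainingStats", function(object) {
  cat(sprintf("TrainingStats: NDVI-diff >= %.5f (mean %.4f, sd %.4f, k %.1f); slope < %.3f deg\n",
              object@ndviThreshold, object@ndviMean, object@ndviSd,
              object@kNdvi, object@slopeThreshold))
  if (nrow(object@coverTable)) print(object@coverTable, row.names = FALSE)
})

#' Slope grid from a DEM (Horn's method)
#'
#' Standard 3x3 finite-difference slope: per cell,
#' gx = ((zNE + 2 zE + zSE) - (zNW + 2 zW + zSW)) / (8 cellSize) and the
#' analogous gy; slope = atan(sqrt(gx^2 + gy^2)) in degrees. Edge cells use
#' clamped (edge-replicated) neighborhoods.
#'
#' @param dem elevation \linkS4class{RasterGrid} in meters
#' @return slope \linkS4class{RasterGrid} in degrees
#' @export
slopeGrid <- function(dem) {
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2)
    stop("DEM must have at least 2 rows and 2 columns", call. = FALSE)
  up <- c(1, seq_len(nr - 1)); dn <- c(seq_len(nr - 1) + 1, nr)
  lf <- c(1, seq_len(nc - 1)); rt <- c(seq_len(nc - 1) + 1, nc)
  cs <- dem@cellSize
  gx <- ((z[up, rt] + 2 * z[, rt] + z[dn, rt]) -
         (z[up, lf] + 2 * z[, lf] + z[dn, lf])) / (8 * cs)
  gy <- ((z[dn, lf] + 2 * z[dn, ] + z[dn, rt]) -
         (z[up, lf] + 2 * z[up, ] + z[up, rt])) / (8 * cs)
  withValues(dem, atan(sqrt(gx^2 + gy^2)) * 180 / pi)
}

#' Classify segments as active winter cropland
#'
#' A segment is active winter cropland iff its mean NDVI difference is greater
#' than or equal to the NDVI threshold (inclusive), its mean slope is strictly
#' below the slope threshold (segments at or above the slope cut are filtered
#' out), and it is not masked. Mapped area and class proportions W_i are
#' computed over the unmasked study area.
#'
#' @param layer a \linkS4class{SegmentLayer} carrying meanNdviDiff and
#'   meanSlope attributes (see \code{\link{zonalAttributes}}) with the water
#'   mask applied
#' @param stats a \linkS4class{TrainingStats}
#' @param period epoch id
#' @return a \linkS4class{PeriodClassification}
#' @export
classifyPeriod <- function(layer, stats, period = "A") {
  tab <- layer@table
  need <- c("meanNdviDiff", "meanSlope")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("segment attribute(s) missing: %s (run zonalAttributes first)",
                 paste(miss, collapse = ", ")), call. = FALSE)
  isCrop <- !tab$masked &
    !is.na(tab$meanNdviDiff) & tab$meanNdviDiff >= stats@ndviThreshold &
    !is.na(tab$meanSlope) & tab$meanSlope < stats@slopeThreshold
  tab$class <- ifelse(tab$masked, NA_character_,
                      ifelse(isCrop, "active_winter_cropland", "other"))
  layer@table <- tab
  cellArea <- layer@labels@cellSize^2
  unmasked <- !tab$masked
  cropCells <- sum(tab$n[isCrop])
  totCells <- sum(tab$n[unmasked])
  W <- c(cropland = cropCells / totCells, other = 1 - cropCells / totCells)
  new("PeriodClassification", period = period, layer = layer,
      cropAreaKm2 = cropCells * cellArea / 1e6, proportions = W)
}

setMethod("show", "PeriodClassification", function(object) {
  cat(sprintf("PeriodClassification %s: crop area %.1f km2 (W_crop %.4f) over %d segments\n",
              object@period, object@cropAreaKm2, object@proportions["cropland"],
              nrow(object@layer@table)))
})

#' Crop presence grid of a classification
#'
#' @param pc a \linkS4class{PeriodClassification}
#' @return RasterGrid of 0/1 crop presence (NA where masked/invalid)
#' @export
cropPresence <- function(pc) {
  tab <- pc@layer@table
  lab <- pc@layer@labels@values
  isCrop <- !is.na(tab$class) & tab$class == "active_winter_cropland"
  lut <- rep(NA_real_, max(tab$id))
  lut[tab$id] <- ifelse(tab$masked, NA_real_, as.numeric(isCrop))
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  ok <- !is.na(lab)
  out[ok] <- lut[lab[ok]]
  withValues(pc@layer@labels, out)
}

#' Multi-period overlay of crop classifications
#'
#' Rasterized overlay on the common imagery grid: per cell, a combination code
#' with bit i set iff period i mapped the cell as active winter cropland
#' (masked/invalid cells count as absent). Reports area per combination code,
#' the derived change categories (stable = cropped in all periods; reclaimed =
#' all but the first; all-but-second; new in the last period only), and the
#' union area. A minimum-area reporting filter for map products is available
#' via \code{\link{filterOverlayTable}} and never touches the totals.
#'
#' @param classifications list of \linkS4class{PeriodClassification} on one
#'   shared grid (typically the four epochs A-D)
#' @return an \linkS4class{OverlayResult}
#' @export
overlayPeriods <- function(classifications) {
  stopifnot(length(classifications) >= 2)
  pres <- lapply(classifications, cropPresence)
  ref <- pres[[1]]
  for (p in pres[-1]) stopIfGeometryMismatch(ref, p, "period classifications")
  periods <- vapply(classifications, function(x) x@period, character(1))
  nP <- length(pres)
  code <- matrix(0, nrow(ref@values), ncol(ref@values))
  for (i in seq_len(nP)) {
    v <- pres[[i]]@values
    v[is.na(v)] <- 0
    code <- code + v * 2^(i - 1)
  }
  cellArea <- ref@cellSize^2 / 1e6
  counts <- tabulate(as.vector(code) + 1, nbins = 2^nP)
  tab <- data.frame(code = 0:(2^nP - 1))
  for (i in seq_len(nP))
    tab[[periods[i]]] <- bitwAnd(tab$code, 2^(i - 1)) > 0
  tab$areaKm2 <- counts * cellArea
  all4 <- rowSums(as.matrix(tab[, periods])) == nP
  cats <- c(stable = sum(tab$areaKm2[all4]))
  if (nP == 4) {
    m <- as.matrix(tab[, periods])
    cats <- c(cats,
      reclaimed = sum(tab$areaKm2[!m[, 1] & m[, 2] & m[, 3] & m[, 4]]),
      all_but_second = sum(tab$areaKm2[m[, 1] & !m[, 2] & m[, 3] & m[, 4]]),
      new_in_last = sum(tab$areaKm2[!m[, 1] & !m[, 2] & !m[, 3] & m[, 4]]))
  }
  new("OverlayResult", codes = withValues(ref, code), periods = periods,
      areaTable = tab, categories = cats,
      unionAreaKm2 = sum(tab$areaKm2[tab$code != 0]))
}

#' Reporting filter for overlay map products
#'
#' Drops combination codes below a minimum area from the reported table (map
#' legend), leaving the overlay totals untouched.
#'
#' @param overlay an \linkS4class{OverlayResult}
#' @param minKm2 minimum combination area to keep (the reference analysis
#'   mapped only combinations above 100 km2)
#' @return the filtered combination table
#' @export
filterOverlayTable <- function(overlay, minKm2 = 100) {
  tab <- overlay@areaTable
  tab[tab$code != 0 & tab$areaKm2 > minKm2, , drop = FALSE]
}

setMethod("show", "OverlayResult", function(object) {
  cat(sprintf("OverlayResult over periods %s: union %.1f km2\n",
              paste(object@periods, collapse = ""), object@unionAreaKm2))
  print(round(object@categories, 1))
})
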