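#' @import methods
#' @importFrom stats median quantile rnorm runif sd setNames qnorm rbinom rmultinom
#' @importFrom utils read.csv write.csv head
#' @useDynLib wincrop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' RasterGrid: a single-band regular raster
#'
#' Minimal raster container used throughout the pipeline: a numeric matrix of
#' cell values on a square-cell grid in projected map coordinates. Missing
#' cells are held as \code{NA} in memory; the \code{nodata} slot records the
#' sentinel written to / read from disk. Rows run north to south (row 1 is the
#' northern edge), columns west to east; \code{origin} is the map coordinate of
#' the grid's upper-left corner and cell centers sit half a cell in from the
#' corner.
#'
#' @slot values numeric matrix of cell values (\code{NA} = missing)
#' @slot cellSize cell edge length in meters
#' @slot origin numeric length-2, map x/y of the upper-left grid corner
#' @slot crs free-form coordinate reference identifier
#' @slot nodata numeric sentinel used on disk for missing cells
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character", nodata = "numeric"),
  prototype(cellSize = 1, origin = c(0, 0), crs = "local", nodata = -9999))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0) msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite map coordinates")
  if (length(object@nodata) != 1) msg <- c(msg, "nodata must be a single value")
  if (length(msg)) msg else TRUE
})

#' BandStack: one acquisition's co-registered spectral bands
#'
#' @slot bands named list of \linkS4class{RasterGrid}, roles among
#'   \code{blue}, \code{green}, \code{red}, \code{nir}
#' @slot acquisitionDate \code{Date} of acquisition
#' @slot season \code{"spring"} (pre-harvest) or \code{"summer"} (post-harvest)
#' @slot period epoch id, one of \code{"A","B","C","D"}
#' @slot valueKind \code{"digital_number"}, \code{"toa_reflectance"} or
#'   \code{"surface_reflectance"}
#' @slot qa optional quality grid (same geometry; nonzero = cloud/snow/haze
#'   contaminated, treated as missing when compositing), or \code{NULL}
#' @slot provenance correction provenance tag (e.g. \code{"ledaps_input"},
#'   \code{"dos_corrected"})
#' @exportClass BandStack
setClass("BandStack",
  representation(bands = "list", acquisitionDate = "Date", season = "character",
                 period = "character", valueKind = "character", qa = "ANY",
                 provenance = "character"),
  prototype(qa = NULL, provenance = "unspecified"))

setValidity("BandStack", function(object) {
  msg <- character()
  if (length(object@bands) == 0) msg <- c(msg, "at least one band required")
  if (is.null(names(object@bands)) || any(!nzchar(names(object@bands))))
    msg <- c(msg, "bands must be named by role")
  ok <- vapply(object@bands, function(b) is(b, "RasterGrid"), logical(1))
  if (!all(ok)) msg <- c(msg, "all bands must be RasterGrid objects")
  if (all(ok) && length(object@bands) > 1) {
    ref <- object@bands[[1]]
    same <- vapply(object@bands[-1], function(b) sameGeometry(ref, b), logical(1))
    if (!all(same)) msg <- c(msg, "all bands must share grid geometry")
  }
  if (!object@season %in% c("spring", "summer"))
    msg <- c(msg, "season must be 'spring' or 'summer'")
  if (!object@valueKind %in% c("digital_number", "toa_reflectance",
                               "surface_reflectance"))
    msg <- c(msg, "unknown valueKind")
  if (!is.null(object@qa)) {
    if (!is(object@qa, "RasterGrid") ||
        !sameGeometry(object@bands[[1]], object@qa))
      msg <- c(msg, "qa must be a RasterGrid sharing the band geometry")
  }
  if (length(msg)) msg else TRUE
})

#' PeriodManifest: scene catalog grouped into analysis epochs
#'
#' @slot periods data.frame with columns id, label, yearFrom, yearTo
#' @slot scenes data.frame with one row per scene: period, date (Date),
#'   julian ("YYYY-DDD"), season, valueKind, segmentation (logical), and
#'   optional per-band file paths
#' @exportClass PeriodManifest
setClass("PeriodManifest",
  representation(periods = "data.frame", scenes = "data.frame"))

setValidity("PeriodManifest", function(object) {
  msg <- character()
  p <- object@periods
  if (!all(c("id", "label", "yearFrom", "yearTo") %in% names(p)))
    msg <- c(msg, "periods needs id/label/yearFrom/yearTo")
  if (anyDuplicated(p$id)) msg <- c(msg, "duplicate period ids")
  s <- object@scenes
  if (!all(c("period", "season") %in% names(s)))
    msg <- c(msg, "scenes needs period/season columns")
  for (id in p$id) {
    sub <- s[s$period == id, , drop = FALSE]
    if (!any(sub$season == "spring") || !any(sub$season == "summer"))
      msg <- c(msg, sprintf("period %s needs at least one spring and one summer scene", id))
  }
  if (length(msg)) msg else TRUE
})

#' CalibrationMeta: per-scene radiometric calibration constants
#'
#' Gains and biases convert digital numbers to at-sensor spectral radiance;
#' solar geometry, earth-sun distance and exo-atmospheric irradiance convert
#' radiance to reflectance.
#'
#' @slot gain named numeric, radiance per DN, per band
#' @slot bias named numeric, radiance offset, per band
#' @slot esun named numeric, exo-atmospheric solar irradiance per band
#' @slot wavelength named numeric, band effective wavelength in micrometers
#' @slot solarZenith solar zenith angle, degrees (0 <= theta < 90)
#' @slot viewZenith sensor view zenith angle, degrees (0 = nadir)
#' @slot earthSunDistance earth-sun distance in astronomical units
#' @exportClass CalibrationMeta
setClass("CalibrationMeta",
  representation(gain = "numeric", bias = "numeric", esun = "numeric",
                 wavelength = "numeric", solarZenith = "numeric",
                 viewZenith = "numeric", earthSunDistance = "numeric"),
  prototype(viewZenith = 0, earthSunDistance = 1))

setValidity("CalibrationMeta", function(object) {
  msg <- character()
  if (object@solarZenith < 0 || object@solarZenith >= 90)
    msg <- c(msg, "solarZenith must be in [0, 90)")
  if (object@earthSunDistance <= 0) msg <- c(msg, "earthSunDistance must be > 0")
  if (any(object@gain <= 0)) msg <- c(msg, "gains must be positive")
  for (sl in c("bias", "esun", "wavelength"))
    if (is.null(names(slot(object, sl))) && length(slot(object, sl)) > 1)
      msg <- c(msg, sprintf("%s must be named by band role", sl))
  if (length(msg)) msg else TRUE
})

#' NDVIComposite: per-period seasonal NDVI composites and their difference
#'
#' @slot period epoch id
#' @slot springMVC per-cell maximum NDVI over the period's spring scenes
#' @slot summerMedian per-cell median NDVI over the period's summer scenes
#' @slot difference springMVC - summerMedian (the crop-phenology signal)
#' @slot springCount,summerCount per-cell counts of contributing scenes
#' @exportClass NDVIComposite
setClass("NDVIComposite",
  representation(period = "character", springMVC = "RasterGrid",
                 summerMedian = "RasterGrid", difference = "RasterGrid",
                 springCount = "RasterGrid", summerCount = "RasterGrid"))

#' SegmentLayer: image objects from region-merging segmentation
#'
#' Segments are raster-backed: \code{labels} assigns every valid cell a segment
#' id (1..k, \code{NA} outside the valid region); \code{table} carries one row
#' per segment with zonal attributes. Polygon geometry is derived on demand
#' (\code{\link{segmentPolygons}}).
#'
#' @slot labels integer-valued \linkS4class{RasterGrid} of segment ids
#' @slot table data.frame: id, n (cell count), perimeter (m), centroidX/Y (map
#'   coords of the region's area centroid), per-band mean/sd, and (after
#'   \code{\link{zonalAttributes}} / \code{\link{classifyPeriod}}) meanNdviDiff,
#'   meanSlope, masked, class
#' @slot params the \linkS4class{SegmentationParams} used
#' @exportClass SegmentLayer
setClass("SegmentLayer",
  representation(labels = "RasterGrid", table = "data.frame", params = "ANY"))

setValidity("SegmentLayer", function(object) {
  msg <- character()
  if (!all(c("id", "n") %in% names(object@table)))
    msg <- c(msg, "segment table needs id and n columns")
  lab <- object@labels@values
  nValid <- sum(!is.na(lab))
  if (nrow(object@table) && nValid != sum(object@table$n))
    msg <- c(msg, "segment cell counts must partition the valid region")
  if (length(msg)) msg else TRUE
})

#' SegmentationParams: multiresolution segmentation settings
#'
#' @slot scale scale parameter; a merge is admissible iff its fusion cost is
#'   below \code{scale^2}
#' @slot shapeWeight weight of shape vs spectral heterogeneity, in [0, 1)
#' @slot compactness weight of compactness vs smoothness within the shape term
#' @slot bandWeights named weights of the bands entering the spectral term
#' @slot valueScale multiplier applied to reflectance before merging (10000 =
#'   the conventional integer scaling of surface-reflectance products, which
#'   the published scale settings presume)
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(scale = "numeric", shapeWeight = "numeric",
                 compactness = "numeric", bandWeights = "numeric",
                 valueScale = "numeric"),
  prototype(scale = 100, shapeWeight = 0.1, compactness = 0.1,
            bandWeights = c(green = 1, red = 1, nir = 1), valueScale = 10000))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (object@shapeWeight < 0 || object@shapeWeight >= 1)
    msg <- c(msg, "shapeWeight must be in [0, 1)")
  if (object@compactness < 0 || object@compactness > 1)
    msg <- c(msg, "compactness must be in [0, 1]")
  if (any(object@bandWeights < 0) || !any(object@bandWeights > 0))
    msg <- c(msg, "band weights must be >= 0 with at least one > 0")
  if (object@valueScale <= 0) msg <- c(msg, "valueScale must be positive")
  if (length(msg)) msg else TRUE
})

#' TrainingStats: classification thresholds derived from training samples
#'
#' @slot ndviMean,ndviSd mean / sd of the spring-summer NDVI difference over
#'   cropland training points
#' @slot kNdvi multiplier: threshold = mean - kNdvi * sd
#' @slot ndviThreshold lower NDVI-difference threshold for active cropland
#' @slot slopeMean,slopeSd mean / sd of slope over cropland training points
#' @slot kSlope multiplier: threshold = mean + kSlope * sd
#' @slot slopeThreshold upper slope threshold (degrees); segments at or above
#'   it are filtered from the cropland layer
#' @slot coverTable per-cover summary (n, mean, sd, median of the difference)
#' @exportClass TrainingStats
setClass("TrainingStats",
  representation(ndviMean = "numeric", ndviSd = "numeric", kNdvi = "numeric",
                 ndviThreshold = "numeric", slopeMean = "numeric",
                 slopeSd = "numeric", kSlope = "numeric",
                 slopeThreshold = "numeric", coverTable = "data.frame"),
  prototype(coverTable = data.frame()))

#' PeriodClassification: one period's crop/other segment classification
#'
#' @slot period epoch id
#' @slot layer the classified \linkS4class{SegmentLayer} (class column set)
#' @slot cropAreaKm2 mapped active-winter-cropland area
#' @slot proportions mapped class proportions W_i over the unmasked study area
#' @exportClass PeriodClassification
setClass("PeriodClassification",
  representation(period = "character", layer = "SegmentLayer",
                 cropAreaKm2 = "numeric", proportions = "numeric"))

#' OverlayResult: multi-period presence/absence overlay accounting
#'
#' @slot codes integer \linkS4class{RasterGrid}; per cell, the bitwise
#'   combination of crop presence across periods (bit 1 = first period, ...)
#' @slot periods period ids in bit order
#' @slot areaTable data.frame: code, one logical column per period, areaKm2
#' @slot categories named areas (km2) of the derived change categories
#' @slot unionAreaKm2 area cropped in at least one period
#' @exportClass OverlayResult
setClass("OverlayResult",
  representation(codes = "RasterGrid", periods = "character",
                 areaTable = "data.frame", categories = "numeric",
                 unionAreaKm2 = "numeric"))

#' ErrorMatrix: mapped vs reference cross-tabulation
#'
#' Rows are mapped (classified) classes, columns reference classes.
#'
#' @slot counts integer matrix of sample counts n_ij
#' @slot classes ordered class names (shared by rows and columns)
#' @exportClass ErrorMatrix
setClass("ErrorMatrix",
  representation(counts = "matrix", classes = "character"))

setValidity("ErrorMatrix", function(object) {
  msg <- character()
  k <- length(object@classes)
  if (!all(dim(object@counts) == c(k, k)))
    msg <- c(msg, "counts must be a square matrix matching classes")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be whole numbers")
  if (length(msg)) msg else TRUE
})

#' AreaEstimate: stratified adjusted class areas with confidence intervals
#'
#' @slot classes class names
#' @slot totalAreaKm2 total study area A_tot
#' @slot W mapped proportions per class (the strata weights)
#' @slot proportions estimated true proportions p-hat_.j per class
#' @slot areaKm2 adjusted areas A_tot * p-hat_.j
#' @slot se standard errors S(p-hat_.j)
#' @slot z confidence multiplier (1.96 for the 95 percent level)
#' @slot halfWidthKm2 CI half-widths z * A_tot * S(p-hat_.j)
#' @exportClass AreaEstimate
setClass("AreaEstimate",
  representation(classes = "character", totalAreaKm2 = "numeric",
                 W = "numeric", proportions = "numeric", areaKm2 = "numeric",
                 se = "numeric", z = "numeric", halfWidthKm2 = "numeric"))

#' ChangeBound: interval arithmetic between two area estimates
#'
#' @slot from,to class-matched \linkS4class{AreaEstimate} summaries
#'   (area and half-width) for the compared class
#' @slot overlapKm2 overlap of the two confidence intervals
#' @slot maxIncreaseKm2 largest increase compatible with the intervals
#' @slot maxDecreaseKm2 largest decrease compatible with the intervals
#' @exportClass ChangeBound
setClass("ChangeBound",
  representation(from = "numeric", to = "numeric", overlapKm2 = "numeric",
                 maxIncreaseKm2 = "numeric", maxDecreaseKm2 = "numeric"))

#' SceneTemplate: parameters of the synthetic multi-period scene generator
#'
#' See \code{\link{sceneTemplate}} for the field-by-field description and
#' defaults.
#'
#' @exportClass SceneTemplate
setClass("SceneTemplate",
  representation(nrow = "numeric", ncol = "numeric", cellSize = "numeric",
                 nSpring = "numeric", nSummer = "numeric",
                 fieldSize = "numeric", coverFractions = "numeric",
                 cropDiffMean = "numeric", cropDiffSd = "numeric",
                 fallowRate = "numeric", periodActiveRate = "numeric",
                 hazeProb = "numeric", hazeNdviDrop = "numeric",
                 sceneNoiseSd = "numeric", seed = "numeric"))

#' TruthBundle: synthetic scenes plus the truth needed to score them
#'
#' @slot template the generating \linkS4class{SceneTemplate}
#' @slot scenes named list (by period) of lists of \linkS4class{BandStack}
#' @slot truth named list (by period) of cover-label RasterGrids (integer
#'   codes; see \code{coverLevels})
#' @slot coverLevels character vector decoding truth codes
#' @slot dem elevation RasterGrid (m)
#' @slot water list of water-body polygons (two-column coordinate matrices)
#' @slot road two-column coordinate matrix: the validation road polyline
#' @slot trueCropAreaKm2 named per-period true active-cropland area
#' @slot fieldActivity per-field by per-period/year activity bookkeeping
#' @exportClass TruthBundle
setClass("TruthBundle",
  representation(template = "SceneTemplate", scenes = "list", truth = "list",
                 coverLevels = "character", dem = "RasterGrid", water = "list",
                 road = "matrix", trueCropAreaKm2 = "numeric",
                 fieldActivity = "list"))
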