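#' Default pipeline configuration
#'
#' A declarative list covering all stages. \code{source = "synthetic"} runs on
#' generated scenes; \code{source = "manifest"} reads band rasters from the
#' paths in a scene manifest (plus a DEM, water polygons and sample points).
#' Thresholds: \code{derive = FALSE} uses the published decision constants
#' (NDVI difference >= 0.30291, slope < 7.625 degrees); \code{derive = TRUE}
#' recomputes both rules from the training points.
#'
#' @param seed RNG seed recorded and used by every stochastic stage
#' @return nested configuration list
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = seed,
    source = "synthetic",
    template = list(),               # sceneTemplate() overrides
    manifest = NULL, dem = NULL, water = NULL, points = NULL,
    thresholds = list(derive = FALSE, kNdvi = 2.3, kSlope = 2),
    segmentation = list(scale = 100, shape = 0.1, compactness = 0.1),
    accuracy = list(z = 1.96),
    training = list(nTrain = 333, nTrainCrop = 51, nValid = 240))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration file
#'
#' YAML keys override \code{\link{defaultConfig}} entries.
#'
#' @param path YAML config file
#' @return configuration list
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config not found: %s", path), call. = FALSE)
  mergeConfig(defaultConfig(), yaml::read_yaml(path))
}

pipelineLogger <- function(path) {
  function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    cat(line, "\n", sep = "")
    if (!is.null(path)) cat(line, "\n", sep = "", file = path, append = TRUE)
  }
}

#' Run the full winter-crop mapping and change pipeline
#'
#' Chains every stage: scene generation (or loading), per-period NDVI
#' compositing, segmentation of one scene per period, zonal attributes
#' (NDVI difference and slope), water-centroid masking, threshold
#' classification, four-period overlay, and stratified accuracy assessment
#' with adjusted area estimates. All stage parameters and the seed are
#' logged; identical config and seed give identical outputs.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}) or path
#'   to a YAML file
#' @param outdir output directory (created); NULL computes without writing
#' @param seed overrides the config seed when given
#' @return (invisibly) list with bundle, composites, classifications, overlay,
#'   assessments, and the per-period report data.frame
#' @export
runPipeline <- function(config = defaultConfig(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- loadConfig(config)
  config <- mergeConfig(defaultConfig(), config)
  if (!is.null(seed)) config$seed <- seed
  logPath <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outdir, "pipeline.log")
    if (file.exists(logPath)) unlink(logPath)
  }
  log <- pipelineLogger(logPath)
  log("setup", "seed = %d, source = %s", config$seed, config$source)

  # ---- inputs -------------------------------------------------------------
  if (config$source == "synthetic") {
    tpl <- do.call(sceneTemplate, config$template)
    bundle <- generateSceneCollection(tpl, seed = config$seed)
    log("synth", "generated %d periods of %dx%d scenes",
        length(bundle@scenes), tpl@nrow, tpl@ncol)
    pts <- samplePoints(bundle, nTrain = config$training$nTrain,
                        nTrainCrop = config$training$nTrainCrop,
                        nValid = config$training$nValid,
                        seed = config$seed)
    dem <- bundle@dem
    water <- bundle@water
    periods <- names(bundle@scenes)
    segIdx <- bundle@fieldActivity$segScene
  } else if (config$source == "manifest") {
    if (is.null(config$manifest))
      stop("manifest source needs config$manifest", call. = FALSE)
    if (is.null(config$dem))
      stop("slope masking stage requires a DEM (config$dem missing)",
           call. = FALSE)
    bundle <- loadScenesFromManifest(config$manifest, log)
    dem <- readAsciiGrid(config$dem)
    water <- if (is.null(config$water)) list()
             else readPolygonsGeoJSON(config$water)
    pts <- if (is.null(config$points)) NULL else readPointsCSV(config$points)
    periods <- names(bundle@scenes)
    segIdx <- bundle@fieldActivity$segScene
  } else stop(sprintf("unknown source '%s'", config$source), call. = FALSE)

  refGrid <- getBand(bundle@scenes[[1]][[1]], "red")
  demOnGrid <- if (sameGeometry(dem, refGrid)) dem
               else resampleNearest(dem, refGrid)
  slope <- slopeGrid(demOnGrid)
  log("slope", "terrain slope computed (max %.1f deg)",
      max(slope@values, na.rm = TRUE))

  # ---- composites ---------------------------------------------------------
  composites <- lapply(periods, function(per) {
    sc <- bundle@scenes[[per]]
    isSpring <- vapply(sc, function(s) seasonOf(s) == "spring", logical(1))
    comp <- ndviComposite(sc[isSpring], sc[!isSpring], period = per)
    log("composite", "period %s: %d spring + %d summer scenes", per,
        sum(isSpring), sum(!isSpring))
    comp
  })
  names(composites) <- periods

  # ---- thresholds ---------------------------------------------------------
  if (isTRUE(config$thresholds$derive)) {
    if (is.null(pts)) stop("threshold derivation needs training points",
                           call. = FALSE)
    train <- pts[pts$role == "training", ]
    stats <- deriveThresholds(train, composites[[length(composites)]]@difference,
                              slope, kNdvi = config$thresholds$kNdvi,
                              kSlope = config$thresholds$kSlope)
    log("thresholds", "derived: ndvi >= %.5f, slope < %.3f",
        stats@ndviThreshold, stats@slopeThreshold)
  } else {
    stats <- defaultThresholds()
    log("thresholds", "defaults: ndvi >= %.5f, slope < %.3f",
        stats@ndviThreshold, stats@slopeThreshold)
  }

  # ---- segmentation + classification per period ---------------------------
  segPar <- segmentationParams(scale = config$segmentation$scale,
                               shapeWeight = config$segmentation$shape,
                               compactness = config$segmentation$compactness)
  classifications <- lapply(periods, function(per) {
    segStack <- bundle@scenes[[per]][[segIdx[[per]]]]
    layer <- multiresolutionSegment(segStack, segPar)
    log("segment", "period %s: %d segments from scene %s", per,
        nrow(layer@table), names(bundle@scenes[[per]])[segIdx[[per]]])
    layer <- zonalAttributes(layer, list(ndviDiff = composites[[per]]@difference,
                                         slope = slope))
    layer <- maskWater(layer, water)
    pc <- classifyPeriod(layer, stats, period = per)
    log("classify", "period %s: mapped crop area %.2f km2 (W_crop %.4f)",
        per, pc@cropAreaKm2, pc@proportions["cropland"])
    pc
  })
  names(classifications) <- periods

  # ---- overlay ------------------------------------------------------------
  overlay <- overlayPeriods(classifications)
  log("overlay", "union %.2f km2; stable %.2f km2", overlay@unionAreaKm2,
      overlay@categories["stable"])

  # ---- accuracy / adjusted areas ------------------------------------------
  cellArea <- refGrid@cellSize^2 / 1e6
  assessments <- NULL
  if (!is.null(pts)) {
    valid <- pts[pts$role == "validation", ]
    assessments <- lapply(periods, function(per) {
      vper <- valid
      if (config$source == "synthetic") {
        # reference labels re-read from the period's truth map
        lab <- bundle@coverLevels[extractAtXY(bundle@truth[[per]], valid$x,
                                              valid$y)]
        vper$label <- lab
      }
      m <- buildErrorMatrix(vper, classifications[[per]])
      st <- accuracyStats(m, W = classifications[[per]]@proportions)
      totArea <- sum(classifications[[per]]@layer@table$n[
        !classifications[[per]]@layer@table$masked]) * cellArea
      est <- adjustedArea(m, classifications[[per]]@proportions, totArea,
                          z = config$accuracy$z)
      log("assess", "period %s: OA %.1f%%, kappa %.3f, adjusted crop %.2f km2 (+-%.2f)",
          per, 100 * st$overallAccuracy, st$kappa, est@areaKm2["cropland"],
          est@halfWidthKm2["cropland"])
      list(matrix = m, stats = st, estimate = est)
    })
    names(assessments) <- periods
  }

  report <- data.frame(
    period = periods,
    mappedCropKm2 = vapply(classifications, function(x) x@cropAreaKm2,
                           numeric(1)),
    row.names = NULL)
  if (!is.null(assessments)) {
    report$adjustedCropKm2 <- vapply(assessments, function(a)
      unname(a$estimate@areaKm2["cropland"]), numeric(1))
    report$halfWidthKm2 <- vapply(assessments, function(a)
      unname(a$estimate@halfWidthKm2["cropland"]), numeric(1))
    report$overallAccuracy <- vapply(assessments, function(a)
      a$stats$overallAccuracy, numeric(1))
    report$kappa <- vapply(assessments, function(a) a$stats$kappa, numeric(1))
  }
  if (is(bundle, "TruthBundle") && length(bundle@trueCropAreaKm2))
    report$trueCropKm2 <- unname(bundle@trueCropAreaKm2[periods])

  if (!is.null(outdir)) writeRunOutputs(outdir, bundle, composites,
                                        classifications, overlay, assessments,
                                        report, pts, log)
  invisible(list(config = config, bundle = bundle, composites = composites,
                 classifications = classifications, overlay = overlay,
                 assessments = assessments, report = report))
}

writeRunOutputs <- function(outdir, bundle, composites, classifications,
                            overlay, assessments, report, pts, log) {
  fmtNum <- function(x) formatC(x, format = "g", digits = 12)
  for (per in names(composites)) {
    writeAsciiGrid(composites[[per]]@difference,
                   file.path(outdir, sprintf("difference_%s.asc", per)))
    writeAsciiGrid(classifications[[per]]@layer@labels,
                   file.path(outdir, sprintf("segments_%s.asc", per)))
    tab <- classifications[[per]]@layer@table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], fmtNum)
    write.csv(tab, file.path(outdir, sprintf("segments_%s.csv", per)),
              row.names = FALSE)
    writeSegmentsGeoJSON(classifications[[per]]@layer,
                         file.path(outdir, sprintf("segments_%s.geojson", per)))
  }
  if (is(bundle, "TruthBundle") && length(bundle@water))
    writePolygonsGeoJSON(bundle@water, file.path(outdir, "water.geojson"))
  writeAsciiGrid(overlay@codes, file.path(outdir, "overlay_codes.asc"))
  ot <- overlay@areaTable
  ot$areaKm2 <- fmtNum(ot$areaKm2)
  write.csv(ot, file.path(outdir, "overlay_areas.csv"), row.names = FALSE)
  rep2 <- report
  num <- vapply(rep2, is.numeric, logical(1))
  rep2[num] <- lapply(rep2[num], fmtNum)
  write.csv(rep2, file.path(outdir, "report.csv"), row.names = FALSE)
  if (!is.null(assessments)) {
    stats <- lapply(assessments, function(a) list(
      counts = a$matrix@counts,
      userAccuracy = a$stats$userAccuracy,
      producerAccuracy = a$stats$producerAccuracy,
      overallAccuracy = a$stats$overallAccuracy,
      kappa = a$stats$kappa,
      adjustedAreaKm2 = a$estimate@areaKm2,
      halfWidthKm2 = a$estimate@halfWidthKm2))
    writeLines(jsonlite::toJSON(stats, auto_unbox = TRUE, digits = NA),
               file.path(outdir, "accuracy.json"))
  }
  if (!is.null(pts)) writePointsCSV(pts, file.path(outdir, "points.csv"))
  log("write", "outputs written to %s", outdir)
  invisible(outdir)
}

# Load scenes listed in a manifest into a minimal bundle-like object.
loadScenesFromManifest <- function(path, log = function(...) invisible()) {
  man <- loadManifest(path)
  s <- man@scenes
  periods <- man@periods$id
  scenes <- list(); segScene <- integer(0)
  for (per in periods) {
    sub <- s[s$period == per, , drop = FALSE]
    perScenes <- list()
    for (i in seq_len(nrow(sub))) {
      paths <- unlist(sub[i, paste0("path_", c("blue", "green", "red", "nir"))])
      if (any(is.na(paths)))
        stop(sprintf("scene %s lacks band paths", sub$julian[i]), call. = FALSE)
      bands <- lapply(paths, readAsciiGrid)
      names(bands) <- c("blue", "green", "red", "nir")
      perScenes[[sub$julian[i]]] <- bandStack(bands, sub$date[i],
        season = sub$season[i], period = per, valueKind = sub$valueKind[i])
    }
    scenes[[per]] <- perScenes
    segScene[per] <- which(sub$segmentation)[1]
    if (is.na(segScene[per])) segScene[per] <- which(sub$season == "spring")[1]
  }
  log("load", "%d scenes read from manifest", nrow(s))
  new("TruthBundle", template = sceneTemplate(), scenes = scenes,
      truth = list(), coverLevels = coverLevels(),
      dem = rasterGrid(matrix(0, 2, 2)), water = list(),
      road = matrix(numeric(0), 0, 2), trueCropAreaKm2 = numeric(0),
      fieldActivity = list(segScene = segScene))
}
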