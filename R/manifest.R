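#' Load a period/scene manifest
#'
#' The manifest is a declarative YAML file listing the analysis epochs
#' (periods) and every scene with its "YYYY-DDD" date, season tag, value kind
#' and (optionally) per-band raster paths. Scene dates are validated against
#' their period's year range (error) and against the seasonal acquisition
#' windows, spring = March-June, summer = July-September (warning only:
#' operational catalogs occasionally include a usable late-winter scene in the
#' spring set).
#'
#' @param path YAML manifest file
#' @return a \linkS4class{PeriodManifest}
#' @export
loadManifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$periods)) stop("manifest has no 'periods' key", call. = FALSE)
  pl <- lapply(cfg$periods, function(p) {
    data.frame(id = p$id, label = if (is.null(p$label)) p$id else p$label,
               yearFrom = p$years[[1]], yearTo = p$years[[2]],
               stringsAsFactors = FALSE)
  })
  periods <- do.call(rbind, pl)
  sl <- list()
  for (p in cfg$periods) {
    for (s in p$scenes) {
      row <- data.frame(
        period = p$id, julian = s$date, date = parseSceneDate(s$date),
        season = s$season,
        valueKind = if (is.null(s$value_kind)) "surface_reflectance" else s$value_kind,
        segmentation = isTRUE(s$segmentation), stringsAsFactors = FALSE)
      for (b in c("blue", "green", "red", "nir"))
        row[[paste0("path_", b)]] <-
          if (!is.null(s$bands[[b]])) s$bands[[b]] else NA_character_
      sl[[length(sl) + 1]] <- row
    }
  }
  scenes <- do.call(rbind, sl)
  yr <- as.integer(format(scenes$date, "%Y"))
  rng <- periods[match(scenes$period, periods$id), ]
  bad <- yr < rng$yearFrom | yr > rng$yearTo
  if (any(bad))
    stop(sprintf("scene date(s) outside the declared period year range: %s",
                 paste(scenes$julian[bad], collapse = ", ")), call. = FALSE)
  derived <- seasonFromDate(scenes$date)
  off <- is.na(derived) | derived != scenes$season
  if (any(off))
    warning(sprintf("scene date(s) outside the declared season window: %s",
                    paste(scenes$julian[off], collapse = ", ")), call. = FALSE)
  new("PeriodManifest", periods = periods, scenes = scenes)
}

#' Scene counts per period and season
#'
#' @param manifest a \linkS4class{PeriodManifest}
#' @return data.frame with columns period, season, n
#' @export
sceneCounts <- function(manifest) {
  s <- manifest@scenes
  agg <- stats::aggregate(list(n = seq_len(nrow(s))), by = list(period = s$period,
                   season = s$season), FUN = length)
  agg[order(agg$period, agg$season), ]
}

#' @describeIn sceneCounts total number of scenes
#' @export
sceneTotal <- function(manifest) nrow(manifest@scenes)

#' Scene selected for segmentation in one period
#'
#' @param manifest a \linkS4class{PeriodManifest}
#' @param period period id
#' @return one-row data.frame describing the scene
#' @export
segmentationScene <- function(manifest, period) {
  s <- manifest@scenes
  sub <- s[s$period == period & s$segmentation, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no segmentation scene flagged for period %s", period),
         call. = FALSE)
  sub[1, , drop = FALSE]
}

setMethod("show", "PeriodManifest", function(object) {
  cat(sprintf("PeriodManifest: %d periods, %d scenes\n",
              nrow(object@periods), nrow(object@scenes)))
  print(sceneCounts(object), row.names = FALSE)
})

#' Path to the bundled reference scene catalog
#'
#' A scene catalog (no pixel data) for the Duhok governorate Landsat analysis:
#' 47 scenes over four epochs, pre-Anfal (A, 1984-1987), post-Anfal
#' (B, 1989-1991), reconstruction (C, 1998-2002) and present (D, 2011-2014).
#'
#' @return file path of the YAML manifest
#' @export
referenceManifestPath <- function() {
  system.file("extdata", "duhok_landsat_manifest.yaml", package = "wincrop",
              mustWork = TRUE)
}
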