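stackToArray <- function(grids, what = "composite inputs") {
  if (!length(grids)) stop("at least one grid required", call. = FALSE)
  ref <- grids[[1]]
  for (g in grids[-1]) stopIfGeometryMismatch(ref, g, what)
  arr <- vapply(grids, function(g) g@values,
                matrix(0, nrow(ref@values), ncol(ref@values)))
  dim(arr) <- c(dim(ref@values), length(grids))
  arr
}

#' Maximum-value composite
#'
#' Per cell, the maximum over all non-missing inputs; cells missing everywhere
#' stay missing. Taking the per-cell maximum of NDVI over a season's scenes
#' retains the greenest observation, suppressing clouds, haze and fallow years.
#'
#' @param grids list of \linkS4class{RasterGrid} on a shared geometry
#' @return a \linkS4class{RasterGrid}
#' @export
maxValueComposite <- function(grids) {
  arr <- stackToArray(grids)
  out <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  withValues(grids[[1]], out)
}

#' Median composite
#'
#' Per cell, the median over all non-missing inputs (even counts: midpoint of
#' the central pair). The post-harvest summer composite uses the median so
#' that single bright (fallow regrowth) or dark (cloud) observations do not
#' dominate.
#'
#' @inheritParams maxValueComposite
#' @return a \linkS4class{RasterGrid}
#' @export
medianComposite <- function(grids) {
  arr <- stackToArray(grids)
  out <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  withValues(grids[[1]], out)
}

#' Valid-observation counts per cell
#'
#' @inheritParams maxValueComposite
#' @return integer-valued \linkS4class{RasterGrid} of contributing-scene counts
#' @export
validCount <- function(grids) {
  arr <- stackToArray(grids)
  withValues(grids[[1]], apply(arr, c(1, 2), function(v) sum(!is.na(v))))
}

#' Spring-minus-summer difference layer
#'
#' The crop-phenology signal: winter cereals are green before the June harvest
#' and senesced after it, so active cropland has a large positive difference.
#' Missing cells in either input propagate.
#'
#' @param spring,summer \linkS4class{RasterGrid} composites on one geometry
#' @return a \linkS4class{RasterGrid}
#' @export
differenceLayer <- function(spring, summer) {
  stopIfGeometryMismatch(spring, summer, "spring and summer composites")
  withValues(spring, spring@values - summer@values)
}

#' NDVI of a scene with its quality mask applied
#'
#' Cells flagged in the scene's QA grid (nonzero) are set missing before
#' compositing.
#'
#' @param stack a \linkS4class{BandStack}
#' @return a \linkS4class{RasterGrid}
#' @export
maskedNdvi <- function(stack) {
  g <- ndvi(stack)
  if (!is.null(qaMask(stack))) {
    v <- g@values
    v[!is.na(qaMask(stack)@values) & qaMask(stack)@values != 0] <- NA_real_
    g <- withValues(g, v)
  }
  g
}

#' Build a period's NDVI composite set
#'
#' Computes per-scene (QA-masked) NDVI, the spring maximum-value composite,
#' the summer median composite, and their difference. The difference is valid
#' only where at least one valid spring and one valid summer observation
#' exist.
#'
#' @param springStacks,summerStacks lists of \linkS4class{BandStack}
#' @param period epoch id
#' @return an \linkS4class{NDVIComposite}
#' @export
ndviComposite <- function(springStacks, summerStacks, period = "A") {
  if (!length(springStacks) || !length(summerStacks))
    stop(sprintf("period %s needs at least one spring and one summer scene",
                 period), call. = FALSE)
  sN <- lapply(springStacks, maskedNdvi)
  uN <- lapply(summerStacks, maskedNdvi)
  mvc <- maxValueComposite(sN)
  med <- medianComposite(uN)
  diff <- differenceLayer(mvc, med)
  new("NDVIComposite", period = period, springMVC = mvc, summerMedian = med,
      difference = diff, springCount = validCount(sN), summerCount = validCount(uN))
}

setMethod("show", "NDVIComposite", function(object) {
  d <- object@difference@values
  cat(sprintf("NDVIComposite period %s: %d x %d, difference mean %.4f (%d missing)\n",
              object@period, nrow(d), ncol(d), mean(d, na.rm = TRUE),
              sum(is.na(d))))
})
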