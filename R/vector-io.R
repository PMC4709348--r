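# Polygonization of raster segments (cell-edge-following boundaries) and
# GeoJSON / CSV interchange.

# Trace the boundary rings of one raster region. Returns a list of closed
# two-column coordinate matrices; the first ring (largest |area|) is the
# outer ring (counterclockwise), the rest are holes.
traceRegion <- function(lab, id, cellSize, origin) {
  cells <- which(lab == id, arr.ind = TRUE)
  nr <- nrow(lab); nc <- ncol(lab)
  inReg <- matrix(FALSE, nr + 2, nc + 2)
  inReg[cbind(cells[, 1] + 1, cells[, 2] + 1)] <- TRUE
  # directed boundary edges between lattice corners, interior on the left.
  # corner key: (r, c) with r in 0..nr, c in 0..nc -> r * (nc + 1) + c
  key <- function(r, c) r * (nc + 1) + c
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    if (!inReg[r, c + 1])     { from <- c(from, key(r - 1, c));     to <- c(to, key(r - 1, c - 1)) } # north, heading west
    if (!inReg[r + 2, c + 1]) { from <- c(from, key(r, c - 1));     to <- c(to, key(r, c)) }         # south, heading east
    if (!inReg[r + 1, c])     { from <- c(from, key(r - 1, c - 1)); to <- c(to, key(r, c - 1)) }     # west, heading south
    if (!inReg[r + 1, c + 2]) { from <- c(from, key(r, c));         to <- c(to, key(r - 1, c)) }     # east, heading north
  }
  used <- rep(FALSE, length(from))
  ord <- order(from)
  starts <- split(ord, from[ord])   # edge indices by start corner
  rings <- list()
  # direction of an edge in map orientation (x east, y north)
  dirOf <- function(e) c(to[e] %% (nc + 1) - from[e] %% (nc + 1),
                         -(to[e] %/% (nc + 1) - from[e] %/% (nc + 1)))
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      ring <- c(ring, to[e])
      if (to[e] == from[e0]) break
      cand <- starts[[as.character(to[e])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) stop("boundary tracing failed (open ring)")
      if (length(cand) > 1) {
        # ambiguous corner (diagonal touch): take the left-most turn
        d <- dirOf(e)
        turns <- vapply(cand, function(ce) {
          dn <- dirOf(ce)
          atan2(d[1] * dn[2] - d[2] * dn[1], d[1] * dn[1] + d[2] * dn[2])
        }, numeric(1))
        cand <- cand[which.max(turns)]
      }
      e <- cand
    }
    r <- ring %/% (nc + 1); c <- ring %% (nc + 1)
    rings[[length(rings) + 1]] <- cbind(x = origin[1] + c * cellSize,
                                        y = origin[2] - r * cellSize)
  }
  areas <- vapply(rings, ringSignedArea, numeric(1))
  rings[order(-abs(areas))]
}

ringSignedArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Polygon geometry of every segment
#'
#' Cell-edge-following boundaries (4-connected regions), as closed coordinate
#' rings; ring 1 of each segment is the outer boundary, later rings are holes.
#'
#' @param layer a \linkS4class{SegmentLayer}
#' @return named list (by segment id) of lists of rings
#' @export
segmentPolygons <- function(layer) {
  lab <- layer@labels@values
  out <- lapply(layer@table$id, function(id)
    traceRegion(lab, id, layer@labels@cellSize, layer@labels@origin))
  names(out) <- layer@table$id
  out
}

#' Write a segment layer to GeoJSON
#'
#' One Polygon feature per segment carrying the full attribute table as
#' properties.
#'
#' @param layer a \linkS4class{SegmentLayer}
#' @param path output .geojson path
#' @return the path, invisibly
#' @export
writeSegmentsGeoJSON <- function(layer, path) {
  polys <- segmentPolygons(layer)
  tab <- layer@table
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    rings <- lapply(polys[[i]], function(r) unname(lapply(seq_len(nrow(r)),
      function(j) c(r[j, 1], r[j, 2]))))
    props <- as.list(tab[i, , drop = FALSE])
    props <- lapply(props, function(v) if (is.na(v)) NULL else unname(v))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = rings),
         properties = props)
  })
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                              auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Supports Polygon and MultiPolygon features; returns the rings as coordinate
#' matrices (outer rings only), suitable for the water mask and study-boundary
#' inputs.
#'
#' @param path .geojson file
#' @return list of two-column coordinate matrices
#' @export
readPolygonsGeoJSON <- function(path) {
  if (!file.exists(path))
    stop(sprintf("GeoJSON file not found: %s", path), call. = FALSE)
  gj <- jsonlite::read_json(path)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    ringToMat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (g$type == "Polygon") out[[length(out) + 1]] <- ringToMat(g$coordinates[[1]])
    else if (g$type == "MultiPolygon")
      for (p in g$coordinates) out[[length(out) + 1]] <- ringToMat(p[[1]])
    else stop(sprintf("unsupported GeoJSON geometry: %s", g$type), call. = FALSE)
  }
  out
}

#' Write a single polygon (or polygon list) to GeoJSON
#'
#' @param polys one two-column matrix or a list of them
#' @param path output path
#' @return the path, invisibly
#' @export
writePolygonsGeoJSON <- function(polys, path) {
  if (is.matrix(polys)) polys <- list(polys)
  feats <- lapply(polys, function(m) {
    m <- closeRing(m)
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(seq_len(nrow(m)),
                           function(j) c(m[j, 1], m[j, 2]))))),
         properties = structure(list(), names = character(0)))
  })
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

closeRing <- function(m) {
  if (m[1, 1] != m[nrow(m), 1] || m[1, 2] != m[nrow(m), 2]) rbind(m, m[1, ])
  else m
}

#' Read or write sample points
#'
#' Points CSV with columns x, y, label, role (training/validation).
#'
#' @param path CSV file
#' @return data.frame
#' @export
readPointsCSV <- function(path) {
  if (!file.exists(path))
    stop(sprintf("points file not found: %s", path), call. = FALSE)
  pts <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "label", "role")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop(sprintf("points file lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  pts
}

#' @describeIn readPointsCSV write points
#' @param pts data.frame with x, y, label, role
#' @export
writePointsCSV <- function(pts, path) {
  write.csv(pts, path, row.names = FALSE)
  invisible(path)
}
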