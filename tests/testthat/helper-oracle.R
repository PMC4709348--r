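# Independent brute-force region-merging simulator. Recomputes every region
# statistic from scratch at every step (no incremental bookkeeping), merging
# the globally cheapest admissible adjacent pair (ties: lowest id pair, ids
# being the smallest row-major cell index of each region). Used as the oracle
# for the fast implementation on small instances.

refRegionStats <- function(lab, id, vals) {
  sel <- lab == id & !is.na(lab)
  cells <- which(sel, arr.ind = TRUE)
  nb <- dim(vals)[3]
  sds <- numeric(nb)
  for (b in seq_len(nb)) {
    x <- vals[, , b][sel]
    sds[b] <- sqrt(max(0, mean(x^2) - mean(x)^2))
  }
  # perimeter: edges to outside / other labels
  nr <- nrow(lab); nc <- ncol(lab)
  per <- 0
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || is.na(lab[rr, cc]) ||
          lab[rr, cc] != id) per <- per + 1
    }
  }
  list(n = nrow(cells), sd = sds, perim = per,
       bbox = c(range(cells[, 1]), range(cells[, 2])))
}

refH <- function(st, w, wCmpct) {
  hColor <- sum(w * st$n * st$sd)
  b <- 2 * ((st$bbox[2] - st$bbox[1] + 1) + (st$bbox[4] - st$bbox[3] + 1))
  hShape <- wCmpct * (st$perim / sqrt(st$n)) + (1 - wCmpct) * (st$perim / b)
  c(color = hColor, shape = hShape)
}

refMergeCost <- function(lab, a, b, vals, w, wShape, wCmpct) {
  sa <- refRegionStats(lab, a, vals)
  sb <- refRegionStats(lab, b, vals)
  lab2 <- lab
  lab2[lab2 == b] <- a
  sm <- refRegionStats(lab2, a, vals)
  ha <- refH(sa, w, wCmpct); hb <- refH(sb, w, wCmpct); hm <- refH(sm, w, wCmpct)
  wShape * (hm["shape"] - ha["shape"] - hb["shape"]) +
    (1 - wShape) * (hm["color"] - ha["color"] - hb["color"])
}

refAdjacentPairs <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lab[r, c])) next
    for (d in list(c(0, 1), c(1, 0))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr <= nr && cc <= nc && !is.na(lab[rr, cc]) &&
          lab[rr, cc] != lab[r, c])
        pairs <- rbind(pairs, sort(c(lab[r, c], lab[rr, cc])))
    }
  }
  if (is.null(pairs)) return(NULL)
  unique(pairs)
}

refSegment <- function(vals, weights, scale, wShape, wCmpct) {
  nr <- dim(vals)[1]; nc <- dim(vals)[2]
  valid <- apply(!is.na(vals), c(1, 2), all)
  # ids: row-major cell index
  lab <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (valid[r, c]) lab[r, c] <- (r - 1) * nc + c
  repeat {
    pairs <- refAdjacentPairs(lab)
    if (is.null(pairs)) break
    costs <- apply(pairs, 1, function(p)
      refMergeCost(lab, p[1], p[2], vals, weights, wShape, wCmpct))
    ord <- order(costs, pairs[, 1], pairs[, 2])
    best <- ord[1]
    if (costs[best] >= scale^2) break
    lab[lab == pairs[best, 2]] <- pairs[best, 1]
  }
  # compact labels in row-major first-occurrence order
  ids <- unique(as.vector(t(lab))[!is.na(as.vector(t(lab)))])
  out <- matrix(NA_integer_, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# run the packaged segmenter on a raw array (single-period convenience)
fastSegment <- function(vals, weights, scale, wShape, wCmpct, cellSize = 30) {
  nb <- dim(vals)[3]
  roles <- paste0("b", seq_len(nb))
  bands <- lapply(seq_len(nb), function(b) mkGrid(vals[, , b], cellSize))
  names(bands) <- roles
  st <- bandStack(bands, "2014-100", period = "D")
  w <- setNames(weights, roles)
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = scale, shapeWeight = wShape, compactness = wCmpct,
    bandWeights = w, valueScale = 1))
  gridValues(lay@labels)
}
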