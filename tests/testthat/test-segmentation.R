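test_that("a spatially uniform image collapses to a single segment", {
  st <- mkStack(red = matrix(0.4, 8, 8), nir = matrix(0.4, 8, 8))
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = 5, bandWeights = c(red = 1, nir = 1), valueScale = 1))
  expect_equal(nrow(lay@table), 1)
  expect_equal(lay@table$n, 64L)
})

test_that("a two-tone image splits into its halves at a small enough scale", {
  # 2x2 instance with two homogeneous vertical halves; exhaustive check of
  # the admissible merge sequences: within-half merges cost 0 (spectral) and
  # a negative-to-small shape increment; any cross-half merge raises the
  # spectral term by >= 10. scale^2 = 5 admits only the within-half merges.
  m <- matrix(c(0, 0, 10, 10), 2)
  lay <- fastSegment(array(m, c(2, 2, 1)), 1, sqrt(5), 0, 0.5)
  expect_equal(max(lay, na.rm = TRUE), 2)
  expect_equal(lay[, 1], c(1L, 1L))
  expect_equal(lay[, 2], c(2L, 2L))
  # and the brute-force simulator agrees
  expect_equal(lay, refSegment(array(m, c(2, 2, 1)), 1, sqrt(5), 0, 0.5))
})

test_that("segment count is non-increasing in the scale parameter", {
  set.seed(31)
  for (i in 1:50) {
    vals <- array(runif(64, 0, 100), c(8, 8, 1))
    scales <- sort(runif(2, 2, 60))
    n1 <- max(fastSegment(vals, 1, scales[1], 0.1, 0.1), na.rm = TRUE)
    n2 <- max(fastSegment(vals, 1, scales[2], 0.1, 0.1), na.rm = TRUE)
    expect_gte(n1, n2)
  }
})

test_that("fast segmentation matches the brute-force simulator on small instances", {
  set.seed(32)
  for (i in 1:12) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    nb <- sample(1:2, 1)
    vals <- array(sample(0:6, nr * nc * nb, replace = TRUE), c(nr, nc, nb))
    scale <- runif(1, 1, 8)
    fast <- fastSegment(vals, rep(1, nb), scale, 0.1, 0.1)
    ref <- refSegment(vals, rep(1, nb), scale, 0.1, 0.1)
    expect_equal(fast, ref, label = sprintf("instance %d", i))
  }
})

test_that("segments partition the valid region and mirror symmetric inputs", {
  set.seed(33)
  half <- matrix(runif(60, 0, 50), 10, 6)
  m <- cbind(half, half[, 6:1])
  m[3, 1] <- NA
  st <- mkStack(red = m, nir = m)
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = 10, bandWeights = c(red = 1, nir = 1), valueScale = 1))
  lab <- gridValues(lay@labels)
  expect_true(is.na(lab[3, 1]))
  expect_equal(sum(lay@table$n), sum(!is.na(lab)))
  # mirrored halves of a symmetric, NA-free image get mirrored statistics
  st2 <- mkStack(red = cbind(half, half[, 6:1]), nir = cbind(half, half[, 6:1]))
  lay2 <- multiresolutionSegment(st2, segmentationParams(
    scale = 10, bandWeights = c(red = 1, nir = 1), valueScale = 1))
  lab2 <- gridValues(lay2@labels)
  left <- table(lab2[, 1:6])
  right <- table(lab2[, 12:7])
  expect_equal(sort(as.integer(left)), sort(as.integer(right)))
})

test_that("zonal attributes equal brute-force per-cell aggregation", {
  set.seed(34)
  m <- matrix(runif(64), 8, 8)
  st <- mkStack(red = m, nir = m)
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = 4, bandWeights = c(red = 1), valueScale = 1))
  g <- mkGrid(matrix(runif(64), 8, 8))
  g2 <- withValues(g, {v <- gridValues(g); v[1:5] <- NA; v})
  lay <- zonalAttributes(lay, list(ndviDiff = g2))
  lab <- gridValues(lay@labels)
  for (i in seq_len(nrow(lay@table))) {
    cells <- gridValues(g2)[lab == lay@table$id[i]]
    want <- if (all(is.na(cells))) NA_real_ else mean(cells, na.rm = TRUE)
    expect_equal(lay@table$meanNdviDiff[i], want)
  }
  # constant grid: every mean equals the constant
  layC <- zonalAttributes(lay, list(slope = mkGrid(matrix(3.5, 8, 8))))
  expect_true(all(layC@table$meanSlope == 3.5))
  expect_error(zonalAttributes(lay, list(x = mkGrid(matrix(1, 2, 2)))),
               "geometry")
})

test_that("water masking follows the centroid rule", {
  lay <- mkSegmentLayer(meanNdviDiff = c(0.5, 0.4, 0.6),
                        meanSlope = c(0, 0, 0), n = c(2L, 2L, 2L))
  expect_equal(maskWater(lay, list())@table$masked, rep(FALSE, 3))
  # lake covering segment 2 entirely
  cx <- lay@table$centroidX[2]; cy <- lay@table$centroidY[2]
  lake <- cbind(c(cx - 40, cx + 40, cx + 40, cx - 40),
                c(cy - 20, cy - 20, cy + 20, cy + 20))
  m <- maskWater(lay, list(lake))
  expect_equal(m@table$masked, c(FALSE, TRUE, FALSE))
  # self-intersecting polygon is rejected
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(maskWater(lay, list(bow)), "self-intersecting")
})

test_that("a C-shaped segment with its centroid in a lake is masked", {
  # C-shaped region around a small lake: most cells on land, centroid inside
  m <- matrix(80, 5, 5)
  m[2:4, 2:4] <- 10    # lake-ish center, also a distinct segment
  m[2:4, 4] <- 80      # open the C toward the east
  st <- mkStack(red = m, nir = m, cellSize = 10)
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = 3, bandWeights = c(red = 1), valueScale = 1))
  lay <- zonalAttributes(lay, list(ndviDiff = mkGrid(m / 100, cellSize = 10)))
  # the big bright segment is C-shaped; its centroid falls near the grid
  # center, inside the lake polygon below
  big <- lay@table$id[which.max(lay@table$n)]
  ctr <- lay@table[lay@table$id == big, c("centroidX", "centroidY")]
  lake <- cbind(c(10, 40, 40, 10), c(10, 10, 40, 40))
  expect_true(pointInPolygon(ctr$centroidX, ctr$centroidY, lake))
  masked <- maskWater(lay, list(lake))
  expect_true(masked@table$masked[masked@table$id == big])
})

test_that("segment polygons trace boundaries that close and conserve area", {
  m <- matrix(20, 6, 6)
  m[2:5, 2:5] <- 80
  m[3:4, 3:4] <- 20    # ring segment with a hole
  st <- mkStack(red = m, nir = m, cellSize = 10)
  lay <- multiresolutionSegment(st, segmentationParams(
    scale = 2, bandWeights = c(red = 1), valueScale = 1))
  polys <- segmentPolygons(lay)
  areas <- vapply(polys, function(rings)
    sum(vapply(rings, function(r) {
      x <- r[, 1]; y <- r[, 2]; n <- nrow(r)
      sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
    }, numeric(1))), numeric(1))
  # net signed area (outer CCW minus holes) equals cell count x cell area
  expect_equal(unname(areas[as.character(lay@table$id)]),
               lay@table$n * 100)
  tf <- withr::local_tempfile(fileext = ".geojson")
  writeSegmentsGeoJSON(lay, tf)
  back <- readPolygonsGeoJSON(tf)
  expect_equal(length(back), nrow(lay@table))
})
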