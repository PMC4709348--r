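test_that("threshold derivation follows the mean -/+ k sd rule", {
  # zero-variance cropland: threshold equals the common value for any k
  diffG <- mkGrid(matrix(0.45, 4, 4))
  slopeG <- mkGrid(matrix(2, 4, 4))
  cc <- cellCenters(diffG)
  pts <- data.frame(x = as.vector(cc$x)[1:6], y = as.vector(cc$y)[1:6],
                    label = c(rep("cropland", 3), rep("bare", 3)))
  st <- deriveThresholds(pts, diffG, slopeG, kNdvi = 2.3)
  expect_equal(st@ndviThreshold, 0.45)
  expect_equal(st@slopeThreshold, 2)
  expect_true(all(c("cropland", "bare") %in% st@coverTable$cover))
  expect_error(deriveThresholds(pts[c(1, 4:6), ], diffG, slopeG),
               "at least 2")
})

test_that("the printed training statistics imply the direct-arithmetic threshold", {
  # the rule itself: mean 0.5713, sd 0.113, k 2.3 -> 0.3114; the published
  # decision constant 0.30291 is carried as the pipeline default instead
  expect_equal(0.5713 - 2.3 * 0.113, 0.3114, tolerance = 1e-9)
  expect_equal(defaultThresholds()@ndviThreshold, 0.30291)
  expect_equal(defaultThresholds()@slopeThreshold, 7.625)
})

test_that("derived thresholds recover the generating parameters from samples", {
  set.seed(41)
  mu <- 0.5713; sigma <- 0.113; n <- 51
  m <- matrix(rnorm(n, mu, sigma), 1)
  diffG <- mkGrid(m)
  slopeG <- mkGrid(matrix(1, 1, n))
  cc <- cellCenters(diffG)
  pts <- data.frame(x = as.vector(cc$x), y = as.vector(cc$y),
                    label = "cropland")
  st <- deriveThresholds(pts, diffG, slopeG, kNdvi = 2.3)
  expect_lt(abs(st@ndviThreshold - (mu - 2.3 * sigma)), 3 * sigma / sqrt(n) * 3)
})

test_that("Horn slope matches flat, analytic-plane and brute-force cases", {
  expect_true(all(gridValues(slopeGrid(mkGrid(matrix(100, 5, 5),
                                              cellSize = 1))) == 0))
  plane <- mkGrid(matrix(rep(1:6, each = 5), 5, 6), cellSize = 1)
  s <- gridValues(slopeGrid(plane))
  expect_equal(s[2:4, 2:5], matrix(45, 3, 4))
  # brute-force oracle with explicit clamped 3x3 neighborhoods
  set.seed(42)
  z <- matrix(runif(49, 0, 50), 7)
  dem <- mkGrid(z, cellSize = 10)
  got <- gridValues(slopeGrid(dem))
  idx <- function(i, n) pmin(pmax(i, 1), n)
  for (r in c(1, 3, 7)) for (c in c(1, 4, 7)) {
    zz <- z[idx(r + (-1:1), 7), idx(c + (-1:1), 7)]
    gx <- ((zz[1, 3] + 2 * zz[2, 3] + zz[3, 3]) -
           (zz[1, 1] + 2 * zz[2, 1] + zz[3, 1])) / 80
    gy <- ((zz[3, 1] + 2 * zz[3, 2] + zz[3, 3]) -
           (zz[1, 1] + 2 * zz[1, 2] + zz[1, 3])) / 80
    expect_equal(got[r, c], atan(sqrt(gx^2 + gy^2)) * 180 / pi,
                 tolerance = 1e-9)
  }
  expect_error(slopeGrid(mkGrid(matrix(1, 1, 5))), "2 rows")
})

test_that("classification honors the inclusive NDVI and exclusive slope boundaries", {
  lay <- mkSegmentLayer(
    meanNdviDiff = c(0.30291, 0.30290999, 0.9, 0.9, 0.5),
    meanSlope = c(0, 0, 7.625, 7.624, 3),
    masked = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  pc <- classifyPeriod(lay, defaultThresholds())
  cls <- pc@layer@table$class
  expect_equal(cls[1], "active_winter_cropland")  # exactly at the NDVI cut
  expect_equal(cls[2], "other")                   # just below it
  expect_equal(cls[3], "other")                   # slope at the cut: filtered
  expect_equal(cls[4], "active_winter_cropland")  # slope just below
  expect_true(is.na(cls[5]))                      # masked segments drop out
  expect_equal(unname(sum(pc@proportions)), 1)
})

test_that("an all-below-threshold map yields zero crop area and W_other = 1", {
  lay <- mkSegmentLayer(meanNdviDiff = c(0.1, 0.2), meanSlope = c(0, 0))
  pc <- classifyPeriod(lay, defaultThresholds())
  expect_equal(pc@cropAreaKm2, 0)
  expect_equal(unname(pc@proportions["other"]), 1)
})

test_that("classification is monotone in both thresholds", {
  set.seed(43)
  lay <- mkSegmentLayer(meanNdviDiff = runif(30, 0, 0.8),
                        meanSlope = runif(30, 0, 15))
  nCrop <- function(tN, tS) {
    st <- defaultThresholds()
    st@ndviThreshold <- tN; st@slopeThreshold <- tS
    sum(classifyPeriod(lay, st)@layer@table$class == "active_winter_cropland",
        na.rm = TRUE)
  }
  for (t in seq(0, 0.8, by = 0.1))
    expect_gte(nCrop(t, 7.625), nCrop(t + 0.1, 7.625))
  for (t in seq(0, 15, by = 3))
    expect_lte(nCrop(0.3, t), nCrop(0.3, t + 3))
})

test_that("overlay accounting matches identity, disjoint and brute-force cases", {
  set.seed(44)
  pres <- matrix(runif(100) < 0.4, 10, 10)
  ident <- overlayPeriods(lapply(c("A", "B", "C", "D"), function(p)
    mkPC(pres, p)))
  cellKm2 <- 0.01
  expect_equal(unname(ident@categories["stable"]), sum(pres) * cellKm2)
  expect_equal(ident@unionAreaKm2, sum(pres) * cellKm2)
  expect_true(all(ident@areaTable$areaKm2[!ident@areaTable$code %in%
                                            c(0, 15)] == 0))
  # disjoint: each period crops its own quadrant
  quad <- function(r, c) {
    m <- matrix(FALSE, 10, 10); m[r, c] <- TRUE; m
  }
  parts <- list(quad(1:5, 1:5), quad(1:5, 6:10), quad(6:10, 1:5),
                quad(6:10, 6:10))
  disj <- overlayPeriods(Map(mkPC, parts, c("A", "B", "C", "D")))
  expect_equal(disj@unionAreaKm2, 4 * 25 * cellKm2)
  expect_equal(unname(disj@categories["stable"]), 0)
  # random layers: per-code areas equal a brute-force tabulation
  layers <- lapply(1:4, function(i) matrix(runif(100) < 0.5, 10, 10))
  ov <- overlayPeriods(Map(mkPC, layers, c("A", "B", "C", "D")))
  code <- layers[[1]] + 2 * layers[[2]] + 4 * layers[[3]] + 8 * layers[[4]]
  for (k in 0:15)
    expect_equal(ov@areaTable$areaKm2[ov@areaTable$code == k],
                 sum(code == k) * cellKm2)
  # conservation: all 16 codes sum to the study area
  expect_equal(sum(ov@areaTable$areaKm2), 100 * cellKm2)
})

test_that("the map-product area filter never touches the totals", {
  set.seed(45)
  layers <- lapply(1:4, function(i) matrix(runif(400) < 0.5, 20, 20))
  ov <- overlayPeriods(Map(mkPC, layers, c("A", "B", "C", "D"),
                              cellSize = 1000))
  kept <- filterOverlayTable(ov, minKm2 = 30)
  expect_true(all(kept$areaKm2 > 30))
  expect_equal(sum(ov@areaTable$areaKm2), 400)  # totals unchanged
})
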