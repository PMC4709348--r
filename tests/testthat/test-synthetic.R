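bundle256 <- NULL
getBundle <- function() {
  if (is.null(bundle256))
    bundle256 <<- generateSceneCollection(sceneTemplate(), seed = 1)
  bundle256
}

test_that("composited crop NDVI difference hits the target moments", {
  bundle <- getBundle()
  lev <- coverLevels()
  for (per in c("A", "D")) {
    sc <- bundle@scenes[[per]]
    isSpring <- vapply(sc, function(s) seasonOf(s) == "spring", logical(1))
    comp <- ndviComposite(sc[isSpring], sc[!isSpring], per)
    crop <- gridValues(bundle@truth[[per]]) == match("cropland", lev)
    d <- gridValues(comp@difference)[crop]
    expect_lt(abs(mean(d, na.rm = TRUE) - 0.5713), 0.02)
    expect_lt(abs(sd(d, na.rm = TRUE) - 0.113), 0.03)
  }
})

test_that("non-crop covers stay below the classification threshold on average", {
  bundle <- getBundle()
  lev <- coverLevels()
  sc <- bundle@scenes$D
  isSpring <- vapply(sc, function(s) seasonOf(s) == "spring", logical(1))
  comp <- ndviComposite(sc[isSpring], sc[!isSpring], "D")
  d <- gridValues(comp@difference)
  tru <- gridValues(bundle@truth$D)
  for (cv in setdiff(lev, "cropland")) {
    sel <- tru == match(cv, lev)
    if (!any(sel)) next
    expect_lt(mean(d[sel], na.rm = TRUE), defaultThresholds()@ndviThreshold)
  }
  # water is dark in both seasons
  w <- tru == match("water", lev)
  expect_true(all(gridValues(comp@springMVC)[w] < 0, na.rm = TRUE))
  expect_true(all(gridValues(comp@summerMedian)[w] < 0, na.rm = TRUE))
})

test_that("grassland sits on steeper terrain than cropland", {
  bundle <- getBundle()
  lev <- coverLevels()
  slope <- gridValues(slopeGrid(bundle@dem))
  tru <- gridValues(bundle@truth$D)
  expect_gt(mean(slope[tru == match("grassland", lev)]),
            mean(slope[tru == match("cropland", lev)]))
})

test_that("true crop area equals the active-cell count times cell area", {
  bundle <- getBundle()
  lev <- coverLevels()
  cs <- bundle@template@cellSize
  for (per in names(bundle@truth)) {
    nCrop <- sum(gridValues(bundle@truth[[per]]) == match("cropland", lev))
    expect_equal(unname(bundle@trueCropAreaKm2[per]), nCrop * cs^2 / 1e6)
  }
})

test_that("fields inactive in a period show no spring green-up there", {
  bundle <- getBundle()
  fa <- bundle@fieldActivity
  expect_gt(sum(!fa$activePeriod[, "B"]), 0)  # some abandonment in B
  lev <- coverLevels()
  truB <- gridValues(bundle@truth$B)
  truD <- gridValues(bundle@truth$D)
  # cells that are cropland in D but not in B are exactly the B-inactive
  # fields; none of B's spring scenes shows crop-like greenness there
  offB <- truB == match("bare", lev) & truD == match("cropland", lev)
  expect_gt(sum(offB), 0)
  sc <- bundle@scenes$B
  for (s in sc[vapply(sc, function(x) seasonOf(x) == "spring", logical(1))]) {
    v <- gridValues(ndvi(s))
    expect_lt(max(v[offB], na.rm = TRUE), 0.4)
  }
})

test_that("a zero-cropland template classifies to (almost) no crop area", {
  tpl <- sceneTemplate(nrow = 60, ncol = 60,
                       coverFractions = c(cropland = 0, bare = 0.6,
                                          orchard = 0.2, shrub = 0.15,
                                          built_up = 0.05))
  bundle <- generateSceneCollection(tpl, seed = 9, periods = "A")
  expect_equal(unname(bundle@trueCropAreaKm2["A"]), 0)
  sc <- bundle@scenes$A
  isSpring <- vapply(sc, function(s) seasonOf(s) == "spring", logical(1))
  comp <- ndviComposite(sc[isSpring], sc[!isSpring], "A")
  lay <- multiresolutionSegment(sc[[which(isSpring)[1]]])
  lay <- zonalAttributes(lay, list(ndviDiff = comp@difference,
                                   slope = slopeGrid(bundle@dem)))
  lay <- maskWater(lay, bundle@water)
  pc <- classifyPeriod(lay, defaultThresholds(), "A")
  # false positives only: under 2 percent of the scene
  expect_lt(pc@cropAreaKm2, 0.02 * (60 * 30)^2 / 1e6)
})

test_that("a degenerate crop signal below the threshold warns", {
  expect_warning(generateSceneCollection(
    sceneTemplate(nrow = 20, ncol = 20, cropDiffMean = 0.2), seed = 2,
    periods = "A"), "below the classification threshold")
})

test_that("road transect geometry places points at fixed spacing on the right", {
  road <- cbind(c(0, 10000), c(0, 0))   # straight 10 km road heading east
  pts <- roadTransectPoints(road, spacing = 1000, offset = 15)
  expect_equal(nrow(pts), 10)
  expect_equal(diff(pts$x), rep(1000, 9))
  expect_true(all(pts$y == -15))        # right of eastbound travel is south
})

test_that("sample point sets have the reference design and are reproducible", {
  bundle <- getBundle()
  p1 <- samplePoints(bundle, seed = 7)
  p2 <- samplePoints(bundle, seed = 7)
  expect_identical(p1, p2)
  train <- p1[p1$role == "training", ]
  expect_equal(nrow(train), 333)
  expect_equal(sum(train$label == "cropland"), 51)
  valid <- p1[p1$role == "validation", ]
  expect_equal(nrow(valid), 240)
  # a too-short road yields fewer points with a warning
  shortBundle <- bundle
  shortBundle@road <- cbind(c(0, 3000), c(100, 100))
  expect_warning(samplePoints(shortBundle, nValid = 240, spacing = 1000),
                 "only")
})

test_that("scene generation is deterministic given the seed", {
  t1 <- sceneTemplate(nrow = 30, ncol = 30)
  b1 <- generateSceneCollection(t1, seed = 4, periods = "A")
  b2 <- generateSceneCollection(t1, seed = 4, periods = "A")
  expect_identical(gridValues(getBand(b1@scenes$A[[1]], "red")),
                   gridValues(getBand(b2@scenes$A[[1]], "red")))
  expect_identical(b1@trueCropAreaKm2, b2@trueCropAreaKm2)
})
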