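test_that("error matrices cross-tabulate validation points against the map", {
  lay <- mkSegmentLayer(meanNdviDiff = c(0.6, 0.1), meanSlope = c(0, 0),
                        n = c(3L, 3L))
  pc <- classifyPeriod(lay, defaultThresholds())
  cc <- cellCenters(lay@labels)
  pts <- data.frame(x = as.vector(t(cc$x)), y = as.vector(t(cc$y)),
                    label = c("cropland", "cropland", "grassland",
                              "bare", "cropland", "built_up"))
  m <- buildErrorMatrix(pts, pc)
  expect_equal(unname(matrixCounts(m)), matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  # perfect agreement gives a diagonal matrix
  pts2 <- pts
  pts2$label <- c("cropland", "cropland", "cropland", "bare", "bare", "bare")
  expect_equal(unname(diag(matrixCounts(buildErrorMatrix(pts2, pc)))),
               c(3, 3))
  expect_error(buildErrorMatrix(pts[0, ], pc), "empty")
  # points outside the grid are excluded and counted
  pts3 <- rbind(pts, data.frame(x = -1000, y = -1000, label = "cropland"))
  m3 <- buildErrorMatrix(pts3, pc)
  expect_equal(attr(m3, "nExcluded"), 1L)
  expect_equal(sum(matrixCounts(m3)), 6)
})

test_that("accuracy statistics reproduce the published per-period values", {
  ref <- duhokReference()
  want <- list(
    A = list(ua = c(69.8, 91.6), kappa = 0.597),
    B = list(ua = c(82.9, 98.9), kappa = 0.859),
    C = list(ua = c(69.2, 96.1), kappa = 0.696),
    D = list(ua = c(82.6, 94.6), kappa = 0.759))
  for (p in names(want)) {
    st <- accuracyStats(ref$errorMatrices[[p]])
    expect_equal(round(100 * unname(st$userAccuracy), 1), want[[p]]$ua,
                 label = p)
    expect_equal(round(st$kappa, 3), want[[p]]$kappa, label = p)
  }
  # chance-level agreement has kappa 0
  st0 <- accuracyStats(errorMatrix(matrix(10, 2, 2)))
  expect_equal(st0$kappa, 0)
  # degenerate rows are NA, not zero
  stz <- accuracyStats(errorMatrix(matrix(c(0, 0, 5, 10), 2, byrow = TRUE)))
  expect_true(is.na(stz$userAccuracy["cropland"]))
})

test_that("user's accuracy is unchanged by area weighting; kappa stays in range", {
  set.seed(51)
  for (i in 1:20) {
    n <- matrix(rpois(4, 40) + 1, 2)
    m <- errorMatrix(n)
    Wc <- runif(1, 0.05, 0.95)
    st <- accuracyStats(m, W = c(cropland = Wc, other = 1 - Wc))
    # row-conditional: UA_i = p_ii / p_i. regardless of W
    pRow <- st$areaWeighted$p / rowSums(st$areaWeighted$p)
    expect_equal(unname(diag(pRow)), unname(st$userAccuracy), tolerance = 1e-12)
    expect_true(st$kappa >= -1 && st$kappa <= 1)
  }
  # kappa = 1 iff the off-diagonal is empty with both classes present
  expect_equal(accuracyStats(errorMatrix(matrix(c(7, 0, 0, 9), 2)))$kappa, 1)
})

test_that("adjusted areas reproduce the published confidence intervals", {
  ref <- duhokReference()
  for (p in c("B", "D")) {
    m <- ref$errorMatrices[[p]]
    W <- solveMappedProportion(m, ref$totalAreaKm2, ref$adjustedCropKm2[p])
    est <- adjustedArea(m, W, ref$totalAreaKm2)
    expect_equal(unname(round(est@areaKm2["cropland"])),
                 unname(ref$adjustedCropKm2[p]), label = p)
    expect_equal(unname(round(est@halfWidthKm2["cropland"])),
                 unname(ref$halfWidthKm2[p]), label = p)
  }
})

test_that("an error-free map yields the mapped areas exactly, with zero width", {
  m <- errorMatrix(matrix(c(40, 0, 0, 160), 2, byrow = TRUE))
  est <- adjustedArea(m, c(cropland = 0.3, other = 0.7), 1000)
  expect_equal(unname(est@areaKm2), c(300, 700))
  expect_equal(unname(est@halfWidthKm2), c(0, 0))
  expect_error(adjustedArea(errorMatrix(matrix(c(1, 0, 3, 7), 2, byrow = TRUE)),
                            c(cropland = 0.3, other = 0.7), 1000),
               "at least 2")
})

test_that("adjusted areas always sum to the total area", {
  set.seed(52)
  for (i in 1:25) {
    n <- matrix(rpois(4, 30) + 2, 2)
    Wc <- runif(1, 0.05, 0.95)
    est <- adjustedArea(errorMatrix(n), c(cropland = Wc, other = 1 - Wc), 6600)
    expect_equal(unname(sum(est@areaKm2)), 6600, tolerance = 1e-9)
  }
})

test_that("interval change bounds reproduce the published overlap arithmetic", {
  a <- areaEstimate(1200, 263, 6600)
  b <- areaEstimate(868, 141, 6600)
  c_ <- areaEstimate(1040, 216, 6600)
  ab <- changeBounds(a, b)
  expect_equal(ab@overlapKm2, 72)
  expect_equal(ab@maxDecreaseKm2, 736)
  bc <- changeBounds(b, c_)
  expect_equal(bc@maxIncreaseKm2, 529)
  expect_equal(bc@maxDecreaseKm2, 185)
  # identity: overlap and both bounds collapse to twice the half-width
  ii <- changeBounds(a, a)
  expect_equal(ii@overlapKm2, 2 * 263)
  expect_equal(ii@maxIncreaseKm2, 2 * 263)
  # disjoint intervals have zero overlap
  dd <- changeBounds(areaEstimate(100, 10, 6600), areaEstimate(500, 10, 6600))
  expect_equal(dd@overlapKm2, 0)
})

test_that("the 95 percent CI covers the true area at close to nominal rate", {
  # validation draws from a known confusion process on a mapped stratification
  set.seed(53)
  W <- c(cropland = 0.1848, other = 0.8152)
  pTrue <- rbind(c(0.826, 0.174), c(0.054, 0.946))
  Atot <- 6600; nPts <- 240
  trueCrop <- Atot * sum(W * pTrue[, 1])
  hits <- 0; nrep <- 500
  for (r in seq_len(nrep)) {
    n1 <- rbinom(1, nPts, W[1])
    n1 <- min(max(n1, 2), nPts - 2)
    k1 <- rbinom(1, n1, pTrue[1, 1])
    k2 <- rbinom(1, nPts - n1, pTrue[2, 1])
    m <- errorMatrix(matrix(c(k1, n1 - k1, k2, nPts - n1 - k2), 2,
                            byrow = TRUE))
    est <- adjustedArea(m, W, Atot)
    lo <- est@areaKm2["cropland"] - est@halfWidthKm2["cropland"]
    hi <- est@areaKm2["cropland"] + est@halfWidthKm2["cropland"]
    if (trueCrop >= lo && trueCrop <= hi) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.9)
})
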