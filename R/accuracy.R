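#' Create an error matrix
#'
#' Rows index the mapped (classified) class, columns the reference class.
#'
#' @param counts square numeric matrix of sample counts
#' @param classes class names in row/column order
#' @return an \linkS4class{ErrorMatrix}
#' @export
errorMatrix <- function(counts, classes = c("cropland", "other")) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(mapped = classes, reference = classes)
  new("ErrorMatrix", counts = counts, classes = classes)
}

#' @describeIn errorMatrix count matrix
#' @param m an ErrorMatrix
#' @export
matrixCounts <- function(m) m@counts

setMethod("show", "ErrorMatrix", function(object) {
  cat(sprintf("ErrorMatrix (%d samples):\n", sum(object@counts)))
  print(object@counts)
})

#' Cross-tabulate validation points against a classification
#'
#' Each validation point is assigned the class of the segment containing it;
#' reference labels other than the crop label are collapsed to "other". Points
#' outside the study grid, or falling in masked or invalid cells, are excluded
#' (their count is reported as an attribute).
#'
#' @param points data.frame with x, y, label (reference cover)
#' @param classification a \linkS4class{PeriodClassification}
#' @param cropLabel reference label counted as cropland
#' @return an \linkS4class{ErrorMatrix} (classes cropland/other)
#' @export
buildErrorMatrix <- function(points, classification, cropLabel = "cropland") {
  if (!nrow(points)) stop("empty validation point set", call. = FALSE)
  layer <- classification@layer
  lab <- extractAtXY(layer@labels, points$x, points$y)
  cls <- rep(NA_character_, length(lab))
  ok <- !is.na(lab)
  cls[ok] <- layer@table$class[match(lab[ok], layer@table$id)]
  usable <- !is.na(cls)
  mapped <- ifelse(cls[usable] == "active_winter_cropland", "cropland", "other")
  ref <- ifelse(points$label[usable] == cropLabel, "cropland", "other")
  classes <- c("cropland", "other")
  counts <- table(factor(mapped, classes), factor(ref, classes))
  out <- errorMatrix(unclass(as.matrix(counts)), classes)
  attr(out, "nExcluded") <- sum(!usable)
  out
}

#' Accuracy statistics of an error matrix
#'
#' Count-based user's accuracy UA_i = n_ii / n_i., producer's accuracy
#' PA_j = n_jj / n_.j, overall accuracy OA = sum(n_ii) / n, and Cohen's kappa
#' (p_o - p_e)/(1 - p_e) with p_e the product of the marginal proportions.
#' When mapped proportions W are supplied, the area-weighted cell proportions
#' p_ij = W_i n_ij / n_i. give the area-weighted overall and producer's
#' accuracies (user's accuracy is row-conditional and unchanged by the
#' weighting). Zero rows/columns make the corresponding UA/PA undefined (NA).
#'
#' @param m an \linkS4class{ErrorMatrix}
#' @param W optional mapped class proportions (named like the classes)
#' @return list with userAccuracy, producerAccuracy, overallAccuracy, kappa,
#'   and (when W is given) areaWeighted = list(p, overallAccuracy,
#'   producerAccuracy)
#' @export
accuracyStats <- function(m, W = NULL) {
  n <- m@counts
  tot <- sum(n)
  if (tot <= 0) stop("empty error matrix", call. = FALSE)
  rowT <- rowSums(n); colT <- colSums(n)
  ua <- ifelse(rowT > 0, diag(n) / rowT, NA_real_)
  pa <- ifelse(colT > 0, diag(n) / colT, NA_real_)
  oa <- sum(diag(n)) / tot
  pe <- sum((rowT / tot) * (colT / tot))
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else NA_real_
  out <- list(userAccuracy = setNames(ua, m@classes),
              producerAccuracy = setNames(pa, m@classes),
              overallAccuracy = oa, kappa = kappa)
  if (!is.null(W)) {
    W <- W[m@classes]
    p <- sweep(n, 1, ifelse(rowT > 0, rowT, NA_real_), "/") * W
    pj <- colSums(p)
    out$areaWeighted <- list(
      p = p,
      overallAccuracy = sum(diag(p)),
      producerAccuracy = setNames(ifelse(pj > 0, diag(p) / pj, NA_real_),
                                  m@classes))
  }
  out
}

#' Stratified adjusted area estimates with confidence intervals
#'
#' Good-practice stratified estimator with the map classes as strata: the
#' estimated proportion of reference class j is p_.j = sum_i W_i n_ij / n_i.,
#' the adjusted area A_j = A_tot p_.j, with standard error
#' S(p_.j) = sqrt( sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1) ) and CI
#' half-width z A_tot S(p_.j). Adjusted areas always sum to A_tot.
#'
#' @param m an \linkS4class{ErrorMatrix}
#' @param W mapped class proportions (the strata weights; must sum to 1)
#' @param totalAreaKm2 total study area A_tot in km2
#' @param z confidence multiplier (1.96 for the 95 percent level)
#' @return an \linkS4class{AreaEstimate}
#' @export
adjustedArea <- function(m, W, totalAreaKm2, z = 1.96) {
  n <- m@counts
  W <- W[m@classes]
  if (abs(sum(W) - 1) > 1e-8) stop("mapped proportions W must sum to 1",
                                   call. = FALSE)
  rowT <- rowSums(n)
  if (any(rowT < 2))
    stop("every mapped class needs at least 2 samples (variance undefined)",
         call. = FALSE)
  pij <- sweep(n, 1, rowT, "/") * W          # p-hat_ij = W_i n_ij / n_i.
  pj <- colSums(pij)
  se <- sqrt(colSums(W^2 * sweep(n, 1, rowT, "/") *
                       (1 - sweep(n, 1, rowT, "/")) / (rowT - 1)))
  new("AreaEstimate", classes = m@classes, totalAreaKm2 = totalAreaKm2,
      W = setNames(as.numeric(W), m@classes),
      proportions = setNames(as.numeric(pj), m@classes),
      areaKm2 = setNames(as.numeric(totalAreaKm2 * pj), m@classes),
      se = setNames(as.numeric(se), m@classes), z = z,
      halfWidthKm2 = setNames(as.numeric(z * totalAreaKm2 * se), m@classes))
}

setMethod("show", "AreaEstimate", function(object) {
  cat(sprintf("AreaEstimate (A_tot %.0f km2, z %.2f):\n", object@totalAreaKm2,
              object@z))
  print(data.frame(class = object@classes, W = round(object@W, 4),
                   areaKm2 = round(object@areaKm2, 1),
                   halfWidthKm2 = round(object@halfWidthKm2, 1)),
        row.names = FALSE)
})

#' Solve the mapped crop proportion from a published adjusted estimate
#'
#' Mapped areas are often not printed alongside adjusted estimates; given the
#' error matrix and the published adjusted crop area, this inverts
#' A_crop/A_tot = W_c (n_11/n_1.) + (1 - W_c)(n_21/n_2.) for W_c.
#'
#' @param m an \linkS4class{ErrorMatrix} (2 classes, crop first)
#' @param totalAreaKm2 total area A_tot
#' @param adjustedCropKm2 published adjusted crop area
#' @return named mapped proportions c(cropland, other)
#' @export
solveMappedProportion <- function(m, totalAreaKm2, adjustedCropKm2) {
  n <- m@counts
  p1 <- n[1, 1] / sum(n[1, ]); p2 <- n[2, 1] / sum(n[2, ])
  Wc <- (adjustedCropKm2 / totalAreaKm2 - p2) / (p1 - p2)
  setNames(c(Wc, 1 - Wc), m@classes)
}

#' Build an area estimate from published numbers
#'
#' Wraps a reported adjusted area and CI half-width (e.g. values printed in a
#' report) as an \linkS4class{AreaEstimate} so interval arithmetic like
#' \code{\link{changeBounds}} can run on them directly.
#'
#' @param areaKm2 adjusted class area
#' @param halfWidthKm2 CI half-width
#' @param totalAreaKm2 total study area
#' @param class class name (complement labeled "other")
#' @param z confidence multiplier the half-width corresponds to
#' @return an \linkS4class{AreaEstimate}
#' @export
areaEstimate <- function(areaKm2, halfWidthKm2, totalAreaKm2,
                         class = "cropland", z = 1.96) {
  classes <- c(class, "other")
  a <- c(areaKm2, totalAreaKm2 - areaKm2)
  hw <- c(halfWidthKm2, halfWidthKm2)
  new("AreaEstimate", classes = classes, totalAreaKm2 = totalAreaKm2,
      W = setNames(rep(NA_real_, 2), classes),
      proportions = setNames(a / totalAreaKm2, classes),
      areaKm2 = setNames(a, classes), se = setNames(hw / (z * totalAreaKm2),
                                                    classes),
      z = z, halfWidthKm2 = setNames(hw, classes))
}

#' Confidence-interval change bounds between two area estimates
#'
#' Interval arithmetic on one class's estimates in two periods: the overlap of
#' the two confidence intervals, the maximum increase (upper bound of the
#' second minus lower bound of the first) and the maximum decrease (upper
#' bound of the first minus lower bound of the second), each floored at zero.
#'
#' @param e1,e2 \linkS4class{AreaEstimate} objects with equal total area
#' @param class class compared (default cropland)
#' @return a \linkS4class{ChangeBound}
#' @export
changeBounds <- function(e1, e2, class = "cropland") {
  if (abs(e1@totalAreaKm2 - e2@totalAreaKm2) > 1e-6)
    stop("area estimates refer to different total areas", call. = FALSE)
  a1 <- e1@areaKm2[class]; h1 <- e1@halfWidthKm2[class]
  a2 <- e2@areaKm2[class]; h2 <- e2@halfWidthKm2[class]
  lo1 <- a1 - h1; up1 <- a1 + h1; lo2 <- a2 - h2; up2 <- a2 + h2
  new("ChangeBound",
      from = c(areaKm2 = unname(a1), halfWidthKm2 = unname(h1)),
      to = c(areaKm2 = unname(a2), halfWidthKm2 = unname(h2)),
      overlapKm2 = max(0, min(up1, up2) - max(lo1, lo2)),
      maxIncreaseKm2 = max(0, up2 - lo1),
      maxDecreaseKm2 = max(0, up1 - lo2))
}

setMethod("show", "ChangeBound", function(object) {
  cat(sprintf("ChangeBound: %.0f (+-%.0f) -> %.0f (+-%.0f) km2; overlap %.0f, max increase %.0f, max decrease %.0f\n",
              object@from["areaKm2"], object@from["halfWidthKm2"],
              object@to["areaKm2"], object@to["halfWidthKm2"],
              object@overlapKm2, object@maxIncreaseKm2, object@maxDecreaseKm2))
})

#' Published reference validation data (Duhok winter-crop study)
#'
#' The four per-period error matrices (mapped x reference, classes
#' cropland/other) of the reference analysis, its published adjusted crop-area
#' estimates with 95 percent CI half-widths, and the study total area.
#'
#' @return list with errorMatrices (named list of \linkS4class{ErrorMatrix}),
#'   adjustedCropKm2, halfWidthKm2 (named numeric vectors) and totalAreaKm2
#' @export
duhokReference <- function() {
  list(
    errorMatrices = list(
      A = errorMatrix(matrix(c(30, 13, 16, 174), 2, byrow = TRUE)),
      B = errorMatrix(matrix(c(34, 7, 2, 184), 2, byrow = TRUE)),
      C = errorMatrix(matrix(c(36, 16, 7, 171), 2, byrow = TRUE)),
      D = errorMatrix(matrix(c(38, 8, 10, 174), 2, byrow = TRUE))),
    adjustedCropKm2 = c(A = 1200, B = 868, C = 1040, D = 1300),
    halfWidthKm2 = c(A = 263, B = 141, C = 216, D = 222),
    totalAreaKm2 = 6600)
}
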