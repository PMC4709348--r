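#' Create a BandStack
#'
#' @param bands named list of \linkS4class{RasterGrid} (roles among blue,
#'   green, red, nir)
#' @param acquisitionDate a \code{Date}, or a "YYYY-DDD" year/day-of-year string
#' @param season "spring" or "summer"; derived from the date when NULL
#'   (spring = March-June, summer = July-September)
#' @param period epoch id
#' @param valueKind one of "digital_number", "toa_reflectance",
#'   "surface_reflectance"
#' @param qa optional quality RasterGrid (nonzero = contaminated cell)
#' @param provenance correction provenance tag
#' @return a \linkS4class{BandStack}
#' @export
bandStack <- function(bands, acquisitionDate, season = NULL, period = "A",
                      valueKind = "surface_reflectance", qa = NULL,
                      provenance = "unspecified") {
  if (is.character(acquisitionDate)) acquisitionDate <- parseSceneDate(acquisitionDate)
  derived <- seasonFromDate(acquisitionDate)
  if (is.null(season)) {
    if (is.na(derived))
      stop("acquisition date falls outside the spring/summer windows; pass season explicitly",
           call. = FALSE)
    season <- derived
  } else if (!is.na(derived) && derived != season) {
    warning(sprintf("declared season '%s' disagrees with the %s date window",
                    season, format(acquisitionDate)), call. = FALSE)
  }
  new("BandStack", bands = bands, acquisitionDate = acquisitionDate,
      season = season, period = period, valueKind = valueKind, qa = qa,
      provenance = provenance)
}

#' @describeIn bandStack extract one band by role
#' @param x a BandStack
#' @param role band role, e.g. "red"
#' @export
getBand <- function(x, role) {
  if (!role %in% names(x@bands))
    stop(sprintf("band '%s' missing from stack", role), call. = FALSE)
  x@bands[[role]]
}

#' @describeIn bandStack band roles present
#' @export
bandRoles <- function(x) names(x@bands)

#' @describeIn bandStack season tag
#' @export
seasonOf <- function(x) x@season

#' @describeIn bandStack period id
#' @export
periodOf <- function(x) x@period

#' @describeIn bandStack value kind
#' @export
valueKind <- function(x) x@valueKind

#' @describeIn bandStack quality grid (or NULL)
#' @export
qaMask <- function(x) x@qa

setMethod("show", "BandStack", function(object) {
  cat(sprintf("BandStack: period %s, %s, %s [%s], bands: %s\n",
              object@period, format(object@acquisitionDate),
              object@season, object@valueKind,
              paste(names(object@bands), collapse = ", ")))
})

#' Parse a year/day-of-year scene date
#'
#' Scene catalogs encode acquisition dates as "YYYY-DDD" (calendar year and
#' Julian day of year).
#'
#' @param x character vector like "1984-158"
#' @return a \code{Date} vector
#' @export
parseSceneDate <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{1,3})$", x))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop(sprintf("malformed scene date(s): %s",
                 paste(x[bad], collapse = ", ")), call. = FALSE)
  year <- as.integer(vapply(m, `[`, character(1), 2))
  doy <- as.integer(vapply(m, `[`, character(1), 3))
  as.Date(doy - 1, origin = as.Date(sprintf("%d-01-01", year)))
}

#' Season implied by an acquisition date
#'
#' Pre-harvest spring is March-June, post-harvest summer July-September;
#' other months return NA.
#'
#' @param date a Date vector
#' @return character vector of "spring"/"summer"/NA
#' @export
seasonFromDate <- function(date) {
  mo <- as.integer(format(date, "%m"))
  out <- rep(NA_character_, length(date))
  out[mo >= 3 & mo <= 6] <- "spring"
  out[mo >= 7 & mo <= 9] <- "summer"
  out
}
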