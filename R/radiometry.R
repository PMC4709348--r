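#' Create calibration metadata
#'
#' @param gain,bias per-band radiance calibration (radiance = gain*DN + bias);
#'   named by band role, or length-1 to recycle
#' @param esun per-band exo-atmospheric solar irradiance
#' @param wavelength per-band effective wavelength, micrometers
#' @param solarZenith solar zenith angle, degrees
#' @param viewZenith view zenith angle, degrees (0 = nadir)
#' @param earthSunDistance earth-sun distance, astronomical units
#' @return a \linkS4class{CalibrationMeta}
#' @export
calibrationMeta <- function(gain, bias, esun, wavelength = NULL,
                            solarZenith, viewZenith = 0,
                            earthSunDistance = 1) {
  if (is.null(wavelength))
    wavelength <- setNames(rep(NA_real_, length(gain)), names(gain))
  new("CalibrationMeta", gain = gain, bias = bias, esun = esun,
      wavelength = wavelength, solarZenith = solarZenith,
      viewZenith = viewZenith, earthSunDistance = earthSunDistance)
}

bandMeta <- function(meta, slotName, role) {
  v <- slot(meta, slotName)
  if (length(v) == 1 && is.null(names(v))) return(unname(v))
  if (!role %in% names(v))
    stop(sprintf("calibration %s missing for band '%s'", slotName, role),
         call. = FALSE)
  unname(v[[role]])
}

#' Convert digital numbers to top-of-atmosphere reflectance
#'
#' Per band, at-sensor radiance L = gain*DN + bias and TOA reflectance
#' rho = pi * L * d^2 / (E_sun * cos(theta_z)).
#'
#' @param stack a \linkS4class{BandStack} with valueKind "digital_number"
#' @param meta a \linkS4class{CalibrationMeta}
#' @return the stack with reflectance values and valueKind "toa_reflectance"
#' @export
dnToToa <- function(stack, meta) {
  if (valueKind(stack) != "digital_number")
    stop("dnToToa expects a digital_number stack", call. = FALSE)
  cosz <- cos(meta@solarZenith * pi / 180)
  d2 <- meta@earthSunDistance^2
  bands <- lapply(names(stack@bands), function(role) {
    g <- bandMeta(meta, "gain", role); b <- bandMeta(meta, "bias", role)
    es <- bandMeta(meta, "esun", role)
    L <- g * stack@bands[[role]]@values + b
    withValues(stack@bands[[role]], pi * L * d2 / (es * cosz))
  })
  names(bands) <- names(stack@bands)
  initialize(stack, bands = bands, valueKind = "toa_reflectance",
             provenance = "toa")
}

#' Rayleigh optical thickness
#'
#' The standard analytic approximation used by image-based atmospheric
#' correction: tau(lambda) = 0.008569 lambda^-4 (1 + 0.0113 lambda^-2
#' + 0.00013 lambda^-4), lambda in micrometers.
#'
#' @param lambda wavelength in micrometers
#' @return Rayleigh optical thickness (dimensionless)
#' @export
rayleighTau <- function(lambda) {
  0.008569 * lambda^-4 * (1 + 0.0113 * lambda^-2 + 0.00013 * lambda^-4)
}

#' Dark-object-subtraction (DOS3) atmospheric correction
#'
#' Image-based correction assuming the scene's darkest objects have 1 percent
#' surface reflectance, with Rayleigh-only transmittances. Per band: the
#' dark-object radiance is the \code{darkFraction} quantile of positive
#' radiances; the path radiance is that radiance minus what a 1 percent
#' reflector would return through the Rayleigh atmosphere,
#' L_p = L_dark - 0.01 * (E_sun cos(theta_z) T_z) * T_v / (pi d^2);
#' surface reflectance is
#' rho = pi (L - L_p) d^2 / (T_v E_sun cos(theta_z) T_z),
#' with T_v = exp(-tau_r/cos(theta_v)), T_z = exp(-tau_r/cos(theta_z)).
#' Results are clipped to [0, 1]; the number of clipped cells is reported as
#' an attribute.
#'
#' @param stack a \linkS4class{BandStack} with valueKind "digital_number"
#' @param meta a \linkS4class{CalibrationMeta} (wavelengths required)
#' @param darkFraction quantile of positive radiances defining the dark
#'   object, in (0, 0.05]
#' @return corrected stack with valueKind "surface_reflectance" and
#'   provenance "dos_corrected"
#' @export
dosCorrect <- function(stack, meta, darkFraction = 0.01) {
  if (valueKind(stack) != "digital_number")
    stop("dosCorrect expects a digital_number stack", call. = FALSE)
  if (darkFraction <= 0 || darkFraction > 0.05)
    stop("darkFraction must be in (0, 0.05]", call. = FALSE)
  cosz <- cos(meta@solarZenith * pi / 180)
  cosv <- cos(meta@viewZenith * pi / 180)
  d2 <- meta@earthSunDistance^2
  nClipped <- 0L
  bands <- lapply(names(stack@bands), function(role) {
    g <- bandMeta(meta, "gain", role); b <- bandMeta(meta, "bias", role)
    es <- bandMeta(meta, "esun", role)
    lam <- bandMeta(meta, "wavelength", role)
    if (!is.finite(lam))
      stop(sprintf("wavelength required for DOS correction of band '%s'", role),
           call. = FALSE)
    L <- g * stack@bands[[role]]@values + b
    pos <- L[!is.na(L) & L > 0]
    if (!length(pos)) stop(sprintf("band '%s' has no positive radiance", role),
                           call. = FALSE)
    tau <- rayleighTau(lam)
    Tv <- exp(-tau / cosv); Tz <- exp(-tau / cosz)
    Ldark <- unname(quantile(pos, darkFraction, type = 7))
    Lp <- Ldark - 0.01 * (es * cosz * Tz) * Tv / (pi * d2)
    rho <- pi * (L - Lp) * d2 / (Tv * es * cosz * Tz)
    nClipped <<- nClipped + sum(rho < 0 | rho > 1, na.rm = TRUE)
    rho <- pmin(pmax(rho, 0), 1)
    withValues(stack@bands[[role]], rho)
  })
  names(bands) <- names(stack@bands)
  out <- initialize(stack, bands = bands, valueKind = "surface_reflectance",
                    provenance = "dos_corrected")
  attr(out, "nClipped") <- nClipped
  out
}

#' NDVI of a reflectance stack
#'
#' (NIR - Red)/(NIR + Red) per cell. Cells with a zero denominator or any
#' missing input are missing in the result.
#'
#' @param stack a \linkS4class{BandStack} holding red and nir bands (any
#'   reflectance kind)
#' @return a \linkS4class{RasterGrid} in [-1, 1]
#' @export
ndvi <- function(stack) {
  red <- getBand(stack, "red")@values
  nir <- getBand(stack, "nir")@values
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  withValues(getBand(stack, "red"), out)
}

#' Mean absolute NDVI difference between two corrections of one scene
#'
#' Used to compare an image-based correction (DOS) against a reference
#' surface-reflectance product over the same acquisition.
#'
#' @param a,b \linkS4class{BandStack} objects on the same geometry
#' @return mean of |NDVI_a - NDVI_b| over cells valid in both
#' @export
compareCorrections <- function(a, b) {
  stopIfGeometryMismatch(getBand(a, "red"), getBand(b, "red"),
                         "the two stacks")
  na <- ndvi(a)@values; nb <- ndvi(b)@values
  mean(abs(na - nb), na.rm = TRUE)
}
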