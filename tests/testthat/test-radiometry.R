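meta1 <- calibrationMeta(gain = c(red = 0.1, nir = 0.1),
                         bias = c(red = 0, nir = 0),
                         esun = c(red = 1000, nir = 1000),
                         wavelength = c(red = 0.66, nir = 0.84),
                         solarZenith = 30)

test_that("DN to TOA reflectance matches the closed form", {
  cosz <- cos(30 * pi / 180)
  # DN chosen so that L = Esun*cos/(pi*d^2) -> rho = 1
  dnOne <- 1000 * cosz / pi / 0.1
  st <- mkStack(red = matrix(dnOne, 2, 2), nir = matrix(0, 2, 2),
                valueKind = "digital_number")
  out <- dnToToa(st, meta1)
  expect_equal(gridValues(getBand(out, "red")), matrix(1, 2, 2))
  expect_equal(gridValues(getBand(out, "nir")), matrix(0, 2, 2))
  expect_equal(valueKind(out), "toa_reflectance")
  # independent arithmetic: gain 0.1, DN 50 -> L = 5; rho = pi*5/(1000*cos30)
  st2 <- mkStack(red = matrix(50, 1, 1), nir = matrix(50, 1, 1),
                 valueKind = "digital_number")
  out2 <- dnToToa(st2, meta1)
  expect_equal(gridValues(getBand(out2, "red"))[1, 1],
               pi * 5 / (1000 * cos(pi / 6)))
  # affine + monotone in DN
  st3 <- mkStack(red = matrix(c(10, 20, 30, 40), 2), nir = matrix(1, 2, 2),
                 valueKind = "digital_number")
  v <- as.vector(gridValues(getBand(dnToToa(st3, meta1), "red")))
  expect_true(all(diff(v) > 0))
  expect_equal(diff(v)[1], diff(v)[2])
  expect_error(dnToToa(mkStack(red = matrix(1, 1, 1)), meta1),
               "digital_number")
})

test_that("DOS reduces to transmittance-adjusted TOA when the scene is haze-free", {
  # darkest pixels already at the 1 percent reference radiance -> L_p ~ 0
  cosz <- cos(30 * pi / 180)
  tau <- rayleighTau(0.66)
  Tz <- exp(-tau / cosz); Tv <- exp(-tau)
  Lref <- 0.01 * (1000 * cosz * Tz) * Tv / pi
  dnDark <- Lref / 0.1
  m <- matrix(dnDark, 4, 4); m[4, 4] <- dnDark * 30
  st <- mkStack(red = m, nir = m, valueKind = "digital_number")
  out <- dosCorrect(st, meta1, darkFraction = 0.05)
  rho <- gridValues(getBand(out, "red"))
  expect_equal(rho[1, 1], 0.01, tolerance = 1e-10)
  expect_equal(rho[4, 4], pi * (dnDark * 30 * 0.1) / (Tv * 1000 * cosz * Tz),
               tolerance = 1e-10)
})

test_that("DOS recovers the haze-free reflectance from a hazy scene", {
  set.seed(11)
  cosz <- cos(30 * pi / 180)
  rho0 <- matrix(runif(400, 0.01, 0.6), 20, 20)
  rho0[1:2, 1:2] <- 0.01                  # genuine dark objects
  tau <- rayleighTau(0.66)
  Tz <- exp(-tau / cosz); Tv <- exp(-tau)
  L <- rho0 * (Tv * 1000 * cosz * Tz) / pi
  Lhaze <- 2.5                            # additive path radiance
  dn <- (L + Lhaze) / 0.1
  st <- mkStack(red = dn, nir = dn, valueKind = "digital_number")
  out <- dosCorrect(st, calibrationMeta(gain = 0.1, bias = 0, esun = 1000,
                                        wavelength = c(red = 0.66, nir = 0.66),
                                        solarZenith = 30),
                    darkFraction = 0.01)
  expect_lt(max(abs(gridValues(getBand(out, "red")) - rho0)), 0.01)
})

test_that("DOS output never exceeds plain TOA when path radiance is non-negative", {
  set.seed(12)
  dn <- matrix(runif(100, 100, 400), 10, 10)
  st <- mkStack(red = dn, nir = dn, valueKind = "digital_number")
  toa <- gridValues(getBand(dnToToa(st, meta1), "red"))
  dos <- gridValues(getBand(dosCorrect(st, meta1), "red"))
  expect_true(all(dos <= toa + 1e-12))
})

test_that("NDVI handles arithmetic, symmetry, degenerate and scaled inputs", {
  st <- mkStack(red = matrix(0.1, 1, 1), nir = matrix(0.5, 1, 1))
  expect_equal(gridValues(ndvi(st))[1, 1], 2 / 3, tolerance = 1e-12)
  st2 <- mkStack(red = matrix(0.3, 1, 1), nir = matrix(0.3, 1, 1))
  expect_equal(gridValues(ndvi(st2))[1, 1], 0)
  st3 <- mkStack(red = matrix(0, 1, 1), nir = matrix(0, 1, 1))
  expect_true(is.na(gridValues(ndvi(st3))[1, 1]))
  expect_error(ndvi(mkStack(red = matrix(1, 1, 1))), "nir")
  # invariant to positive rescaling of both bands
  set.seed(4)
  r <- matrix(runif(25, 0.05, 0.5), 5); n <- matrix(runif(25, 0.05, 0.6), 5)
  a <- gridValues(ndvi(mkStack(red = r, nir = n)))
  b <- gridValues(ndvi(mkStack(red = 3.7 * r, nir = 3.7 * n)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("correction comparison returns the cell-wise mean absolute NDVI gap", {
  set.seed(5)
  r <- matrix(runif(36, 0.05, 0.4), 6); n <- matrix(runif(36, 0.1, 0.6), 6)
  a <- mkStack(red = r, nir = n)
  expect_equal(compareCorrections(a, a), 0)
  # constructed uniform NDVI shift of +0.05
  v <- gridValues(ndvi(a))
  b <- ndviStack(v + 0.05)
  expect_equal(compareCorrections(a, b), 0.05, tolerance = 1e-10)
  # brute-force oracle on an arbitrary pair
  r2 <- matrix(runif(36, 0.05, 0.4), 6); n2 <- matrix(runif(36, 0.1, 0.6), 6)
  b2 <- mkStack(red = r2, nir = n2)
  manual <- mean(abs(gridValues(ndvi(a)) - gridValues(ndvi(b2))))
  expect_equal(compareCorrections(a, b2), manual)
  expect_error(compareCorrections(a, mkStack(red = matrix(1, 2, 2),
                                             nir = matrix(1, 2, 2))),
               "geometry")
})
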