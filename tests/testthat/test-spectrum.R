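test_that("constant maps have an all-zero spectrum outside DC", {
  sp <- amplitudeSpectrum(surfaceMap(matrix(5, 64, 64), 20))
  expect_lt(max(amplitude2d(sp)), 1e-12)
  expect_true(is.na(sTdi(sp)))
  expect_true(is.na(sRwi(sp)))
  expect_true(is.na(sHw(sp)))
})

test_that("a single cosine concentrates at its radius and angle", {
  m <- 256
  sp <- amplitudeSpectrum(cosineMap(m, cycles = 8))
  amp <- amplitude2d(sp)
  centre <- m / 2 + 1
  ## two off-DC peaks at radius 8 on the kx axis
  expect_equal(amp[centre, centre + 8], 0.5, tolerance = 1e-9)
  expect_equal(amp[centre, centre - 8], 0.5, tolerance = 1e-9)
  others <- amp
  others[centre, c(centre + 8, centre - 8)] <- 0
  expect_lt(max(others), 1e-9)
  ## the radial spectrum concentrates in bin 8
  b <- radialAmplitudes(sp)
  expect_gt(b[8] / sum(b), 0.999)
  ## the wave-vector direction is the angle-zero line
  expect_equal(which.max(angularAmplitudes(sp)), 1L)
})

test_that("the modulus spectrum is invariant under circular shifts", {
  v <- mapValues(generateSurface(surfaceConfig(gridSize = 64L), seed = 2))
  sp1 <- amplitudeSpectrum(surfaceMap(v, 20))
  shifted <- v[c(21:64, 1:20), c(51:64, 1:50)]
  sp2 <- amplitudeSpectrum(surfaceMap(shifted, 20))
  expect_equal(amplitude2d(sp2), amplitude2d(sp1), tolerance = 1e-9)
})

test_that("sector binning matches the brute-force per-pixel oracle", {
  for (s in 1:3) {
    set.seed(s)
    v <- matrix(rnorm(32 * 32), 32)
    sp <- amplitudeSpectrum(surfaceMap(v, 20))
    amp <- amplitude2d(sp)
    expect_equal(angularSpectrum(sp, nLines = 32, method = "sector",
                                 normalized = FALSE),
                 bruteAngular(amp, 32), tolerance = 1e-12)
    expect_equal(radialSpectrum(sp), bruteRadial(amp), tolerance = 1e-12)
  }
})

test_that("radial sums conserve the binned half-plane amplitude", {
  sp <- amplitudeSpectrum(generateSurface(surfaceConfig(gridSize = 64L),
                                          seed = 4))
  amp <- amplitude2d(sp)
  m <- 64L; centre <- 33L
  kx <- matrix(rep(seq_len(m) - centre, each = m), m)
  ky <- matrix(rep(seq_len(m) - centre, times = m), m)
  half <- (ky > 0) | (ky == 0 & kx > 0)
  r <- round(sqrt(kx^2 + ky^2))
  kept <- half & r >= 1 & r <= m / 2 - 1
  expect_equal(sum(radialAmplitudes(sp)), sum(amp[kept]),
               tolerance = 1e-12)
  ## the discarded corners hold only a modest share
  expect_gt(sum(amp[kept]) / sum(amp[half]), 0.7)
})

test_that("Stdi reads direction dominance from the angular spectrum", {
  ## uniform angular spectrum: no dominant direction
  sp <- amplitudeSpectrum(surfaceMap(matrix(rnorm(64^2), 64), 20))
  sp@angular <- rep(2, 64)
  expect_equal(sTdi(sp), 1)
  ## a single nonzero line: maximal dominance
  sp@angular <- c(5, rep(0, 63))
  expect_equal(sTdi(sp), 1 / 64)
  ## a strongly striped surface scores near zero
  stripes <- cosineMap(128, cycles = 6)
  expect_lt(sTdi(amplitudeSpectrum(stripes)), 0.15)
  ## isotropic white noise scores near one
  set.seed(9)
  iso <- mean(sapply(1:5, function(i)
    sTdi(amplitudeSpectrum(matrix(rnorm(128^2), 128), pixelPitch = 20))))
  expect_gt(iso, 0.8)
})

test_that("Srwi reads wavelength dominance from the radial profile", {
  sp <- amplitudeSpectrum(surfaceMap(matrix(rnorm(64^2), 64), 20))
  sp@radial <- rep(3, 31); sp@radialCounts <- rep(1, 31)
  expect_equal(sRwi(sp), 1)
  ## pure single wavelength: close to zero
  pure <- sRwi(amplitudeSpectrum(cosineMap(128, cycles = 8)))
  expect_lt(pure, 5 / 63)
  ## white noise: flat profile, near one
  set.seed(10)
  wn <- mean(sapply(1:10, function(i)
    sRwi(amplitudeSpectrum(matrix(rnorm(128^2), 128), pixelPitch = 20))))
  expect_gt(wn, 0.6)
})

test_that("Shw equals half the wavelength of a pure sinusoid", {
  ## exact concentration: 5 cycles on a 256 grid (wavelength 1024 nm);
  ## the cumulative profile steps at r = 5, so the interpolated r0.5 is
  ## 4.5 exactly and Shw = 20 * 255 / 9
  spx <- amplitudeSpectrum(cosineMap(256, cycles = 5))
  expect_equal(sHw(spx), 20 * 255 / 9, tolerance = 1e-9)
  ## within one radial bin of interpolation, that is half the wavelength
  expect_equal(sHw(spx), 1024 / 2, tolerance = 0.15)

  ## 1000 nm wavelength (5.12 cycles): spectral leakage of the
  ## non-integer cycle count widens the band a little further
  m <- 256
  x <- matrix(rep(0:(m - 1), each = m), m)
  v <- cos(2 * pi * x * 20 / 1000)
  sp <- amplitudeSpectrum(surfaceMap(v, 20))
  expect_equal(sHw(sp), 500, tolerance = 0.25)
  ## amplitude invariance
  sp10 <- amplitudeSpectrum(surfaceMap(10 * v, 20))
  expect_equal(sHw(sp10), sHw(sp), tolerance = 1e-12)
  ## the halfFactor switch removes the factor two
  expect_equal(sHw(sp, halfFactor = FALSE), 2 * sHw(sp),
               tolerance = 1e-12)
})

test_that("the cumulative radial spectrum halves at the interpolated
          radius", {
  sp <- amplitudeSpectrum(generateSurface(surfaceConfig(gridSize = 128L,
                                                        activationLevel = 0.5),
                                          seed = 6))
  hp <- halfPowerRadius(sp)
  expect_equal(hp$fraction, 0.5, tolerance = 1e-9)
})

test_that("smaller grains give a smaller average half wavelength", {
  pairs <- sapply(1:20, function(s) {
    big <- generateSurface(surfaceConfig(activationLevel = 1,
                                         grainRadius = 70), seed = s)
    small <- generateSurface(surfaceConfig(activationLevel = 1,
                                           grainRadius = 45), seed = s)
    c(sHw(amplitudeSpectrum(big)), sHw(amplitudeSpectrum(small)))
  })
  expect_gt(mean(pairs[1, ] - pairs[2, ]), 0)
  expect_gt(mean(pairs[1, ] > pairs[2, ]), 0.8)
})

test_that("rotation behaves correctly for both surface types", {
  ## isotropic surface: Stdi within 5% under a 90-degree rotation
  set.seed(11)
  v <- matrix(rnorm(128^2), 128)
  a <- sTdi(amplitudeSpectrum(v, pixelPitch = 20))
  b <- sTdi(amplitudeSpectrum(t(v)[128:1, ], pixelPitch = 20))
  expect_equal(a, b, tolerance = 0.05)
  ## anisotropic surface: the dominant angle rotates by 90 degrees
  stripes <- mapValues(cosineMap(128, cycles = 6))
  aAng <- which.max(angularAmplitudes(amplitudeSpectrum(stripes,
                                                        pixelPitch = 20)))
  bAng <- which.max(angularAmplitudes(amplitudeSpectrum(t(stripes),
                                                        pixelPitch = 20)))
  shift <- abs(aAng - bAng) * 180 / 128
  expect_equal(min(shift, 180 - shift), 90, tolerance = 0.1)
})

test_that("Stdi and Srwi stay inside (0, 1] across mixed surface types", {
  seeds <- 1:60
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  anis <- c(0, 0.5, 1)
  for (s in seeds) {
    cfg <- surfaceConfig(gridSize = 64L,
                         activationLevel = levels[s %% 5 + 1],
                         foldAnisotropy = anis[s %% 3 + 1])
    sp <- amplitudeSpectrum(generateSurface(cfg, seed = s))
    expect_gt(sTdi(sp), 0); expect_lte(sTdi(sp), 1)
    expect_gt(sRwi(sp), 0); expect_lte(sRwi(sp), 1)
  }
})
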