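test_that("plane-tilt removal recovers structure under a plane exactly", {
  m <- 64L
  x <- matrix(rep(0:(m - 1), each = m), m)   # column coordinate
  y <- matrix(rep(0:(m - 1), times = m), m)  # row coordinate
  plane <- 3 + 0.02 * x + 0.05 * y
  flat <- removePlaneTilt(surfaceMap(plane, 20))
  expect_lt(max(abs(mapValues(flat))), 1e-9)

  ## half-pixel-offset cosine over whole periods: exactly orthogonal to
  ## the constant and both plane gradients on the discrete grid
  wave <- cos(2 * pi * 4 * (x + 0.5) / m)
  both <- removePlaneTilt(surfaceMap(wave + plane, 20))
  expect_equal(mapValues(both), wave - mean(wave), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mean(mapValues(both)), 0, tolerance = 1e-12)
})

test_that("plane-tilt removal is idempotent and spectrum-preserving", {
  m1 <- removePlaneTilt(generateSurface(surfaceConfig(gridSize = 64L),
                                        seed = 1))
  m2 <- removePlaneTilt(m1)
  expect_equal(mapValues(m2), mapValues(m1), tolerance = 1e-9)
  s1 <- amplitudeSpectrum(m1); s2 <- amplitudeSpectrum(m2)
  expect_equal(sTdi(s2), sTdi(s1), tolerance = 1e-9)
  expect_equal(sRwi(s2), sRwi(s1), tolerance = 1e-9)
  expect_equal(sHw(s2), sHw(s1), tolerance = 1e-9)
})

test_that("artifact screening scores what it should", {
  clean <- generateSurface(surfaceConfig(gridSize = 64L), seed = 5)
  expect_true(screenMap(clean)@passed)

  ## one scan line offset by 10x the RMS fails the line-artifact score
  v <- mapValues(clean)
  v[20, ] <- v[20, ] + 10 * afmring:::rmsAboutMean(v)
  bad <- screenMap(surfaceMap(v, 20))
  expect_false(bad@passed)
  expect_gte(bad@lineArtifactScore, 1)

  ## 5% spike pixels fail the spike fraction
  v2 <- mapValues(clean)
  idx <- seq(1, length(v2), length.out = round(0.05 * length(v2)))
  v2[idx] <- v2[idx] + 30 * stats::mad(v2)
  bad2 <- screenMap(surfaceMap(v2, 20))
  expect_false(bad2@passed)
  expect_gt(bad2@spikeFraction, 0.01)

  ## clipping to the range maximum fails the saturation fraction
  v3 <- mapValues(clean)
  v3[v3 > stats::quantile(v3, 0.995)] <- stats::quantile(v3, 0.995)
  bad3 <- screenMap(surfaceMap(v3, 20))
  expect_gt(bad3@saturationFraction, 0.001)
})

test_that("cropping preserves the pitch and respects bounds", {
  big <- generateSurface(surfaceConfig(gridSize = 128L), seed = 1)
  crop <- cropRegion(big, center = c(64, 64), size = 64)
  expect_equal(dim(crop), c(64L, 64L))
  expect_equal(pixelPitch(crop), pixelPitch(big))
  ## identity crop
  all_ <- cropRegion(big, center = c(64, 64), size = 128)
  expect_equal(mapValues(all_), mapValues(big))
  expect_error(cropRegion(big, center = c(10, 10), size = 64), "bounds")
})
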