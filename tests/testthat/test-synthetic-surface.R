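test_that("surface RMS is pinned to the target for every level and seed", {
  for (a in c(0, 0.3, 0.7, 1)) {
    for (s in c(1, 2)) {
      cfg <- surfaceConfig(gridSize = 64L, activationLevel = a,
                           targetRms = 0.35)
      m <- generateSurface(cfg, seed = s)
      expect_equal(dim(m), c(64L, 64L))
      expect_lt(abs(afmring:::rmsAboutMean(mapValues(m)) / 0.35 - 1), 1e-6)
    }
  }
})

test_that("unresolvable grains and bad levels are rejected", {
  expect_error(surfaceConfig(grainRadius = 10), "unresolvable")
  expect_error(surfaceConfig(activationLevel = 1.2), "activationLevel")
  expect_error(surfaceConfig(gridSize = 63L), "even")
})

test_that("a resting-cell surface is oriented and quasi-periodic, an
          activated one is not", {
  cfg0 <- surfaceConfig(activationLevel = 0, noiseSd = 0)
  m0 <- generateSurface(cfg0, seed = 3)
  sp0 <- amplitudeSpectrum(m0)
  expect_lt(sTdi(sp0), 0.6)          # dominant direction present
  expect_lt(sRwi(sp0), 0.35)         # dominant wavelength present

  ## paired comparison at the same seed: full activation raises both
  m1 <- generateSurface(surfaceConfig(activationLevel = 1, noiseSd = 0),
                        seed = 3)
  sp1 <- amplitudeSpectrum(m1)
  expect_gt(sTdi(sp1), sTdi(sp0))
  expect_gt(sRwi(sp1), sRwi(sp0))
})

test_that("mean grain count increases with the activation level", {
  counts <- sapply(c(0.2, 0.5, 0.8, 1), function(a) {
    mean(sapply(1:8, function(s) {
      m <- generateSurface(surfaceConfig(gridSize = 64L,
                                         activationLevel = a), seed = s)
      groundTruth(m)$nGrains
    }))
  })
  expect_true(all(diff(counts) > 0))
})

test_that("the saturating level curve matches its closed form", {
  expect_identical(activationLevel(0), 0)
  expect_equal(activationLevel(30, tau = 10), 1 - exp(-3))
  expect_equal(levelToMinutes(activationLevel(17.5)), 17.5)
})

test_that("activation series have the study layout", {
  ser <- generateActivationSeries(times = c(5, 30), nCells = 3,
                                  base = surfaceConfig(gridSize = 64L),
                                  seed = 2, channels = "restored adhesion")
  man <- seriesManifest(ser)
  expect_setequal(unique(man$group), c("CTR 0m", "CTR 120m", "ACT 5m",
                                       "ACT 30m"))
  expect_equal(nrow(man), 4 * 3)
  expect_true(all(man$activationLevel[grepl("CTR", man$group)] == 0))
  expect_true(all(man$activationLevel[man$group == "ACT 30m"] > 0.8))
  ## determinism: identical seed reproduces identical maps
  ser2 <- generateActivationSeries(times = c(5, 30), nCells = 3,
                                   base = surfaceConfig(gridSize = 64L),
                                   seed = 2, channels = "restored adhesion")
  expect_identical(mapValues(seriesMaps(ser)[[1]]),
                   mapValues(seriesMaps(ser2)[[1]]))
  expect_error(generateActivationSeries(times = numeric(0)), "non-empty")
  expect_error(generateActivationSeries(nCells = 2), "nCells")
})
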