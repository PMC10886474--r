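cfgR <- ringingConfig()

test_that("cycle segmentation recovers the generator's phase boundaries", {
  tr <- generateForceCurve(cfgR, contactScenario(), seed = 1)
  truth <- groundTruth(tr)
  seg <- segmentCycle(tr)
  expect_false(seg$noContact)
  expect_lte(abs(seg$segments$loading[1] - truth$segments$loading[1]), 2)
  expect_lte(abs(seg$segments$loading[2] - truth$segments$loading[2]), 2)
  expect_lte(abs(seg$detachmentIndex - truth$detachmentIndex), 2)
})

test_that("a pure baseline trace is flagged no-contact", {
  tr <- forceTrace(seq(0, 1e-3, length.out = 2048), rep(0, 2048))
  seg <- segmentCycle(tr)
  expect_true(seg$noContact)
  expect_true(is.na(adhesionMinimum(tr, seg)))
})

test_that("zero-adhesion cycles have D at the baseline crossing and no
          ringing", {
  tr <- generateForceCurve(cfgR, contactScenario(adhesionForce = 0,
                                                 restoredForce = 0),
                           seed = 1)
  seg <- segmentCycle(tr)
  expect_false(seg$noContact)
  expect_length(seg$segments$ringing, 0)
  expect_equal(adhesionMinimum(tr, seg), 0, tolerance = 1e-9)
})

test_that("the adhesion minimum matches the well depth and is noise-biased", {
  tr <- generateForceCurve(cfgR, contactScenario(adhesionForce = 2,
                                                 restoredForce = 1.5),
                           seed = 1)
  expect_equal(adhesionMinimum(tr), 2, tolerance = 1e-9)
  ## single-point minimum is biased high by the order of the noise sd
  bias <- mean(sapply(1:25, function(s) {
    trn <- generateForceCurve(cfgR, contactScenario(noiseSd = 0.1),
                              seed = s)
    adhesionMinimum(trn) - 2
  }))
  expect_gt(bias, 0.05)
  expect_lt(bias, 0.5)
})

test_that("the damped-oscillator fit recovers the restored adhesion", {
  tr <- generateForceCurve(cfgR, contactScenario(adhesionForce = 2,
                                                 restoredForce = 1.5),
                           seed = 1)
  fit <- restoredAdhesionFit(tr, cfgR)
  expect_false(fit$unreliable)
  expect_equal(fit$restoredAdhesion, 1.5, tolerance = 0.01)
  expect_equal(fit$frequency, 75e3, tolerance = 0.01)
})

test_that("the fit is invariant to a time-origin shift", {
  tr <- generateForceCurve(cfgR, contactScenario(), seed = 2)
  shifted <- forceTrace(traceTime(tr) + 0.0123, traceForce(tr))
  a <- restoredAdhesionFit(tr, cfgR)$restoredAdhesion
  b <- restoredAdhesionFit(shifted, cfgR)$restoredAdhesion
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("a ringing segment of about one period is flagged unreliable", {
  tr <- generateForceCurve(cfgR, contactScenario(), seed = 1)
  truth <- groundTruth(tr)
  cut <- truth$detachmentIndex + round(1.2 * 2e6 / 75e3)
  short <- forceTrace(traceTime(tr)[1:cut], traceForce(tr)[1:cut])
  fit <- restoredAdhesionFit(short, cfgR)
  expect_true(fit$unreliable)
  expect_true(is.na(fit$restoredAdhesion))
})

test_that("fit error shrinks roughly as one over the square root of the
          ringing length", {
  sc <- contactScenario(adhesionForce = 3, restoredForce = 1.5,
                        noiseSd = 0.1)
  rmseAt <- function(periods) {
    errs <- sapply(1:15, function(s) {
      tr <- generateForceCurve(cfgR, sc, seed = s)
      truth <- groundTruth(tr)
      cut <- truth$detachmentIndex + round(periods * 2e6 / 75e3)
      short <- forceTrace(traceTime(tr)[1:cut], traceForce(tr)[1:cut])
      restoredAdhesionFit(short, cfgR)$restoredAdhesion - 1.5
    })
    sqrt(mean(errs^2))
  }
  r <- c(rmseAt(8), rmseAt(16), rmseAt(32))
  expect_true(all(diff(r) < 0))
  ## 1/sqrt(n) predicts a factor 2 between the shortest and longest
  expect_gt(r[1] / r[3], 1.3)
  expect_lt(r[1] / r[3], 3.5)
})

test_that("viscoelastic adhesion is the clamped difference", {
  expect_equal(viscoelasticAdhesion(2, 1.5), 0.5)
  expect_equal(viscoelasticAdhesion(2, 2), 0)
  clampCount(reset = TRUE)
  expect_equal(viscoelasticAdhesion(2, 2.05), 0)
  expect_identical(clampCount(), 1L)
})

test_that("grids assemble into per-channel maps with QC infill", {
  pattern <- matrix(seq(1.5, 2.5, length.out = 16), 4, 4)
  grid <- simulateForceGrid(pattern, cfgR, seed = 7)
  ## an even square grid is required
  expect_error(processGrid(grid[, 1:3, drop = FALSE], cfgR), "square")
  res <- processGrid(grid, cfgR)
  expect_setequal(names(res$maps),
                  c("height", "adhesion", "restored adhesion",
                    "viscoelastic adhesion", "max load", "deformation"))
  expect_false(any(res$qcMask))
  expect_equal(mapValues(res$maps[["adhesion"]]), unname(pattern),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(mapValues(res$maps[["restored adhesion"]]),
               unname(0.75 * pattern), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("flagged pixels are masked and median-filled", {
  pattern <- matrix(2, 4, 4)
  grid <- simulateForceGrid(pattern, cfgR, seed = 8)
  ## truncate one pixel's ringing to make it unreliable
  tr <- grid[[2, 2]]
  cut <- groundTruth(tr)$detachmentIndex + round(1.2 * 2e6 / 75e3)
  grid[[2, 2]] <- forceTrace(traceTime(tr)[1:cut], traceForce(tr)[1:cut])
  res <- processGrid(grid, cfgR)
  expect_true(res$qcMask[2, 2])
  expect_equal(sum(res$qcMask), 1)
  ## the flagged pixel is filled from its neighbours
  expect_equal(mapValues(res$maps[["restored adhesion"]])[2, 2], 1.5,
               tolerance = 0.02)
})

test_that("an all-baseline grid is fully flagged", {
  flat <- forceTrace(seq(0, 1e-3, length.out = 1024), rep(0, 1024))
  grid <- vector("list", 4); dim(grid) <- c(2, 2)
  for (i in 1:4) grid[[i]] <- flat
  res <- processGrid(grid, cfgR)
  expect_true(all(res$qcMask))
})
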