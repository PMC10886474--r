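test_that("force cycles carry the configured adhesion well and ringing", {
  cfg <- ringingConfig()
  sc <- contactScenario(adhesionForce = 2, restoredForce = 1.5)
  tr <- generateForceCurve(cfg, sc, seed = 1)
  f <- traceForce(tr)
  truth <- groundTruth(tr)

  expect_equal(max(f), sc@maxLoad, tolerance = 1e-12)
  expect_equal(min(f), -sc@adhesionForce, tolerance = 1e-12)
  ## force at the first ringing sample is close to -restoredForce
  i0 <- truth$segments$ringing[1]
  expect_lt(abs(f[i0] + sc@restoredForce), 0.05 * sc@restoredForce)
  ## the ringing PSD peaks at the configured resonance within one bin
  idx <- truth$segments$ringing[1]:truth$segments$ringing[2]
  y <- f[idx] - mean(f[idx])
  n <- length(y)
  spec <- Mod(stats::fft(y))[1:(n %/% 2)]
  fPeak <- (which.max(spec) - 1) * cfg@samplingRate / n
  expect_lt(abs(fPeak - cfg@resonanceFreq), cfg@samplingRate / n)
})

test_that("log ringing envelope decays with slope -pi*f0/Q", {
  cfg <- ringingConfig()
  tr <- generateForceCurve(cfg, contactScenario(), seed = 1)
  truth <- groundTruth(tr)
  idx <- truth$segments$ringing[1]:truth$segments$ringing[2]
  y <- traceForce(tr)[idx]
  tt <- traceTime(tr)[idx]
  pk <- which(diff(sign(diff(abs(y)))) < 0) + 1L
  pk <- pk[abs(y[pk]) > 0.05 * max(abs(y))]
  fit <- stats::lm(log(abs(y[pk])) ~ tt[pk])
  slope <- unname(stats::coef(fit)[2])
  expect_equal(slope, -pi * cfg@resonanceFreq / cfg@qualityFactor,
               tolerance = 0.05)
})

test_that("a cycle without adhesion returns monotonically with no ringing", {
  cfg <- ringingConfig()
  tr <- generateForceCurve(cfg, contactScenario(adhesionForce = 0,
                                                restoredForce = 0),
                           seed = 1)
  f <- traceForce(tr)
  truth <- groundTruth(tr)
  expect_gte(min(f), -1e-12)
  ## after the maximum the force never rises again (no ringing)
  post <- f[which.max(f):length(f)]
  expect_true(all(diff(post) <= 1e-12))
})

test_that("undersampled configurations are rejected", {
  expect_error(ringingConfig(samplingRate = 5e5, resonanceFreq = 75e3),
               "resolvable")
  expect_error(contactScenario(adhesionForce = 1, restoredForce = 1.5),
               "restoredForce")
})

test_that("thermal traces obey equipartition and its scaling law", {
  cfg <- ringingConfig()
  th <- generateThermalTrace(cfg, 295, duration = 0.5, seed = 1)
  expect_identical(th@channel, "deflection")
  v <- stats::var(traceForce(th))
  kB <- 1.380649e-23
  expect_equal(v, kB * 295 / 0.4 * 1e18, tolerance = 0.05)

  ## doubling the spring constant halves the variance
  th2 <- generateThermalTrace(ringingConfig(springConstant = 0.8), 295,
                              duration = 0.5, seed = 1)
  expect_equal(stats::var(traceForce(th2)) / v, 0.5, tolerance = 0.1)
})

test_that("degenerate thermal-trace inputs are handled", {
  cfg <- ringingConfig()
  z <- generateThermalTrace(cfg, 0, duration = 0.05, seed = 1)
  expect_true(all(traceForce(z) == 0))
  expect_error(generateThermalTrace(cfg, -1, duration = 0.05), "temperature")
  expect_error(generateThermalTrace(cfg, 295, duration = 1e-3), "2\\^16")
})
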