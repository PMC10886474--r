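test_that("the suite emits exactly the 37 registry parameters", {
  p <- parameterSuite(generateSurface(surfaceConfig(gridSize = 64L),
                                      seed = 1))
  expect_length(p, 37)
  expect_identical(names(p), parameterNames())
  expect_length(unique(names(p)), 37)
  fams <- parameterNames(byFamily = TRUE)
  expect_identical(lengths(fams), c(amplitude = 9L, spatial = 9L,
                                    hybrid = 7L, functional = 12L))
})

test_that("a constant map yields zero amplitudes and NA shape moments", {
  p <- parameterSuite(surfaceMap(matrix(2, 64, 64), 20))
  expect_equal(unname(p["Sa"]), 0)
  expect_equal(unname(p["Sq"]), 0)
  expect_true(is.na(p["Ssk"]))
  expect_true(is.na(p["Sku"]))
  expect_true(is.na(p["Stdi"]))
})

test_that("maps with non-finite pixels are rejected", {
  v <- matrix(1, 64, 64)
  m <- surfaceMap(v, 20)
  m@values[3, 3] <- NaN   # bypass the constructor validity on purpose
  expect_error(parameterSuite(m), "non-finite")
})

test_that("Gaussian white noise has the normal shape moments", {
  mom <- sapply(1:50, function(s) {
    set.seed(s)
    p <- parameterSuite(surfaceMap(matrix(rnorm(64^2), 64), 20))
    p[c("Ssk", "Sku")]
  })
  expect_equal(mean(mom["Ssk", ]), 0, tolerance = 0.02)
  expect_equal(mean(mom["Sku", ]), 3, tolerance = 0.05)
})

test_that("basic amplitude inequalities hold", {
  for (s in 1:5) {
    p <- parameterSuite(generateSurface(
      surfaceConfig(gridSize = 64L, activationLevel = 0.5), seed = s))
    expect_gte(p[["Sq"]], p[["Sa"]])
    expect_gte(p[["Sa"]], 0)
    expect_equal(p[["Sz"]], p[["Sp"]] + p[["Sv"]], tolerance = 1e-12)
    expect_gt(p[["Stdi"]], 0); expect_lte(p[["Stdi"]], 1)
    expect_gt(p[["Srwi"]], 0); expect_lte(p[["Srwi"]], 1)
    expect_gt(p[["Shw"]], 0)
  }
})

test_that("spatial parameters ignore translation and offsets", {
  v <- mapValues(generateSurface(surfaceConfig(gridSize = 64L,
                                               activationLevel = 0.5),
                                 seed = 3))
  spatial <- parameterNames(byFamily = TRUE)$spatial
  p0 <- parameterSuite(surfaceMap(v, 20))[spatial]
  pShift <- parameterSuite(surfaceMap(v[c(30:64, 1:29), c(9:64, 1:8)],
                                      20))[spatial]
  pOffset <- parameterSuite(surfaceMap(v + 17, 20))[spatial]
  expect_equal(pShift, p0, tolerance = 1e-9)
  expect_equal(pOffset, p0, tolerance = 1e-9)
})

test_that("the bearing-curve family is internally consistent", {
  p <- parameterSuite(generateSurface(surfaceConfig(gridSize = 64L),
                                      seed = 4))
  expect_gt(p[["Sk"]], 0)
  expect_gte(p[["Spk"]], 0)
  expect_gte(p[["Svk"]], 0)
  expect_true(p[["Smr1"]] >= 0 && p[["Smr1"]] <= 100)
  expect_true(p[["Smr2"]] >= 0 && p[["Smr2"]] <= 100)
  expect_lt(p[["Smr1"]], p[["Smr2"]])
  ## height differences between bearing fractions are non-negative and
  ## ordered with the curve
  expect_gte(p[["Sdc0-5"]], 0)
  expect_gte(p[["Sdc5-10"]], 0)
  expect_gte(p[["Sdc10-50"]], 0)
  expect_gte(p[["Sdc50-95"]], 0)
})
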