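test_that("series summaries have the expected layout", {
  se <- cachedSeriesSE()
  tab <- summarizeSeries(se)
  expect_equal(nrow(tab), 7 * 3 * 37)
  expect_setequal(unique(tab$channel),
                  c("height", "restored adhesion",
                    "viscoelastic adhesion"))
  expect_true(all(tab$n == 20))
  ## projected area is identical for every map, so its sd is zero
  s2a <- tab[tab$parameter == "S2A", ]
  expect_true(all(s2a$sd == 0))
})

test_that("Shw falls from control to activation and stays down", {
  se <- cachedSeriesSE()
  tab <- summarizeSeries(se)
  shw <- tab[tab$parameter == "Shw" &
               tab$channel == "restored adhesion", ]
  actMin <- rep(-1, nrow(shw))
  isAct <- grepl("^ACT", shw$group)
  actMin[isAct] <- as.numeric(sub("ACT (\\d+)m", "\\1", shw$group[isAct]))
  ord <- order(!grepl("CTR", shw$group), shw$group != "CTR 0m", actMin)
  mu <- shw$mean[ord]
  sem <- (shw$sd / sqrt(shw$n))[ord]
  ## controls sit highest; each activated group is well below control
  expect_true(all(mu[3:7] < mu[1] - 3 * sem[1]))
  ## no activated group rises meaningfully above its predecessor
  expect_true(all(diff(mu[3:7]) < 2 * sqrt(sem[3:7]^2 + sem[2:6]^2)[-1]))
})

test_that("the correlation screen reports signed, gated trends", {
  se <- cachedSeriesSE()
  sc <- screenCorrelation(se)
  expect_setequal(names(sc)[1:4], c("parameter", "channel", "rho",
                                    "pValue"))
  rest <- sc[sc$channel == "restored adhesion", ]
  get <- function(p) rest[rest$parameter == p, ]
  expect_lt(get("Shw")$rho, 0)
  expect_gt(get("Srwi")$rho, 0)
  expect_gt(get("Stdi")$rho, 0)
  ## constant parameters are excluded with a note
  expect_match(get("S2A")$note, "constant")
  expect_false(get("S2A")$selected)
  ## the held-flat height channel shows no strong trio trends
  hgt <- sc[sc$channel == "height" &
              sc$parameter %in% c("Stdi", "Srwi", "Shw"), ]
  expect_true(all(!hgt$selected))
})

test_that("control stability gates behave on toy data", {
  withr::with_seed(1, {
    se <- toySE(c(rnorm(8, 10, 1), rnorm(8, 10, 1)),
                rep(c("CTR 0m", "CTR 120m"), each = 8),
                rep(c(0, 120), each = 8))
    st <- controlStability(se, "Sq", "restored adhesion")
    expect_true(st$evaluable)
    expect_true(st$stable)
    ## a three-pooled-sd shift is unstable
    se2 <- toySE(c(rnorm(8, 10, 1), rnorm(8, 13, 1)),
                 rep(c("CTR 0m", "CTR 120m"), each = 8),
                 rep(c(0, 120), each = 8))
    st2 <- controlStability(se2, "Sq", "restored adhesion")
    expect_false(st2$stable)
    ## two cells per group cannot be evaluated
    se3 <- toySE(rnorm(4, 10, 1), rep(c("CTR 0m", "CTR 120m"), each = 2),
                 rep(c(0, 120), each = 2))
    expect_false(controlStability(se3, "Sq",
                                  "restored adhesion")$evaluable)
  })
})

test_that("the screen is invariant under monotone rescaling", {
  se <- cachedSeriesSE()
  sc1 <- screenCorrelation(se)
  se2 <- se
  a <- SummarizedExperiment::assay(se2, "parameters")
  a["Shw", ] <- exp(a["Shw", ] / 100)   # monotone transform
  SummarizedExperiment::assay(se2, "parameters") <- a
  sc2 <- screenCorrelation(se2)
  i1 <- sc1$parameter == "Shw" & sc1$channel == "restored adhesion"
  i2 <- sc2$parameter == "Shw" & sc2$channel == "restored adhesion"
  expect_equal(abs(sc2$rho[i2]), abs(sc1$rho[i1]), tolerance = 1e-9)
})

test_that("permuted activation labels select nothing", {
  se <- cachedSeriesSE()
  null <- permutationNull(se, nPerm = 100, seed = 3)
  expect_gte(null$emptyFraction, 0.95)
})

test_that("the activation estimator inverts the calibration", {
  se <- cachedSeriesSE()
  cal <- fitActivationCalibration(se, nBoot = 100, seed = 2)
  x <- afmring:::.assayLong(se)
  rest <- x$cd$channel == "restored adhesion"
  ## control cells estimate to (near) zero
  ctr <- rowMeans(x$mat[, rest & x$cd$group == "CTR 0m"])
  est0 <- estimateActivation(ctr, cal)
  expect_lt(est0$level, 0.1)
  ## a mid-level query lands mid-scale: synthesise the calibration means
  ## at level ~0.63 (the 10-minute group)
  mid <- rowMeans(x$mat[, rest & x$cd$group == "ACT 10m"])
  estM <- estimateActivation(mid, cal)
  expect_gt(estM$level, 0.35)
  expect_lt(estM$level, 0.9)
  expect_true(estM$interval[1] <= estM$interval[2])
  ## full activation estimates high
  act <- rowMeans(x$mat[, rest & x$cd$group == "ACT 120m"])
  expect_gt(estimateActivation(act, cal)$level, 0.7)
})

test_that("held-out cells are recovered with small absolute error", {
  se <- cachedSeriesSE()
  cal <- fitActivationCalibration(se, nBoot = 100, seed = 2)
  ns <- asNamespace("afmring")
  errs <- c()
  for (lv in c(0, 0.39, 0.63, 0.95)) {
    for (cell in 1:5) {
      cs <- ns$deriveSeed(4242, round(100 * lv), cell)
      cfg <- ns$.cellJitter(surfaceConfig(targetRms = 0.35), cs, lv)
      p <- parameterSuite(generateSurface(cfg,
                                          seed = ns$deriveSeed(cs, 101L)))
      errs <- c(errs, estimateActivation(p, cal)$level - lv)
    }
  }
  expect_lt(mean(abs(errs)), 0.15)
})
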