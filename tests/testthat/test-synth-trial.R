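noiselessParams <- function(...) {
  senescenceParams(cultivarSd = 0, noiseSd = 0, mainPlotSd = 0,
                   subPlotSd = 0, ...)
}

smallDesign <- function(nCultivars) trialDesign(nCultivars = nCultivars)

test_that("noiseless trajectories are monotone and ordered low >= int >= high N", {
  g <- simulateGenotypes(30, 60, seed = 10)
  tr <- simulateTrial(smallDesign(30), g, params = noiselessParams(), seed = 10)
  obs <- tr$observations
  # monotone nondecreasing per plot over dates
  byPlot <- split(obs, obs$plot_id)
  expect_true(all(vapply(byPlot, function(d)
    all(diff(d$psri[order(d$gdd)]) >= -1e-12), TRUE)))
  # N gradient at every shared date
  for (d in unique(obs$date)) {
    m <- tapply(obs$psri[obs$date == d], obs$n_level[obs$date == d], mean)
    expect_gte(m[["low"]], m[["intermediate"]] - 1e-12)
    expect_gte(m[["intermediate"]], m[["high"]] - 1e-12)
  }
  # the optional plateau keeps monotonicity
  trP <- simulateTrial(smallDesign(30), g, seed = 10,
                       params = noiselessParams(plateauStart = 30,
                                                plateauLength = 120))
  byPlot <- split(trP$observations, trP$observations$plot_id)
  expect_true(all(vapply(byPlot, function(d)
    all(diff(d$psri[order(d$gdd)]) >= -1e-12), TRUE)))
})

test_that("favourable-allele carriers have lower PSRI (planted direction)", {
  cs <- causalSpec(data.frame(chrom = "5A", pos = 50e6, favAllele = "T",
                              effect = 30, nSpec = "all", maf = 0.3,
                              favIsMinor = FALSE))
  g <- simulateGenotypes(1000, 30, causal = cs, seed = 11, missingRate = 0)
  tr <- simulateTrial(smallDesign(1000), g, causal = cs, seed = 11)
  obs <- tr$observations
  central <- sort(unique(obs$date))[2:3]
  genoMean <- tapply(obs$psri[obs$date %in% central],
                     obs$cultivar[obs$date %in% central], mean)
  dose <- doses(g)[names(genoMean), "QTN_5A_50.0"]
  ct <- cor.test(dose, genoMean)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  carriers <- dose == 2
  expect_lt(mean(genoMean[carriers]), mean(genoMean[!carriers]))
})

test_that("zero causal effects leave no marker-PSRI signal", {
  cs <- causalSpec(data.frame(chrom = "5A", pos = 50e6, favAllele = "T",
                              effect = 0, nSpec = "all", maf = 0.3,
                              favIsMinor = FALSE))
  g <- simulateGenotypes(200, 400, causal = cs, seed = 12, missingRate = 0,
                         structureSd = 0)
  tr <- simulateTrial(smallDesign(200), g, causal = cs, seed = 12)
  obs <- tr$observations
  central <- sort(unique(obs$date))[2:3]
  genoMean <- tapply(obs$psri[obs$date %in% central],
                     obs$cultivar[obs$date %in% central], mean)
  pv <- apply(doses(g)[names(genoMean), ], 2, function(d)
    cor.test(d, genoMean)$p.value)
  frac <- mean(pv < 0.05)
  expect_gt(frac, 0.01); expect_lt(frac, 0.10)   # null calibration
  expect_gt(min(pv), 0.05 / length(pv) / 10)     # no genome-wide hit
})

test_that("yield couples negatively to senescence, strongest at low N", {
  g <- simulateGenotypes(221, 100, seed = 13)
  tr <- simulateTrial(smallDesign(221), g, seed = 13)
  obs <- tr$observations; yl <- tr$yields
  central <- sort(unique(obs$date))[2:3]
  rByN <- sapply(c("low", "intermediate", "high"), function(nl) {
    ps <- tapply(obs$psri[obs$n_level == nl & obs$date %in% central],
                 obs$cultivar[obs$n_level == nl & obs$date %in% central], mean)
    gy <- tapply(yl$grain_yield[yl$n_level == nl],
                 yl$cultivar[yl$n_level == nl], mean)
    cor(ps[names(gy)], gy)
  })
  expect_true(all(rByN < -0.3))
  expect_lt(rByN[["low"]], rByN[["intermediate"]])
  expect_lt(rByN[["low"]], rByN[["high"]])
})

test_that("trial simulation is deterministic and validates its inputs", {
  g <- simulateGenotypes(20, 40, seed = 14)
  t1 <- simulateTrial(smallDesign(20), g, seed = 14)
  t2 <- simulateTrial(smallDesign(20), g, seed = 14)
  expect_identical(t1$observations, t2$observations)
  expect_identical(t1$yields, t2$yields)
  expect_error(simulateTrial(smallDesign(50), g), "configuration error")
  expect_error(trialDesign(imagingDates = c("2020-06-01", "2020-05-01")),
               "increasing")
})

test_that("band reflectances reproduce the recorded index values exactly", {
  g <- simulateGenotypes(15, 30, seed = 15)
  tr <- simulateTrial(smallDesign(15), g, seed = 15)
  o <- tr$observations
  bands <- o[, c("475", "560", "668", "717", "740", "842")]
  expect_equal(computeIndex(bands, "PSRI", cameraModel("dual")), o$psri,
               tolerance = 1e-12)
  expect_equal(computeIndex(bands, "NDVI"), o$ndvi, tolerance = 1e-12)
  expect_equal(computeIndex(bands, "NDRE"), o$ndre, tolerance = 1e-12)
})
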