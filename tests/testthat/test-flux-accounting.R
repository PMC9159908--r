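mkBottle <- function(treatment = "13CH4", bottle = "b1",
                     aToc = 4.65, aCo2 = 15.05, aTon = 2.951, aNh4 = 3.98,
                     cToc = 0.239, cCo2 = 1560, cTon = 0.0145, cNh4 = 5.43,
                     no3bd = TRUE, no2bd = TRUE) {
  data.frame(
    bottle_id = bottle, treatment = treatment,
    pool_id = c("TOC", "CO2", "TON", "NH4", "NO3", "NO2"),
    phase = c("solid", "gas", "solid", "liquid", "liquid", "liquid"),
    concentration = c(cToc, cCo2, cTon, cNh4, 0, 0),
    unit = c("fraction_dw", "umol_per_L", "fraction_dw",
             "mg_per_L", "mg_per_L", "mg_per_L"),
    atom_percent = c(aToc, aCo2, aTon, aNh4, NA, NA),
    below_detection = c(FALSE, FALSE, FALSE, FALSE, no3bd, no2bd),
    stringsAsFactors = FALSE)
}
geo <- bottleGeometry(0.08, 0.04, 0.03)

test_that("total CH4 consumption sums the solid and gas terms", {
  b <- mkBottle(aToc = 1.08, aCo2 = 1.08)
  out <- totalCh4Consumption(b, geo)
  expect_equal(out$t_ch4, 0)
  expect_equal(out$biomass_13C, 0)
  expect_equal(out$co2_13C, 0)

  out2 <- totalCh4Consumption(mkBottle(), geo)
  expect_equal(out2$t_ch4, out2$biomass_13C + out2$co2_13C)
  expect_error(totalCh4Consumption(mkBottle()[-1, ], geo),
               class = "msipMissingPool")
})

test_that("carbon-use efficiency is consistent with the printed flux pair", {
  # components derived from the printed total 1238 and CUE 53%
  expect_equal(round(carbonUseEfficiency(656.1, 1238), 3), 0.530)
  expect_equal(carbonUseEfficiency(5, 5), 1)
  expect_equal(carbonUseEfficiency(0, 100), 0)
  expect_true(is.na(carbonUseEfficiency(0, 0)))
})

test_that("N2 fixation sums solid and detected liquid terms, skipping others", {
  out <- totalN2Fixation(mkBottle(), geo)
  expect_equal(out$t_n2, out$biomass_15N + out$inorganic_15N)
  expect_setequal(out$skipped, c("NO3", "NO2"))
  # all pools at background: zero fixation
  bg <- totalN2Fixation(mkBottle(aTon = 0.369, aNh4 = 0.369), geo)
  expect_equal(bg$t_n2, 0)
})

test_that("mineralized fraction and fold stimulation match printed values", {
  expect_equal(round(mineralizedFraction(18.4, 43.3) * 100, 1), 42.5)
  expect_equal(mineralizedFraction(0, 5), 0)
  expect_equal(mineralizedFraction(4, 4), 1)
  expect_true(is.na(mineralizedFraction(0, 0)))

  expect_equal(round(foldStimulation(43.3, 0.27)), 160)
  expect_equal(round(foldStimulation(43.3, 0.264)), 164)
  expect_equal(foldStimulation(7, 7), 1)
  expect_warning(f <- foldStimulation(1, 0), class = "msipInfiniteFold")
  expect_equal(f, Inf)
})

test_that("N-fixing efficiency is mol N per mol CH4", {
  expect_equal(nfixEfficiency(43.3, 1238), 43.3 / 1238)
  expect_equal(nfixEfficiency(0, 1238), 0)
  expect_true(is.na(nfixEfficiency(1, 0)))
})

test_that("field nitrogen budget inflates net emission to gross production", {
  masses <- molarMasses()
  b <- fieldNitrogenBudget(150, 0.9, 43.3 / 1238, masses)
  # oracle: gross 1500, oxidized 1350 kg CH4 -> kmol -> N kg
  expect_equal(b, 1350 / masses$mCH4 * (43.3 / 1238) * masses$mN)
  # no recycling inflation
  expect_equal(fieldNitrogenBudget(100, 0, 0.03, masses), 0)
  expect_equal(fieldNitrogenBudget(0, 0.9, 0.03, masses), 0)
  # gross interpretation mode oxidizes a fraction of the stated figure
  expect_equal(fieldNitrogenBudget(150, 0.9, 0.03, masses,
                                   mode = "gross_times_fraction"),
               135 / masses$mCH4 * 0.03 * masses$mN)
  expect_error(fieldNitrogenBudget(150, 1, 0.03),
               class = "msipValidationError")
})

test_that("budget is linear in efficiency and in net emission", {
  set.seed(3)
  for (i in 1:20) {
    e <- runif(1, 0, 0.1); net <- runif(1, 10, 500); a <- runif(1, 0.5, 3)
    expect_equal(fieldNitrogenBudget(net, 0.9, a * e),
                 a * fieldNitrogenBudget(net, 0.9, e), tolerance = 1e-12)
    expect_equal(fieldNitrogenBudget(a * net, 0.9, e),
                 a * fieldNitrogenBudget(net, 0.9, e), tolerance = 1e-12)
  }
})

test_that("fluxes are additive and CUE is scale invariant", {
  out <- totalCh4Consumption(mkBottle(), geo)
  expect_identical(out$t_ch4, out$biomass_13C + out$co2_13C)
  # doubling both components doubles the total, leaves CUE unchanged
  cue1 <- carbonUseEfficiency(out$biomass_13C, out$t_ch4)
  cue2 <- carbonUseEfficiency(2 * out$biomass_13C, 2 * out$t_ch4)
  expect_equal(cue1, cue2)
})

test_that("computeFluxes processes bottles and fluxSummary aggregates them", {
  sim <- simulateBottles(simulationConfig(noiseCv = 0))
  f <- computeFluxes(sim$measurements, sim$geometry)
  expect_equal(nrow(f), 9)
  expect_equal(f$t_ch4, f$biomass_13C + f$co2_13C)
  s <- fluxSummary(f)
  ch4 <- s[s$treatment == "13CH4" & s$variable == "t_ch4", ]
  expect_equal(ch4$mean, 1238, tolerance = 1e-9)
  expect_equal(ch4$sd, 0, tolerance = 1e-9)
  expect_equal(ch4$n, 3)
})

test_that("simulator bottles with noise recover planted fluxes within envelope", {
  sim <- simulateBottles(singleTreatmentConfig(nReplicates = 30,
                                               noiseCv = 0.02, seed = 4))
  f <- suppressWarnings(computeFluxes(sim$measurements, sim$geometry))
  expect_equal(mean(f$t_ch4), 1238, tolerance = 0.05)
  expect_equal(mean(f$cue), 0.53, tolerance = 0.05)
})
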