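test_that("zero-noise bottles invert exactly to the planted fluxes", {
  sim <- simulateBottles(simulationConfig(noiseCv = 0))
  f <- computeFluxes(sim$measurements, sim$geometry)
  truth <- sim$truth
  for (tr in truth$treatment) {
    g <- f[f$treatment == tr, ]
    want <- truth[truth$treatment == tr, ]
    expect_equal(g$t_ch4, rep(want$t_ch4, 3), tolerance = 1e-9)
    expect_equal(g$t_n2, rep(want$t_n2, 3), tolerance = 1e-9)
    expect_equal(g$mineralized_fraction, rep(want$mineralized, 3),
                 tolerance = 1e-9)
    if (!is.na(want$cue))
      expect_equal(g$cue, rep(want$cue, 3), tolerance = 1e-9)
  }
})

test_that("same seed gives identical simulator output", {
  s1 <- simulateBottles(simulationConfig(seed = 123, noiseCv = 0.05))
  s2 <- simulateBottles(simulationConfig(seed = 123, noiseCv = 0.05))
  expect_identical(s1$measurements, s2$measurements)
  s3 <- simulateBottles(simulationConfig(seed = 124, noiseCv = 0.05))
  expect_false(identical(s1$measurements, s3$measurements))

  g1 <- simulateGradient(TRUE, 0.03, seed = 7)
  g2 <- simulateGradient(TRUE, 0.03, seed = 7)
  expect_identical(gradientFractions(g1$sample), gradientFractions(g2$sample))

  o1 <- simulateOtuTable(seed = 21)
  o2 <- simulateOtuTable(seed = 21)
  expect_identical(SummarizedExperiment::assay(o1$se, "counts"),
                   SummarizedExperiment::assay(o2$se, "counts"))
})

test_that("simulator does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(simulateBottles(simulationConfig(seed = 5)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("below-detection flags follow the media design", {
  sim <- simulateBottles(simulationConfig(noiseCv = 0))
  m <- sim$measurements
  expect_true(all(m$below_detection[m$treatment == "13CH4" &
                                      m$pool_id %in% c("NO3", "NO2")]))
  expect_false(any(m$below_detection[m$treatment == "13CH4_NO3" &
                                       m$pool_id == "NO3"]))
})

test_that("config validation rejects out-of-range planted truths", {
  badTruths <- defaultTreatmentTruths()
  badTruths$mineralized[1] <- 1.5
  expect_error(simulationConfig(truths = badTruths),
               class = "msipValidationError")
  expect_error(simulationConfig(noiseCv = -0.1),
               class = "msipValidationError")
  expect_error(simulationConfig(treatments = "nope"),
               class = "msipValidationError")
})

test_that("unlabeled gradient pairs are called unlabeled", {
  g <- simulateGradient(labeled = FALSE, shift = 0.03, seed = 8)
  expect_equal(detectLabeling(g$sample, g$control)$call, "unlabeled")
  expect_error(simulateGradient(shift = -0.01),
               class = "msipValidationError")
})

test_that("OTU generator plants modules and responders as designed", {
  o <- simulateOtuTable(seed = 22)
  counts <- SummarizedExperiment::assay(o$se, "counts")
  expect_equal(dim(counts), c(100, 12))
  expect_equal(sum(o$moduleLabels > 0), 40)
  expect_true(all(counts >= 0))
  cd <- SummarizedExperiment::colData(o$se)
  expect_setequal(unique(cd$treatment),
                  c("day0", "NoCH4", "13CH4", "13CH4_NO3"))
  expect_error(simulateOtuTable(responders = data.frame(
    treatment = "13CH4", taxon = "NotATaxon", effect = 2)),
    class = "msipValidationError")
})

test_that("module co-variation is detectable only when the factor is on", {
  oOn <- simulateOtuTable(seed = 23, moduleFactorSd = 1.5,
                          nReplicates = 6, responders = NULL)
  countsOn <- SummarizedExperiment::assay(oOn$se, "counts")
  clr <- clrTransform(countsOn)
  mem <- oOn$moduleLabels
  m1 <- names(mem)[mem == 1]
  rOn <- mean(stats::cor(t(clr[m1, ]))[upper.tri(diag(length(m1)))])
  oOff <- simulateOtuTable(seed = 23, moduleFactorSd = 0,
                           nReplicates = 6, responders = NULL)
  clrOff <- clrTransform(SummarizedExperiment::assay(oOff$se, "counts"))
  rOff <- mean(stats::cor(t(clrOff[m1, ]))[upper.tri(diag(length(m1)))])
  expect_gt(rOn, 0.5)
  expect_lt(abs(rOff), 0.3)
})
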