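# Synthetic microcosm experiments with known ground truth: bottles with
# planted fluxes (inverting the isotope mass balances), density-gradient
# profiles with planted heavy shifts, and OTU tables with planted
# co-occurrence modules and treatment responders.

#' Default planted treatment truths
#'
#' Per-treatment ground truth for the bottle simulator: total CH4
#' consumption and carbon-use efficiency, total N2 fixation and its
#' mineralized fraction. Defaults mirror a dual-label root-incubation
#' design: a no-methane control with trace N2 fixation, a methane
#' treatment with strong fixation, and a nitrate-amended methane treatment
#' in which fixation is almost fully suppressed.
#'
#' @return data.frame with columns treatment, t_ch4, cue, t_n2,
#'   mineralized.
#' @export
defaultTreatmentTruths <- function() {
  data.frame(
    treatment = c("NoCH4", "13CH4", "13CH4_NO3"),
    t_ch4 = c(0, 1238, 1734),
    cue = c(NA, 0.53, 0.38),
    t_n2 = c(0.264, 43.3, 0.53),
    mineralized = c(0.06 / 0.264, 18.4 / 43.3, 0.32 / 0.53),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic microcosm experiment
#'
#' Bundles the design (treatments, replicates), the planted per-treatment
#' truths, bottle geometry, measurement noise and the bulk pool parameters
#' from which the simulator derives internally consistent atom-percent
#' values by inverting the isotope mass balances.
#'
#' @param seed Integer seed.
#' @param nReplicates Replicate bottles per treatment (default 3).
#' @param treatments Treatment labels; must appear in \code{truths} and in
#'   the concentration vectors.
#' @param truths data.frame as from \code{\link{defaultTreatmentTruths}}.
#' @param dryMass Dry root mass per bottle in g (default 0.03).
#' @param headspaceVolume,liquidVolume Bottle volumes in L.
#' @param noiseCv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (default 0.02).
#' @param backgrounds Background atom percents
#'   (\code{\link{isotopeBackgrounds}}).
#' @param masses \code{\link{molarMasses}}.
#' @param tocContent,tonContent C and N content of root dry mass
#'   (fractions).
#' @param co2Conc Headspace CO2 concentration, micromol/L.
#' @param nh4Conc,no3Conc,no2Conc Named per-treatment dissolved
#'   concentrations in mg N/L; \code{NA} marks below-detection species.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1, nReplicates = 3,
                             treatments = c("NoCH4", "13CH4", "13CH4_NO3"),
                             truths = defaultTreatmentTruths(),
                             dryMass = 0.03,
                             headspaceVolume = 0.08, liquidVolume = 0.04,
                             noiseCv = 0.02,
                             backgrounds = isotopeBackgrounds(),
                             masses = molarMasses(),
                             tocContent = 0.239, tonContent = 0.0145,
                             co2Conc = 1560,
                             nh4Conc = c(NoCH4 = 1.27, `13CH4` = 5.43,
                                         `13CH4_NO3` = 0.091),
                             no3Conc = c(NoCH4 = NA, `13CH4` = NA,
                                         `13CH4_NO3` = 100),
                             no2Conc = c(NoCH4 = NA, `13CH4` = NA,
                                         `13CH4_NO3` = 0.5)) {
  if (noiseCv < 0)
    msipError("'noiseCv' must be non-negative", "msipValidationError")
  if (!all(treatments %in% truths$treatment))
    msipError("every treatment needs a row in 'truths'",
              "msipValidationError")
  bad <- with(truths, (!is.na(cue) & (cue < 0 | cue > 1)) |
                mineralized < 0 | mineralized > 1 | t_ch4 < 0 | t_n2 < 0)
  if (any(bad))
    msipError("planted truths out of range (fractions must lie in [0,1])",
              "msipValidationError")
  if (tocContent <= 0 || tocContent > 1 || tonContent <= 0 || tonContent > 1)
    msipError("elemental contents must be fractions in (0, 1]",
              "msipValidationError")
  structure(list(seed = seed, nReplicates = nReplicates,
                 treatments = treatments, truths = truths,
                 geometry = bottleGeometry(headspaceVolume, liquidVolume,
                                           dryMass),
                 noiseCv = noiseCv, backgrounds = backgrounds,
                 masses = masses,
                 tocContent = tocContent, tonContent = tonContent,
                 co2Conc = co2Conc, nh4Conc = nh4Conc,
                 no3Conc = no3Conc, no2Conc = no2Conc),
            class = "SimulationConfig")
}

.noisy <- function(x, cv) {
  if (cv == 0) return(x)
  x * pmax(stats::rnorm(length(x), 1, cv), 1e-6)
}

#' Simulate bottle measurement tables with planted fluxes
#'
#' Derives pool concentrations and atom percents consistent with the
#' planted per-treatment fluxes by inverting the isotope mass balances,
#' then applies multiplicative Gaussian noise (CV \code{noiseCv}) to every
#' measured quantity (concentrations and atom percents). With zero noise
#' the flux pipeline recovers the planted values exactly. Nitrate/nitrite
#' rows are flagged below-detection where the configuration says so
#' (N-free media).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List with \code{measurements} (tidy table accepted by
#'   \code{\link{computeFluxes}}), \code{geometry}, \code{truth} (planted
#'   per-treatment values) and \code{config}.
#' @examples
#' sim <- simulateBottles(simulationConfig(noiseCv = 0))
#' computeFluxes(sim$measurements, sim$geometry)
#' @export
simulateBottles <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  geo <- config$geometry
  ms <- config$masses
  bg <- config$backgrounds
  rows <- list()
  withSeed(config$seed, {
    for (tr in config$treatments) {
      tru <- config$truths[config$truths$treatment == tr, ]
      cue <- if (is.na(tru$cue)) 0 else tru$cue
      biomass13C <- cue * tru$t_ch4
      co2_13C <- tru$t_ch4 - biomass13C
      biomass15N <- (1 - tru$mineralized) * tru$t_n2
      inorg15N <- tru$mineralized * tru$t_n2
      exToc <- biomass13C * ms$m13C / (config$tocContent * 1e6)
      exCo2 <- co2_13C * geo$dryMass / (config$co2Conc *
                                          geo$headspaceVolume)
      exTon <- biomass15N * ms$m15N / (config$tonContent * 1e6)
      nh4 <- config$nh4Conc[[tr]]
      exNh4 <- inorg15N * ms$m15N * geo$dryMass / (nh4 * geo$liquidVolume * 1e3)
      for (rep in seq_len(config$nReplicates)) {
        b <- sprintf("%s_%d", tr, rep)
        cv <- config$noiseCv
        mk <- function(pool, phase, conc, unit, atom, bd = FALSE) {
          data.frame(bottle_id = b, treatment = tr, pool_id = pool,
                     phase = phase,
                     concentration = if (bd) 0 else .noisy(conc, cv),
                     unit = unit,
                     atom_percent = if (bd) NA_real_
                                    else pmin(.noisy(atom, cv), 100),
                     below_detection = bd, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- rbind(
          mk("TOC", "solid", config$tocContent, "fraction_dw",
             bg[["13C"]] + exToc * 100),
          mk("CO2", "gas", config$co2Conc, "umol_per_L",
             bg[["13C"]] + exCo2 * 100),
          mk("TON", "solid", config$tonContent, "fraction_dw",
             bg[["15N"]] + exTon * 100),
          mk("NH4", "liquid", nh4, "mg_per_L",
             bg[["15N"]] + exNh4 * 100),
          mk("NO3", "liquid", config$no3Conc[[tr]], "mg_per_L",
             bg[["15N"]], bd = is.na(config$no3Conc[[tr]])),
          mk("NO2", "liquid", config$no2Conc[[tr]], "mg_per_L",
             bg[["15N"]], bd = is.na(config$no2Conc[[tr]])))
      }
    }
  })
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(measurements = measurements, geometry = geo,
       truth = config$truths[config$truths$treatment %in% config$treatments, ],
       config = config)
}

#' Simulate a density-gradient profile pair
#'
#' Gaussian marker-gene peaks over 15 gradient fractions spanning buoyant
#' densities 1.76 down to 1.69 g/ml (fraction 1 heaviest). The control
#' profile peaks in the light DNA; the labeled profile's peak is displaced
#' toward higher density by \code{shift}. Multiplicative log-normal noise
#' perturbs the copy numbers.
#'
#' @param labeled Logical; displace the sample peak by \code{shift}.
#' @param shift Planted density shift in g/ml (default 0.03).
#' @param noiseSd SD of the log-normal copy-number noise (default 0.05).
#' @param seed Integer seed.
#' @param gene Marker gene label.
#' @param peakDensity Unlabeled peak density in g/ml (default 1.705).
#' @param peakSd Gaussian peak width in g/ml (default 0.008).
#' @param amplitude Peak copy number (default 1e7).
#' @return List with \code{sample} and \code{control}
#'   \linkS4class{GradientProfile}s and the planted \code{shift}.
#' @export
simulateGradient <- function(labeled = TRUE, shift = 0.03, noiseSd = 0.05,
                             seed = 1, gene = "pmoA",
                             peakDensity = 1.705, peakSd = 0.008,
                             amplitude = 1e7) {
  if (shift < 0)
    msipError("'shift' must be non-negative", "msipValidationError")
  densities <- seq(1.76, 1.69, length.out = 15)
  peakS <- peakDensity + if (labeled) shift else 0
  mkCopies <- function(peak) {
    mu <- amplitude * exp(-(densities - peak)^2 / (2 * peakSd^2))
    mu * exp(stats::rnorm(length(mu), 0, noiseSd))
  }
  withSeed(seed, {
    sampleCopies <- mkCopies(peakS)
    controlCopies <- mkCopies(peakDensity)
  })
  list(sample = GradientProfile("sample", gene, seq_along(densities),
                                densities, sampleCopies),
       control = GradientProfile("control", gene, seq_along(densities),
                                 densities, controlCopies),
       shift = if (labeled) shift else 0)
}

#' Simulate an OTU count table with planted modules and responders
#'
#' Log-normal abundance backbone; taxa within a planted module share a
#' per-sample latent factor, inducing co-occurrence; responder taxa are
#' multiplied by a treatment effect size; counts are drawn from a negative
#' binomial around the compositional expectation.
#'
#' @param seed Integer seed.
#' @param nReplicates Samples per group.
#' @param groups Sample group labels (default day-0 roots plus the three
#'   incubation treatments).
#' @param nModules Number of planted co-occurrence modules.
#' @param taxaPerModule Taxa per module.
#' @param nBackgroundTaxa Additional unstructured taxa.
#' @param baseLogSd SD of the per-taxon log abundance backbone.
#' @param moduleFactorSd SD of the shared per-sample module factor (0
#'   disables co-occurrence signal).
#' @param loading Loading of module members on their factor.
#' @param responders data.frame(treatment, taxon, effect) of planted
#'   treatment responders, or NULL. Default: one low-abundance taxon with
#'   an 8.4-fold response under "13CH4".
#' @param dispersion Negative binomial size parameter.
#' @param libSize Expected reads per sample.
#' @return List with \code{se} (SummarizedExperiment, taxa x samples,
#'   colData columns treatment/replicate), \code{moduleLabels} (named; 0 =
#'   background taxon), \code{responders} and the generator arguments.
#' @export
simulateOtuTable <- function(seed = 1, nReplicates = 3,
                             groups = c("day0", "NoCH4", "13CH4",
                                        "13CH4_NO3"),
                             nModules = 4, taxaPerModule = 10,
                             nBackgroundTaxa = 60,
                             baseLogSd = 1.5, moduleFactorSd = 1.5,
                             loading = 1,
                             responders = data.frame(
                               treatment = "13CH4", taxon = "Otu0001",
                               effect = 8.4, stringsAsFactors = FALSE),
                             dispersion = 25, libSize = 2e4) {
  nTaxa <- nModules * taxaPerModule + nBackgroundTaxa
  taxa <- sprintf("Otu%04d", seq_len(nTaxa))
  moduleLabels <- structure(
    c(rep(0L, nBackgroundTaxa),
      rep(seq_len(nModules), each = taxaPerModule))[seq_len(nTaxa)],
    names = taxa)
  # background taxa come first so default responders are module-free
  samples <- paste(rep(groups, each = nReplicates),
                   rep(seq_len(nReplicates), times = length(groups)),
                   sep = "_")
  groupOf <- rep(groups, each = nReplicates)
  if (!is.null(responders) && !all(responders$taxon %in% taxa))
    msipError("responder taxa outside the simulated taxon set",
              "msipValidationError")
  counts <- withSeed(seed, {
    baseLog <- stats::rnorm(nTaxa, 0, baseLogSd)
    sapply(seq_along(samples), function(j) {
      logmu <- baseLog
      if (nModules > 0 && moduleFactorSd > 0) {
        f <- stats::rnorm(nModules, 0, moduleFactorSd)
        inMod <- moduleLabels > 0
        logmu[inMod] <- logmu[inMod] + loading * f[moduleLabels[inMod]]
      }
      if (!is.null(responders)) {
        hit <- responders$treatment == groupOf[j]
        if (any(hit)) {
          idx <- match(responders$taxon[hit], taxa)
          logmu[idx] <- logmu[idx] + log(responders$effect[hit])
        }
      }
      mu <- exp(logmu)
      p <- mu / sum(mu)
      stats::rnbinom(nTaxa, mu = p * libSize, size = dispersion)
    })
  })
  dimnames(counts) <- list(taxa, samples)
  se <- makeOtuExperiment(counts,
                          sampleData = data.frame(
                            treatment = groupOf,
                            replicate = rep(seq_len(nReplicates),
                                            times = length(groups)),
                            stringsAsFactors = FALSE))
  list(se = se, moduleLabels = moduleLabels, responders = responders,
       seed = seed, nReplicates = nReplicates, groups = groups)
}
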