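# Flux assembly from the isotope mass-balance primitives.
#
# Measurement tables are tidy: one row per (bottle, pool) with columns
# bottle_id, treatment, pool_id, phase, concentration, unit, atom_percent,
# below_detection. Recognized pools: TOC (solid), CO2 (gas), TON (solid),
# NH4/NO3/NO2 (liquid). Units: percent_dw / fraction_dw for solids,
# umol_per_L for gas, mg_per_L for liquids.

.measurementCols <- c("bottle_id", "treatment", "pool_id", "phase",
                      "concentration", "unit", "atom_percent",
                      "below_detection")
.allowedUnits <- list(solid = c("percent_dw", "fraction_dw"),
                      gas = "umol_per_L",
                      liquid = "mg_per_L")

.checkMeasurementFrame <- function(m) {
  missing <- setdiff(.measurementCols, names(m))
  if (length(missing))
    msipError(paste0("measurement table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              "msipValidationError")
  bad <- !mapply(function(u, p) u %in% (.allowedUnits[[p]] %||% character()),
                 as.character(m$unit), as.character(m$phase))
  if (any(bad))
    msipError(sprintf("unknown unit/phase combination in row(s): %s",
                      paste(which(bad), collapse = ", ")),
              "msipUnitError")
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.poolRow <- function(m, pool, required = TRUE) {
  r <- m[m$pool_id == pool, , drop = FALSE]
  if (nrow(r) == 0L) {
    if (required)
      msipError(sprintf("required pool '%s' missing from bottle measurements",
                        pool), "msipMissingPool")
    return(NULL)
  }
  if (nrow(r) > 1L)
    msipError(sprintf("duplicate rows for pool '%s'", pool),
              "msipValidationError")
  r
}

.contentFraction <- function(row) {
  if (row$unit == "percent_dw") row$concentration / 100 else row$concentration
}

#' Total CH4 consumption from the dual-pool carbon mass balance
#'
#' Sums the \eqn{^{13}}C recovered in root biomass (solid TOC term) and in
#' headspace \eqn{^{13}}CO2 (gas term) to give total CH4 consumption in
#' micromol C per g dry weight. Dissolved \eqn{^{13}}C organics are not
#' included (their contribution is small, typically below 5\%); pass their
#' amount through \code{dissolvedC13} to add them explicitly.
#'
#' @param measurements Tidy measurement rows for one bottle (see
#'   \code{\link{readMeasurements}} for the format).
#' @param geometry A \code{\link{bottleGeometry}}.
#' @param background Background atom percent of \eqn{^{13}}C (default 1.08).
#' @param masses A \code{\link{molarMasses}} list.
#' @param dissolvedC13 Optional dissolved organic \eqn{^{13}}C term in
#'   micromol C per g dry weight (default 0, i.e. excluded).
#' @param ... Passed to \code{\link{atomPercentExcess}} (e.g. tolerance).
#' @return List with \code{t_ch4}, \code{biomass_13C}, \code{co2_13C}.
#' @seealso \code{\link{computeFluxes}} for a whole measurement table.
#' @export
totalCh4Consumption <- function(measurements, geometry,
                                background = isotopeBackgrounds()[["13C"]],
                                masses = molarMasses(),
                                dissolvedC13 = 0, ...) {
  .checkMeasurementFrame(measurements)
  toc <- .poolRow(measurements, "TOC")
  co2 <- .poolRow(measurements, "CO2")
  exToc <- atomPercentExcess(toc$atom_percent, background, ...) / 100
  exCo2 <- atomPercentExcess(co2$atom_percent, background, ...) / 100
  biomass <- solidLabeledAmount(exToc, .contentFraction(toc), masses$m13C)
  respired <- gasLabeledAmount(exCo2, co2$concentration, geometry)
  list(t_ch4 = biomass + respired + dissolvedC13,
       biomass_13C = biomass, co2_13C = respired)
}

#' Carbon-use efficiency of methanotrophy
#'
#' Fraction of the oxidized CH4 carbon assimilated into biomass rather than
#' respired: \code{biomass13C / tCh4}. Undefined (NA) when no methane was
#' consumed.
#'
#' @param biomass13C Biomass \eqn{^{13}}C term, micromol C per g.
#' @param tCh4 Total CH4 consumption, micromol C per g.
#' @return CUE as a fraction in [0, 1]; \code{NA_real_} when
#'   \code{tCh4 == 0}.
#' @examples
#' carbonUseEfficiency(656.1, 1238) # 0.530
#' @export
carbonUseEfficiency <- function(biomass13C, tCh4) {
  ifelse(tCh4 > 0, biomass13C / tCh4, NA_real_)
}

#' Total N2 fixation from the solid and dissolved nitrogen mass balance
#'
#' Sums the \eqn{^{15}}N recovered in root biomass nitrogen (solid TON term)
#' and in dissolved inorganic nitrogen species (NH4+, NO3-, NO2-) released
#' by mineralization of the fixed organic \eqn{^{15}}N. Species whose bulk
#' concentration was below the detection limit are skipped (their isotope
#' abundance is not measurable) and listed in \code{skipped}.
#'
#' @inheritParams totalCh4Consumption
#' @param background Background atom percent of \eqn{^{15}}N (default 0.369).
#' @return List with \code{t_n2}, \code{biomass_15N}, \code{inorganic_15N},
#'   the per-species breakdown \code{inorganic_by_species}, and
#'   \code{skipped} (character vector of skipped species).
#' @export
totalN2Fixation <- function(measurements, geometry,
                            background = isotopeBackgrounds()[["15N"]],
                            masses = molarMasses(), ...) {
  .checkMeasurementFrame(measurements)
  ton <- .poolRow(measurements, "TON")
  exTon <- atomPercentExcess(ton$atom_percent, background, ...) / 100
  biomass <- solidLabeledAmount(exTon, .contentFraction(ton), masses$m15N)
  species <- c("NH4", "NO3", "NO2")
  terms <- numeric(0)
  skipped <- character(0)
  for (sp in species) {
    row <- .poolRow(measurements, sp, required = FALSE)
    if (is.null(row)) next
    if (isTRUE(row$below_detection)) {
      skipped <- c(skipped, sp)
      terms[sp] <- 0
      next
    }
    ex <- atomPercentExcess(row$atom_percent, background, ...) / 100
    terms[sp] <- liquidLabeledAmount(ex, row$concentration, geometry,
                                     masses$m15N)
  }
  inorganic <- sum(terms)
  list(t_n2 = biomass + inorganic,
       biomass_15N = biomass,
       inorganic_15N = inorganic,
       inorganic_by_species = terms,
       skipped = skipped)
}

#' Fraction of fixed N mineralized to dissolved inorganic forms
#'
#' @param inorganic15N Dissolved inorganic \eqn{^{15}}N, micromol N per g.
#' @param tN2 Total N2 fixation, micromol N per g.
#' @return Fraction; \code{NA_real_} when \code{tN2 == 0}.
#' @examples
#' mineralizedFraction(18.4, 43.3) # 0.425
#' @export
mineralizedFraction <- function(inorganic15N, tN2) {
  ifelse(tN2 > 0, inorganic15N / tN2, NA_real_)
}

#' Fold stimulation of a flux relative to a control
#'
#' @param treatmentValue Flux under the treatment.
#' @param controlValue Flux under the control; a zero control yields
#'   \code{Inf} with a warning.
#' @return Dimensionless fold change.
#' @examples
#' foldStimulation(43.3, 0.27) # ~160
#' @export
foldStimulation <- function(treatmentValue, controlValue) {
  if (any(controlValue < 0))
    msipError("'controlValue' must be non-negative", "msipValidationError")
  if (any(controlValue == 0))
    msipWarning("control value is zero; fold stimulation is infinite",
                "msipInfiniteFold")
  ifelse(controlValue == 0, Inf, treatmentValue / controlValue)
}

#' Methanotrophic N2-fixing efficiency
#'
#' Moles of N2-derived nitrogen fixed per mole of CH4 oxidized,
#' \code{tN2 / tCh4}.
#'
#' @param tN2 Total N2 fixation, micromol N per g.
#' @param tCh4 Total CH4 consumption, micromol C per g.
#' @return mol N per mol CH4; \code{NA_real_} when \code{tCh4 == 0}.
#' @examples
#' nfixEfficiency(43.3, 1238)
#' @export
nfixEfficiency <- function(tN2, tCh4) {
  ifelse(tCh4 > 0, tN2 / tCh4, NA_real_)
}

#' Field-scale nitrogen input from methane-oxidation-coupled N2 fixation
#'
#' Extrapolates the microcosm-derived N-fixing efficiency to an areal
#' nitrogen budget. Under the default \code{mode = "net_is_escape"}, the
#' reported net emission is interpreted as the fraction escaping oxidation,
#' so gross CH4 production is \code{net / (1 - oxidizedFraction)} and the
#' oxidized mass is gross times the oxidized fraction. The alternative mode
#' \code{"gross_times_fraction"} treats the reported figure as gross
#' production and oxidizes a fraction of it directly.
#'
#' @param netEmission Net CH4 emission in kg CH4/ha/yr.
#' @param oxidizedFraction Fraction of gross CH4 production oxidized before
#'   release, in [0, 1).
#' @param efficiency N-fixing efficiency in mol N per mol CH4.
#' @param masses A \code{\link{molarMasses}} list.
#' @param mode Budget interpretation; see Details.
#' @return Fixed nitrogen in kg N/ha/yr.
#' @examples
#' fieldNitrogenBudget(150, 0.9, 43.3 / 1238)
#' @export
fieldNitrogenBudget <- function(netEmission, oxidizedFraction, efficiency,
                                masses = molarMasses(),
                                mode = c("net_is_escape",
                                         "gross_times_fraction")) {
  mode <- match.arg(mode)
  if (any(oxidizedFraction < 0) || any(oxidizedFraction >= 1))
    msipError("'oxidizedFraction' must lie in [0, 1)", "msipValidationError")
  if (any(netEmission < 0))
    msipError("'netEmission' must be non-negative", "msipValidationError")
  oxidized <- switch(mode,
    net_is_escape = netEmission / (1 - oxidizedFraction) * oxidizedFraction,
    gross_times_fraction = netEmission * oxidizedFraction)
  oxidized / masses$mCH4 * efficiency * masses$mN
}

#' Per-bottle flux results for a whole measurement table
#'
#' Runs \code{\link{totalCh4Consumption}} and \code{\link{totalN2Fixation}}
#' for every bottle in a tidy measurement table and derives CUE, the
#' mineralized fraction and the N-fixing efficiency.
#'
#' @param measurements Tidy measurement table covering one or more bottles.
#' @param geometry A \code{\link{bottleGeometry}} shared by all bottles.
#' @param backgrounds Named vector from \code{\link{isotopeBackgrounds}}.
#' @param masses A \code{\link{molarMasses}} list.
#' @param ... Passed to \code{\link{atomPercentExcess}}.
#' @return data.frame with one row per bottle: treatment, t_ch4,
#'   biomass_13C, co2_13C, cue, t_n2, biomass_15N, inorganic_15N,
#'   mineralized_fraction, nfix_efficiency, n_skipped.
#' @export
computeFluxes <- function(measurements, geometry,
                          backgrounds = isotopeBackgrounds(),
                          masses = molarMasses(), ...) {
  .checkMeasurementFrame(measurements)
  bottles <- unique(measurements$bottle_id)
  res <- lapply(bottles, function(b) {
    m <- measurements[measurements$bottle_id == b, , drop = FALSE]
    carbon <- totalCh4Consumption(m, geometry,
                                  background = backgrounds[["13C"]],
                                  masses = masses, ...)
    nitro <- totalN2Fixation(m, geometry,
                             background = backgrounds[["15N"]],
                             masses = masses, ...)
    data.frame(bottle_id = b,
               treatment = m$treatment[1L],
               t_ch4 = carbon$t_ch4,
               biomass_13C = carbon$biomass_13C,
               co2_13C = carbon$co2_13C,
               cue = carbonUseEfficiency(carbon$biomass_13C, carbon$t_ch4),
               t_n2 = nitro$t_n2,
               biomass_15N = nitro$biomass_15N,
               inorganic_15N = nitro$inorganic_15N,
               mineralized_fraction = mineralizedFraction(nitro$inorganic_15N,
                                                          nitro$t_n2),
               nfix_efficiency = nfixEfficiency(nitro$t_n2, carbon$t_ch4),
               n_skipped = length(nitro$skipped),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-treatment mean and standard deviation of flux results
#'
#' @param fluxes data.frame from \code{\link{computeFluxes}}.
#' @return data.frame with one row per (treatment, variable): mean, sd, n.
#' @export
fluxSummary <- function(fluxes) {
  vars <- c("t_ch4", "biomass_13C", "co2_13C", "cue", "t_n2",
            "biomass_15N", "inorganic_15N", "mineralized_fraction",
            "nfix_efficiency")
  out <- do.call(rbind, lapply(split(fluxes, fluxes$treatment), function(g) {
    do.call(rbind, lapply(vars, function(v) {
      x <- g[[v]]
      data.frame(treatment = g$treatment[1L], variable = v,
                 mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE),
                 n = sum(!is.na(x)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
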