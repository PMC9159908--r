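#' Molar masses used in the isotope mass balances
#'
#' Bundles the molar masses of the heavy isotopes and of the bulk species
#' needed to convert labeled-pool contents into molar fluxes. Defaults are
#' the isotopically correct values (13.003 g/mol for \eqn{^{13}}C, 15.000
#' g/mol for \eqn{^{15}}N); \code{nominal = TRUE} requests the integer
#' nominal masses (13, 15, 16, 14), the rounding commonly used in field
#' reports.
#'
#' @param m13C Molar mass of \eqn{^{13}}C in g/mol.
#' @param m15N Molar mass of \eqn{^{15}}N in g/mol.
#' @param mCH4 Molar mass of CH4 in g/mol.
#' @param mN Molar mass of N in g/mol.
#' @param nominal Logical; use integer nominal masses instead of the
#'   isotopic defaults.
#' @return A named list of class \code{"MolarMasses"}.
#' @examples
#' molarMasses()
#' molarMasses(nominal = TRUE)
#' @export
molarMasses <- function(m13C = 13.003, m15N = 15.000,
                        mCH4 = 16.043, mN = 14.007,
                        nominal = FALSE) {
  if (isTRUE(nominal)) {
    m13C <- 13; m15N <- 15; mCH4 <- 16; mN <- 14
  }
  for (nm in c("m13C", "m15N", "mCH4", "mN"))
    assertScalarNumeric(get(nm), nm, positive = TRUE, strict = TRUE)
  structure(list(m13C = m13C, m15N = m15N, mCH4 = mCH4, mN = mN),
            class = "MolarMasses")
}

#' Incubation bottle geometry
#'
#' Headspace volume, liquid medium volume and dry root mass of one serum
#' bottle microcosm. Defaults follow the standard 120-ml serum bottle set-up
#' with 40 ml liquid medium, 80 ml headspace after root addition.
#'
#' @param headspaceVolume Headspace gas volume in L (default 0.08).
#' @param liquidVolume Liquid medium volume in L (default 0.04).
#' @param dryMass Dry weight of the root pellet in g.
#' @return A named list of class \code{"BottleGeometry"}.
#' @examples
#' bottleGeometry(dryMass = 0.03)
#' @export
bottleGeometry <- function(headspaceVolume = 0.08, liquidVolume = 0.04,
                           dryMass) {
  assertScalarNumeric(headspaceVolume, "headspaceVolume",
                      positive = TRUE, strict = TRUE)
  assertScalarNumeric(liquidVolume, "liquidVolume",
                      positive = TRUE, strict = TRUE)
  assertScalarNumeric(dryMass, "dryMass", positive = TRUE, strict = TRUE)
  structure(list(headspaceVolume = headspaceVolume,
                 liquidVolume = liquidVolume,
                 dryMass = dryMass),
            class = "BottleGeometry")
}

#' Natural-abundance (control) isotope backgrounds
#'
#' Baseline atom percent of the heavy isotope in unlabeled pools, used as
#' the subtraction background for atom-percent excess. Defaults are the
#' measured no-label control baselines typical of such incubations (1.08
#' atom% \eqn{^{13}}C, 0.369 atom% \eqn{^{15}}N) rather than textbook
#' natural-abundance values; both are configurable.
#'
#' @param c13 Background atom percent for \eqn{^{13}}C.
#' @param n15 Background atom percent for \eqn{^{15}}N.
#' @return Named numeric vector with elements \code{"13C"} and \code{"15N"}.
#' @export
isotopeBackgrounds <- function(c13 = 1.08, n15 = 0.369) {
  assertScalarNumeric(c13, "c13", positive = TRUE)
  assertScalarNumeric(n15, "n15", positive = TRUE)
  c(`13C` = c13, `15N` = n15)
}

#' Per-cell conversion constants for qPCR-based biomass estimation
#'
#' Constants to convert 16S rRNA gene copy numbers into cell counts and
#' microbial biomass carbon/nitrogen: mean rRNA operon copy number per cell,
#' cell dry weight, carbon fraction of cell dry mass, and the biomass C:N
#' ratio used to derive MBN from MBC.
#'
#' @param copiesPerCell 16S rRNA gene copies per cell (default 3.82).
#' @param cellDryWeight Dry weight of one cell in g (default 6.2e-13).
#' @param carbonFraction g C per g cell dry weight (default 0.5).
#' @param biomassCN C:N mass ratio of microbial biomass (default 8.5,
#'   within the commonly reported 8--9 range for soil microbial biomass).
#' @return A named list of class \code{"CellConversion"}.
#' @examples
#' cellConversion()
#' @export
cellConversion <- function(copiesPerCell = 3.82, cellDryWeight = 6.2e-13,
                           carbonFraction = 0.5, biomassCN = 8.5) {
  assertScalarNumeric(copiesPerCell, "copiesPerCell",
                      positive = TRUE, strict = TRUE)
  assertScalarNumeric(cellDryWeight, "cellDryWeight",
                      positive = TRUE, strict = TRUE)
  assertScalarNumeric(carbonFraction, "carbonFraction",
                      positive = TRUE, strict = TRUE)
  if (carbonFraction > 1)
    msipError("'carbonFraction' cannot exceed 1", "msipValidationError")
  assertScalarNumeric(biomassCN, "biomassCN", positive = TRUE, strict = TRUE)
  structure(list(copiesPerCell = copiesPerCell,
                 cellDryWeight = cellDryWeight,
                 carbonFraction = carbonFraction,
                 biomassCN = biomassCN),
            class = "CellConversion")
}
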