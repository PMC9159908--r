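#' Atom percent of a heavy isotope in a pool
#'
#' Lightweight tagged value: the atom percent (0--100) of the heavy isotope
#' in a measured pool, together with which isotope it refers to. Used by
#' \code{\link{atomPercentExcess}} to guard against mixing \eqn{^{13}}C and
#' \eqn{^{15}}N measurements.
#'
#' @param value Atom percent, between 0 and 100 (vectorized).
#' @param isotope One of \code{"13C"} or \code{"15N"}.
#' @return Numeric vector of class \code{"AtomPercent"} with an
#'   \code{isotope} attribute.
#' @examples
#' atomPercent(4.65, "13C")
#' @export
atomPercent <- function(value, isotope = c("13C", "15N")) {
  isotope <- match.arg(isotope)
  if (!is.numeric(value) || anyNA(value))
    msipError("'value' must be numeric without NA", "msipValidationError")
  if (any(value < 0 | value > 100))
    msipError("atom percent must lie in [0, 100]", "msipValidationError")
  structure(as.numeric(value), isotope = isotope, class = "AtomPercent")
}

#' Atom-percent excess of a labeled pool over its background
#'
#' Subtracts the natural-abundance (control) atom percent from the measured
#' atom percent. Small negative differences (within \code{tolerance}) are
#' treated as measurement noise around the baseline and clamped to zero with
#' a warning; differences more negative than \code{-tolerance} indicate an
#' inconsistent background and raise an error by default.
#'
#' @param sample Measured atom percent (numeric or \code{\link{atomPercent}}).
#' @param background Background atom percent (numeric or
#'   \code{\link{atomPercent}}); when both carry isotope tags they must match.
#' @param tolerance Clamping tolerance in atom percent units (default 0.05).
#' @param negative What to do with differences below \code{-tolerance}:
#'   \code{"error"} (default) or \code{"clamp"} to zero with a warning.
#' @return Numeric vector of excess atom percent (>= 0).
#' @examples
#' atomPercentExcess(4.65, 1.08)   # 3.57
#' atomPercentExcess(2.951, 0.369) # 2.582
#' @export
atomPercentExcess <- function(sample, background, tolerance = 0.05,
                              negative = c("error", "clamp")) {
  negative <- match.arg(negative)
  isoS <- attr(sample, "isotope")
  isoB <- attr(background, "isotope")
  if (!is.null(isoS) && !is.null(isoB) && !identical(isoS, isoB))
    msipError(sprintf("isotope mismatch: sample is %s, background is %s",
                      isoS, isoB), "msipIsotopeMismatch")
  sample <- as.numeric(sample)
  background <- as.numeric(background)
  if (any(sample < 0 | sample > 100) || any(background < 0 | background > 100))
    msipError("atom percent values must lie in [0, 100]",
              "msipValidationError")
  excess <- sample - background
  hard <- excess < -tolerance
  if (any(hard)) {
    msg <- sprintf(
      "sample atom percent below background by more than %g (min excess %g)",
      tolerance, min(excess))
    if (negative == "error") msipError(msg, "msipNegativeExcess")
    msipWarning(msg, "msipNegativeExcess")
  }
  soft <- excess < 0 & !hard
  if (any(soft))
    msipWarning("small negative excess clamped to 0 (within tolerance)",
                "msipClampedExcess")
  pmax(excess, 0)
}

#' Labeled atoms in a solid pool, per g dry weight
#'
#' First term of the solid-phase isotope mass balance: micromoles of heavy
#' atoms per gram of dry root, from the atom-fraction excess and the
#' elemental content of the dry matter.
#'
#' @param excess Atom-fraction excess of the heavy isotope, in [0, 1]
#'   (note: fraction, not percent).
#' @param content Elemental content of the pool as a fraction of dry mass,
#'   in [0, 1].
#' @param molarMass Molar mass of the heavy isotope, g/mol.
#' @return Micromoles of heavy atoms per g dry weight.
#' @examples
#' solidLabeledAmount(0.0357, 0.40, 13.0) # 1098.46
#' @export
solidLabeledAmount <- function(excess, content, molarMass) {
  if (any(!is.finite(excess)) || any(excess < 0 | excess > 1))
    msipError("'excess' must be an atom fraction in [0, 1] (not percent)",
              "msipUnitError")
  if (any(!is.finite(content)) || any(content < 0 | content > 1))
    msipError("'content' must be a mass fraction in [0, 1] (not percent)",
              "msipUnitError")
  assertScalarNumeric(molarMass, "molarMass", positive = TRUE, strict = TRUE)
  excess * content * 1e6 / molarMass
}

#' Labeled atoms in a headspace gas pool, per g dry weight
#'
#' Gas-phase term of the isotope mass balance: heavy atoms in the headspace,
#' scaled by headspace volume and normalized to dry root mass.
#'
#' @param excess Atom-fraction excess in [0, 1].
#' @param concentration Gas concentration in micromol/L.
#' @param geometry A \code{\link{bottleGeometry}}.
#' @return Micromoles of heavy atoms per g dry weight.
#' @examples
#' gasLabeledAmount(0.1397, 2000, bottleGeometry(0.08, 0.04, 0.03))
#' @export
gasLabeledAmount <- function(excess, concentration, geometry) {
  if (any(!is.finite(excess)) || any(excess < 0 | excess > 1))
    msipError("'excess' must be an atom fraction in [0, 1]", "msipUnitError")
  if (any(concentration < 0))
    msipError("'concentration' must be non-negative", "msipValidationError")
  if (!inherits(geometry, "BottleGeometry"))
    msipError("'geometry' must be a bottleGeometry()", "msipValidationError")
  excess * concentration * geometry$headspaceVolume / geometry$dryMass
}

#' Labeled atoms in a dissolved (liquid) pool, per g dry weight
#'
#' Liquid-phase term of the isotope mass balance for dissolved inorganic
#' nitrogen species. Concentrations are in mg N/L, converted to micromoles
#' of heavy atoms via the isotope molar mass, the liquid volume, and the dry
#' root mass. When the bulk concentration of the species was below the
#' detection limit its isotope abundance is not determined: the term is
#' zero and the returned value carries \code{attr(, "skipped") = TRUE}.
#'
#' @param excess Atom-fraction excess in [0, 1].
#' @param concentration Species concentration in mg/L.
#' @param geometry A \code{\link{bottleGeometry}}.
#' @param molarMass Molar mass of the heavy isotope, g/mol.
#' @param belowDetection Logical; bulk concentration below detection limit.
#' @return Micromoles of heavy atoms per g dry weight; zero with a
#'   \code{"skipped"} attribute when \code{belowDetection}.
#' @examples
#' liquidLabeledAmount(0.5, 1.5, bottleGeometry(0.08, 0.04, 0.03), 15.0)
#' @export
liquidLabeledAmount <- function(excess, concentration, geometry, molarMass,
                                belowDetection = FALSE) {
  if (!inherits(geometry, "BottleGeometry"))
    msipError("'geometry' must be a bottleGeometry()", "msipValidationError")
  assertScalarNumeric(molarMass, "molarMass", positive = TRUE, strict = TRUE)
  if (isTRUE(belowDetection))
    return(structure(0, skipped = TRUE))
  if (any(!is.finite(excess)) || any(excess < 0 | excess > 1))
    msipError("'excess' must be an atom fraction in [0, 1]", "msipUnitError")
  if (any(concentration < 0))
    msipError("'concentration' must be non-negative", "msipValidationError")
  excess * concentration * geometry$liquidVolume * 1e3 /
    (molarMass * geometry$dryMass)
}
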