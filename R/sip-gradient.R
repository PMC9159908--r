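# Density-gradient analysis: normalized fraction profiles, peak location,
# and the heavy-shift labeling call comparing a sample against its
# unlabeled control.

#' Normalize a gradient profile to relative abundance per fraction
#'
#' @param profile A \linkS4class{GradientProfile}.
#' @return data.frame with columns fraction, density, rel_abund; the
#'   relative abundances sum to 1.
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  f <- gradientFractions(profile)
  total <- sum(f$copies)
  if (total <= 0)
    msipError("all-zero gradient profile cannot be normalized",
              "msipValidationError")
  data.frame(fraction = f$fraction, density = f$density,
             rel_abund = f$copies / total)
}

#' Peak fraction of a gradient profile
#'
#' Fraction with the maximum (normalized) abundance. Ties break toward the
#' higher buoyant density: isotope labeling can only increase density, so a
#' fixed heavy-ward rule keeps the call deterministic.
#'
#' @param profile A \linkS4class{GradientProfile}.
#' @return List with \code{index} (fraction index) and \code{density}
#'   (buoyant density at the peak).
#' @export
peakFraction <- function(profile) {
  n <- normalizeProfile(profile)
  top <- which(n$rel_abund == max(n$rel_abund))
  if (length(top) > 1L) top <- top[which.max(n$density[top])]
  list(index = n$fraction[top], density = n$density[top])
}

#' Heavy-shift labeling call for a gradient profile pair
#'
#' Declares a gene pool \eqn{^{13}}C-labeled when its abundance peak sits at
#' a buoyant density at least \code{minDensityShift} above the peak of the
#' unlabeled control profile. The shift is compared with \code{>=}, so a
#' shift exactly at the threshold is called labeled. Heavy fractions are
#' those whose density is within \code{halfWindow} below (or anywhere
#' above) the labeled peak density.
#'
#' @param labeledProfile \linkS4class{GradientProfile} from the labeled
#'   incubation.
#' @param controlProfile \linkS4class{GradientProfile} from the unlabeled
#'   control.
#' @param minDensityShift Minimum peak-density shift in g/ml to call the
#'   pool labeled (default 0.015, about half the full \eqn{^{13}}C shift of
#'   DNA).
#' @param halfWindow Half-width in g/ml of the heavy-fraction window below
#'   the labeled peak (default 0.01).
#' @return List with \code{call} (\code{"labeled"} or \code{"unlabeled"}),
#'   \code{shift} (g/ml), \code{peak_labeled}, \code{peak_control} (peak
#'   lists as from \code{\link{peakFraction}}), and \code{heavy_fractions}
#'   (integer fraction indices).
#' @examples
#' g <- simulateGradient(labeled = TRUE, shift = 0.03, seed = 1)
#' detectLabeling(g$sample, g$control)$call
#' @export
detectLabeling <- function(labeledProfile, controlProfile,
                           minDensityShift = 0.015, halfWindow = 0.01) {
  nl <- normalizeProfile(labeledProfile)
  nc <- normalizeProfile(controlProfile)
  if (min(nl$density) > max(nc$density) || min(nc$density) > max(nl$density))
    msipError("gradient profiles cover non-overlapping density ranges",
              "msipValidationError")
  pl <- peakFraction(labeledProfile)
  pc <- peakFraction(controlProfile)
  shift <- pl$density - pc$density
  call <- if (shift >= minDensityShift) "labeled" else "unlabeled"
  heavy <- nl$fraction[nl$density >= pl$density - halfWindow]
  list(call = call, shift = shift,
       peak_labeled = pl, peak_control = pc,
       heavy_fractions = sort(heavy))
}
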