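# Partitioning of total root C and N into compartments (undissolved
# ROC/RON, microbial biomass, respired CO2, inorganic N, dissolved by
# difference), each expressed as a percentage of the day-0 total.

#' Cell count from 16S rRNA gene copy numbers
#'
#' @param copies 16S rRNA gene copies (vectorized).
#' @param conv A \code{\link{cellConversion}}.
#' @return Estimated number of cells.
#' @examples
#' cellsFromCopies(1e10)
#' @export
cellsFromCopies <- function(copies, conv = cellConversion()) {
  if (any(copies < 0))
    msipError("'copies' must be non-negative", "msipValidationError")
  copies / conv$copiesPerCell
}

#' Microbial biomass carbon and nitrogen from cell counts
#'
#' Converts a cell count into biomass dry mass, microbial biomass carbon
#' (MBC) and microbial biomass nitrogen (MBN = MBC / biomass C:N).
#'
#' @param cells Number of cells (vectorized).
#' @param conv A \code{\link{cellConversion}}.
#' @return List with \code{dry_mass}, \code{mbc}, \code{mbn} (all in g).
#' @examples
#' microbialBiomass(1)
#' @export
microbialBiomass <- function(cells, conv = cellConversion()) {
  if (any(cells < 0))
    msipError("'cells' must be non-negative", "msipValidationError")
  dryMass <- cells * conv$cellDryWeight
  mbc <- dryMass * conv$carbonFraction
  list(dry_mass = dryMass, mbc = mbc, mbn = mbc / conv$biomassCN)
}

#' Unlabeled pool by isotope subtraction
#'
#' The unlabeled share of a pool as total minus its labeled share (e.g.
#' \eqn{^{12}}CO2 as total CO2 minus \eqn{^{13}}CO2, or mineralization-
#' derived \eqn{^{14}}NH4+ as total NH4+ minus \eqn{^{15}}NH4+). Labeled
#' amounts slightly exceeding the total (within \code{tolerance} of the
#' total) clamp to zero; larger violations are a mass-balance error.
#'
#' @param total Total pool amount.
#' @param labeled Labeled share of the pool.
#' @param tolerance Relative tolerance (fraction of \code{total}, default
#'   0.02) for clamping.
#' @return \code{total - labeled}, clamped at 0 within tolerance.
#' @examples
#' unlabeledBySubtraction(15.5, 0.55) # 14.95
#' @export
unlabeledBySubtraction <- function(total, labeled, tolerance = 0.02) {
  diff <- total - labeled
  bad <- diff < -tolerance * abs(total)
  if (any(bad))
    msipError("labeled amount exceeds total beyond tolerance",
              "msipMassBalanceError")
  pmax(diff, 0)
}

#' Dissolved pool by mass-balance difference
#'
#' Dissolved organic carbon (or nitrogen) as the day-0 undissolved pool
#' minus the day-30 undissolved pool and the gaseous/inorganic losses.
#'
#' @param day0Undissolved Undissolved pool at day 0.
#' @param day30Undissolved Undissolved pool at day 30.
#' @param losses Gaseous (CO2) or inorganic-N losses over the incubation.
#' @param tolerance Relative tolerance (fraction of \code{day0Undissolved})
#'   for clamping small negative results to zero.
#' @return Dissolved amount in the same unit as the inputs.
#' @examples
#' dissolvedByDifference(100, 40, 10) # 50
#' @export
dissolvedByDifference <- function(day0Undissolved, day30Undissolved, losses,
                                  tolerance = 0.02) {
  res <- day0Undissolved - (day30Undissolved + losses)
  bad <- res < -tolerance * abs(day0Undissolved)
  if (any(bad))
    msipError("day-30 pools plus losses exceed the day-0 pool: mass-balance violation",
              "msipMassBalanceError")
  pmax(res, 0)
}

#' Express compartment amounts as percentages of the day-0 total
#'
#' Builds a closed partition: each compartment as a percentage of the day-0
#' total, plus a residual compartment so that the percentages sum to 100.
#'
#' @param amounts Named numeric vector of compartment amounts, all in one
#'   common basis (per bottle or per g dry weight).
#' @param day0Total Day-0 total in the same basis; must be positive.
#' @param element Which element the partition describes, \code{"C"} or
#'   \code{"N"} (metadata only).
#' @param residualName Name for the closure compartment (default
#'   \code{"other"}); not added when the named compartments already close
#'   the balance.
#' @param tolerance Relative tolerance for a small negative residual
#'   (default 0.02), clamped to zero; a larger overshoot errors.
#' @return A \linkS4class{PoolPartition}.
#' @examples
#' partitionPercentages(c(ROC = 98.6, MBC = 1.4), 100, element = "C")
#' @export
partitionPercentages <- function(amounts, day0Total, element = c("C", "N"),
                                 residualName = "other", tolerance = 0.02) {
  element <- match.arg(element)
  assertScalarNumeric(day0Total, "day0Total", positive = TRUE, strict = TRUE)
  if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
    msipError("'amounts' must be a fully named vector", "msipValidationError")
  if (any(amounts < 0))
    msipError("compartment amounts must be non-negative",
              "msipValidationError")
  residual <- day0Total - sum(amounts)
  if (residual < -tolerance * day0Total)
    msipError("compartments exceed the day-0 total: mass-balance violation",
              "msipMassBalanceError")
  residual <- max(residual, 0)
  if (residual > 0) {
    amounts <- c(amounts, structure(residual, names = residualName))
  }
  tab <- data.frame(compartment = names(amounts),
                    amount = unname(amounts),
                    percent = unname(amounts) / day0Total * 100,
                    stringsAsFactors = FALSE)
  # renormalize the sub-0.1% closure slack that clamping can introduce
  tab$percent <- tab$percent / sum(tab$percent) * 100
  PoolPartition(element = element, table = tab)
}
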