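# Delimited-text readers and writers for the three input table types, and
# the summary report stage. All files are TSV by default (comma accepted on
# read), UTF-8, decimal point, header required.

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path))
    msipError(sprintf("file not found: %s", path), "msipValidationError")
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a bottle measurement table
#'
#' Expects one row per (bottle, pool) with columns bottle_id, treatment,
#' pool_id, phase, concentration, unit, atom_percent, below_detection.
#' Units are validated against the allowed vocabulary per phase
#' (percent_dw/fraction_dw for solids, umol_per_L for gas, mg_per_L for
#' liquids); offending rows are reported with their line numbers.
#'
#' @param path TSV (or CSV) file path.
#' @return Validated measurement data.frame.
#' @export
readMeasurements <- function(path) {
  m <- .readDelim(path)
  missing <- setdiff(.measurementCols, names(m))
  if (length(missing))
    msipError(paste0("missing column(s): ", paste(missing, collapse = ", ")),
              "msipValidationError")
  m$below_detection <- as.logical(m$below_detection)
  bad <- !mapply(function(u, p) u %in% (.allowedUnits[[p]] %||% character()),
                 as.character(m$unit), as.character(m$phase))
  if (any(bad))
    msipError(sprintf("unknown unit/phase combination on line(s): %s",
                      paste(which(bad) + 1L, collapse = ", ")),
              "msipUnitError")
  negC <- !m$below_detection & (is.na(m$concentration) | m$concentration < 0)
  if (any(negC))
    msipError(sprintf("negative or missing concentration on line(s): %s",
                      paste(which(negC) + 1L, collapse = ", ")),
              "msipValidationError")
  dup <- duplicated(m[, c("bottle_id", "pool_id")])
  if (any(dup))
    msipError(sprintf("duplicate (bottle, pool) key on line(s): %s",
                      paste(which(dup) + 1L, collapse = ", ")),
              "msipValidationError")
  m
}

#' Write a bottle measurement table
#'
#' @param measurements Measurement data.frame.
#' @param path Output TSV path.
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an OTU table
#'
#' Taxa as rows and samples as columns; the first column holds taxon ids
#' and an optional \code{taxonomy} column holds taxonomy strings.
#'
#' @param path TSV (or CSV) file path.
#' @param sampleData Optional per-sample metadata data.frame.
#' @return A SummarizedExperiment (see \code{\link{makeOtuExperiment}}).
#' @export
readOtuTable <- function(path, sampleData = NULL) {
  t <- .readDelim(path)
  taxa <- as.character(t[[1L]])
  t <- t[, -1L, drop = FALSE]
  taxonomy <- NULL
  if ("taxonomy" %in% names(t)) {
    taxonomy <- t$taxonomy
    t$taxonomy <- NULL
  }
  counts <- as.matrix(t)
  if (!is.numeric(counts))
    msipError("non-numeric abundance columns in OTU table",
              "msipValidationError")
  rownames(counts) <- taxa
  makeOtuExperiment(counts, taxonomy = taxonomy, sampleData = sampleData)
}

#' Write an OTU table
#'
#' @param se SummarizedExperiment with a \code{"counts"} assay.
#' @param path Output TSV path.
#' @export
writeOtuTable <- function(se, path) {
  counts <- SummarizedExperiment::assay(se, "counts")
  out <- data.frame(taxon = rownames(counts), counts, check.names = FALSE)
  rd <- SummarizedExperiment::rowData(se)
  if ("taxonomy" %in% names(rd)) out$taxonomy <- rd$taxonomy
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gradient profiles
#'
#' Expects columns sample_id, gene, fraction_index, buoyant_density,
#' copies; returns one \linkS4class{GradientProfile} per (sample, gene).
#'
#' @param path TSV (or CSV) file path.
#' @return Named list of \linkS4class{GradientProfile}s
#'   (\code{"<sample>.<gene>"}).
#' @export
readGradients <- function(path) {
  t <- .readDelim(path)
  need <- c("sample_id", "gene", "fraction_index", "buoyant_density",
            "copies")
  missing <- setdiff(need, names(t))
  if (length(missing))
    msipError(paste0("missing column(s): ", paste(missing, collapse = ", ")),
              "msipValidationError")
  keys <- split(t, interaction(t$sample_id, t$gene, drop = TRUE))
  lapply(keys, function(g)
    GradientProfile(as.character(g$sample_id[1L]), as.character(g$gene[1L]),
                    g$fraction_index, g$buoyant_density, g$copies))
}

#' Write gradient profiles
#'
#' @param profiles List of \linkS4class{GradientProfile}s.
#' @param path Output TSV path.
#' @export
writeGradients <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    f <- gradientFractions(p)
    data.frame(sample_id = sampleId(p), gene = markerGene(p),
               fraction_index = f$fraction, buoyant_density = f$density,
               copies = f$copies, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble the summary report for one experiment
#'
#' Runs the flux stage over a measurement table and, when the optional
#' inputs are supplied, the gradient labeling calls and the volcano
#' classification, and collects per-treatment summaries, fold stimulations
#' against the control, and a provenance block recording all constants.
#'
#' @param measurements Tidy measurement table.
#' @param geometry A \code{\link{bottleGeometry}}.
#' @param controlTreatment Label of the control treatment for fold
#'   stimulations.
#' @param otu Optional SummarizedExperiment for the volcano stage.
#' @param gradients Optional named list of (sample, control) gradient
#'   profile pairs for the labeling stage.
#' @param backgrounds,masses Constants as elsewhere.
#' @param alpha Volcano significance level.
#' @param seed Seed recorded in the provenance block.
#' @return List with \code{fluxes}, \code{flux_summary},
#'   \code{fold_stimulation}, optional \code{labeling} and
#'   \code{volcano_summary}, and \code{provenance}.
#' @export
runReport <- function(measurements, geometry, controlTreatment = "NoCH4",
                      otu = NULL, gradients = NULL,
                      backgrounds = isotopeBackgrounds(),
                      masses = molarMasses(), alpha = 0.05, seed = 1) {
  if (nrow(measurements) == 0L)
    msipError("empty measurement table", "msipValidationError")
  if (!controlTreatment %in% measurements$treatment)
    msipError(sprintf("control treatment '%s' absent from measurements",
                      controlTreatment), "msipValidationError")
  fluxes <- suppressWarnings(
    computeFluxes(measurements, geometry, backgrounds = backgrounds,
                  masses = masses, negative = "clamp"))
  fsum <- fluxSummary(fluxes)
  ctrl <- fsum[fsum$treatment == controlTreatment, ]
  folds <- do.call(rbind, lapply(
    setdiff(unique(fsum$treatment), controlTreatment), function(tr) {
      g <- fsum[fsum$treatment == tr, ]
      cv <- ctrl$mean[match(g$variable, ctrl$variable)]
      data.frame(treatment = tr, variable = g$variable,
                 fold = ifelse(cv > 0, g$mean / cv, NA_real_),
                 stringsAsFactors = FALSE)
    }))
  out <- list(fluxes = fluxes, flux_summary = fsum,
              fold_stimulation = folds)
  if (!is.null(gradients)) {
    out$labeling <- do.call(rbind, lapply(names(gradients), function(nm) {
      d <- detectLabeling(gradients[[nm]]$sample, gradients[[nm]]$control)
      data.frame(id = nm, call = d$call, shift = d$shift,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(otu)) {
    treatments <- setdiff(
      unique(SummarizedExperiment::colData(otu)$treatment),
      controlTreatment)
    out$volcano_summary <- do.call(rbind, lapply(treatments, function(tr) {
      v <- volcanoAnalysis(otu, tr, controlTreatment, alpha = alpha)
      data.frame(treatment = tr,
                 enriched = sum(v$class == "enriched"),
                 depleted = sum(v$class == "depleted"),
                 unchanged = sum(v$class == "unchanged"),
                 stringsAsFactors = FALSE)
    }))
  }
  out$provenance <- list(
    package = "MethanoSIP",
    version = as.character(utils::packageVersion("MethanoSIP")),
    seed = seed, alpha = alpha,
    backgrounds = backgrounds,
    masses = unclass(masses),
    geometry = unclass(geometry),
    control_treatment = controlTreatment)
  out
}
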