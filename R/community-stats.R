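# OTU-table statistics: relative abundance, alpha diversity, per-taxon
# fold change and significance, and the volcano enrichment classification.
#
# OTU tables are SummarizedExperiment objects with taxa as rows and samples
# as columns; assay "counts" holds read counts, assay "relabund" (added by
# relativeAbundance) holds per-sample proportions.

#' Build an OTU SummarizedExperiment
#'
#' @param counts Numeric matrix of read counts, taxa as rows and samples as
#'   columns (both dimnames required).
#' @param taxonomy Optional character vector of taxonomy strings, one per
#'   taxon.
#' @param sampleData Optional data.frame of per-sample metadata (e.g.
#'   treatment, replicate), rows matching the count columns.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}.
#' @export
makeOtuExperiment <- function(counts, taxonomy = NULL, sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    msipError("count matrix must have taxon rownames and sample colnames",
              "msipValidationError")
  if (any(counts < 0))
    msipError("counts must be non-negative", "msipValidationError")
  rowData <- if (!is.null(taxonomy))
    S4Vectors::DataFrame(taxonomy = taxonomy, row.names = rownames(counts))
  else S4Vectors::DataFrame(row.names = rownames(counts))
  colData <- if (!is.null(sampleData))
    S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  else S4Vectors::DataFrame(row.names = colnames(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rowData, colData = colData)
}

#' Per-sample relative abundances
#'
#' Normalizes counts so that each sample (column) sums to 1. For a
#' SummarizedExperiment the result is stored as a new assay
#' \code{"relabund"}; for a matrix the normalized matrix is returned.
#'
#' @param x SummarizedExperiment with a \code{"counts"} assay, or a
#'   taxa-by-samples count matrix.
#' @return Same class as the input.
#' @export
relativeAbundance <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    SummarizedExperiment::assay(x, "relabund") <- relativeAbundance(counts)
    return(x)
  }
  counts <- as.matrix(x)
  totals <- colSums(counts)
  if (any(totals <= 0))
    msipError(sprintf("empty sample(s): %s",
                      paste(colnames(counts)[totals <= 0], collapse = ", ")),
              "msipValidationError")
  sweep(counts, 2, totals, "/")
}

#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} with the convention \eqn{0 \ln 0 = 0};
#' computed through \code{vegan::diversity}.
#'
#' @param p Abundance vector (counts or proportions; normalized internally).
#' @return Shannon index in nats.
#' @examples
#' shannonIndex(rep(1, 10)) # log(10)
#' @export
shannonIndex <- function(p) {
  unname(vegan::diversity(p, index = "shannon"))
}

#' Simpson concentration and diversity
#'
#' Reports both the Simpson concentration \eqn{D = \sum p_i^2} and the
#' complement \eqn{1 - D} (Gini-Simpson diversity).
#'
#' @param p Abundance vector (counts or proportions).
#' @return List with \code{D} and \code{one_minus_D}.
#' @export
simpsonIndex <- function(p) {
  gini <- unname(vegan::diversity(p, index = "simpson"))
  list(D = 1 - gini, one_minus_D = gini)
}

#' Alpha diversity table for an OTU experiment
#'
#' @param x SummarizedExperiment with a \code{"counts"} assay, or a
#'   taxa-by-samples matrix.
#' @return data.frame with one row per sample: shannon, simpson_D,
#'   simpson_1mD.
#' @export
alphaDiversity <- function(x) {
  counts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  data.frame(
    sample = colnames(counts),
    shannon = apply(counts, 2, shannonIndex),
    simpson_D = apply(counts, 2, function(p) simpsonIndex(p)$D),
    simpson_1mD = apply(counts, 2, function(p) simpsonIndex(p)$one_minus_D),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Default pseudocount: half the smallest nonzero abundance
#'
#' @param x Relative abundance matrix (or vector).
#' @return Half the minimum positive value; 0 if all values are zero.
#' @export
defaultPseudocount <- function(x) {
  pos <- x[x > 0]
  if (!length(pos)) return(0)
  min(pos) / 2
}

#' Fold change between treatment and control means
#'
#' \code{(meanTreatment + pseudocount) / (meanControl + pseudocount)}. A
#' nonzero pseudocount keeps zero-abundance taxa from producing infinite
#' folds.
#'
#' @param meanTreatment,meanControl Non-negative group means (vectorized).
#' @param pseudocount Additive stabilizer (default 0; see
#'   \code{\link{defaultPseudocount}}).
#' @return List with \code{fold} and \code{log2_fold}.
#' @examples
#' foldChange(14.3, 1.7)$fold # ~8.4
#' @export
foldChange <- function(meanTreatment, meanControl, pseudocount = 0) {
  if (any(meanTreatment < 0) || any(meanControl < 0))
    msipError("group means must be non-negative", "msipValidationError")
  fold <- (meanTreatment + pseudocount) / (meanControl + pseudocount)
  list(fold = fold, log2_fold = log2(fold))
}

#' Two-group per-taxon significance test
#'
#' Pooled-variance two-sample t test (the two-group reduction of one-way
#' ANOVA with the least significant difference criterion). Degenerate
#' inputs are handled explicitly: when both groups have zero within-group
#' variance the p value is 1 for equal means and 0 otherwise.
#'
#' @param treatment,control Numeric replicate vectors (>= 2 each).
#' @return Two-sided p value.
#' @export
taxonTest <- function(treatment, control) {
  if (length(treatment) < 2L || length(control) < 2L)
    msipError("at least 2 replicates per group are required",
              "msipValidationError")
  if (stats::sd(treatment) == 0 && stats::sd(control) == 0)
    return(if (mean(treatment) == mean(control)) 1 else 0)
  stats::t.test(treatment, control, var.equal = TRUE)$p.value
}

#' One-way ANOVA with pairwise LSD comparisons
#'
#' Fits a one-way ANOVA over three or more groups and computes Fisher's
#' least-significant-difference pairwise p values from the pooled residual
#' mean square.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (>= 3 levels).
#' @return List with \code{anova_p} (overall F-test p value) and
#'   \code{pairwise} (data.frame: group1, group2, p).
#' @export
lsdTest <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L)
    msipError("lsdTest requires at least 3 groups; use taxonTest for 2",
              "msipValidationError")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  anovaP <- an["groups", "Pr(>F)"]
  lev <- levels(groups)
  n <- table(groups)
  m <- tapply(values, groups, mean)
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    tval <- (m[[pr[1]]] - m[[pr[2]]]) / se
    2 * stats::pt(-abs(tval), dfres)
  })
  list(anova_p = unname(anovaP),
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p = unname(pw), stringsAsFactors = FALSE))
}

#' Volcano classification of a taxon
#'
#' A taxon is \code{enriched} when its log2 fold change is positive and the
#' p value is below \code{alpha}, \code{depleted} when the log2 fold change
#' is negative with p below \code{alpha}, and \code{unchanged} otherwise.
#'
#' @param log2fc Log2 fold changes (vectorized).
#' @param p p values in [0, 1].
#' @param alpha Significance threshold (default 0.05; no multiple-testing
#'   correction, matching the raw per-OTU criterion; apply
#'   \code{\link[stats]{p.adjust}} upstream for a corrected analysis).
#' @return Character vector: \code{"enriched"}, \code{"depleted"} or
#'   \code{"unchanged"}.
#' @export
volcanoClassify <- function(log2fc, p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msipError("p values must lie in [0, 1]", "msipValidationError")
  out <- rep("unchanged", length(log2fc))
  out[!is.na(p) & p < alpha & log2fc > 0] <- "enriched"
  out[!is.na(p) & p < alpha & log2fc < 0] <- "depleted"
  out
}

#' Per-taxon volcano analysis between two sample groups
#'
#' Computes per-taxon fold changes of mean relative abundance between a
#' treatment and a control group, tests each taxon with the pooled t test
#' (on variance-stabilized abundances by default), and classifies taxa by
#' the volcano criteria.
#'
#' @param x SummarizedExperiment with a \code{"counts"} assay and a
#'   grouping column in \code{colData}.
#' @param treatment,control Group labels to compare.
#' @param groupVar Name of the grouping column (default "treatment").
#' @param alpha Significance threshold.
#' @param transform Transform applied before testing:
#'   \code{"asinsqrt"} (arcsine square root, default for proportions),
#'   \code{"log"} (log with pseudocount) or \code{"none"}.
#' @param pseudocount Fold-change pseudocount; default half the smallest
#'   nonzero relative abundance in the table.
#' @param adjust Multiple-testing correction passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}, the raw per-OTU
#'   criterion; e.g. \code{"BH"} for Benjamini-Hochberg).
#' @return data.frame with one row per taxon: taxon, mean_treatment,
#'   mean_control, fold, log2_fold, p, class.
#' @export
volcanoAnalysis <- function(x, treatment, control, groupVar = "treatment",
                            alpha = 0.05,
                            transform = c("asinsqrt", "none", "log"),
                            pseudocount = NULL, adjust = "none") {
  transform <- match.arg(transform)
  stopifnot(is(x, "SummarizedExperiment"))
  groups <- SummarizedExperiment::colData(x)[[groupVar]]
  if (is.null(groups))
    msipError(sprintf("no '%s' column in colData", groupVar),
              "msipValidationError")
  rel <- relativeAbundance(SummarizedExperiment::assay(x, "counts"))
  sel <- list(t = rel[, groups == treatment, drop = FALSE],
              c = rel[, groups == control, drop = FALSE])
  if (ncol(sel$t) < 2L || ncol(sel$c) < 2L)
    msipError("need >= 2 replicates in both groups", "msipValidationError")
  if (is.null(pseudocount)) pseudocount <- defaultPseudocount(rel)
  tf <- switch(transform,
               asinsqrt = function(v) asin(sqrt(pmin(v, 1))),
               log = function(v) log(v + pseudocount),
               none = identity)
  mt <- rowMeans(sel$t)
  mc <- rowMeans(sel$c)
  fc <- foldChange(mt, mc, pseudocount)
  p <- vapply(seq_len(nrow(rel)), function(i)
    taxonTest(tf(sel$t[i, ]), tf(sel$c[i, ])), numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  data.frame(taxon = rownames(rel),
             mean_treatment = mt, mean_control = mc,
             fold = fc$fold, log2_fold = fc$log2_fold, p = p,
             class = volcanoClassify(fc$log2_fold, p, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}
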