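# Co-occurrence network inference, module detection, and Zi-Pi node-role
# classification.
#
# The inference step is a deliberately simple, fully documented association
# method (CLR transform + stability-selected absolute-correlation
# threshold), not a re-implementation of sparse inverse-covariance
# selection; the provenance record in the returned AssociationNetwork
# labels results accordingly. The downstream Zi-Pi machinery is agnostic to
# how the network was obtained.

#' Centered log-ratio transform of a count matrix
#'
#' Per-sample CLR: \code{log(x + pseudocount)} centered by its sample mean.
#' Standard guard against compositional (closure) artifacts before
#' computing cross-taxon correlations.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param pseudocount Added before the log (default 0.5).
#' @return Matrix of the same shape.
#' @export
clrTransform <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    msipError("counts must be non-negative", "msipValidationError")
  lg <- log(counts + pseudocount)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Infer a taxon co-occurrence network from an OTU table
#'
#' Association network over taxa: counts are CLR-transformed, pairwise
#' Pearson correlations are computed across samples, and edges are kept
#' when the absolute correlation exceeds a threshold chosen to hit a target
#' edge density (sparsity), then filtered by subsample stability (an edge
#' must re-appear in at least \code{stability} of the random
#' sample-subsets). Deterministic for a fixed seed.
#'
#' @param x SummarizedExperiment with a \code{"counts"} assay, or a
#'   taxa-by-samples count matrix.
#' @param prevalenceFilter Minimum fraction of samples in which a taxon
#'   must be present (count > 0) to enter the network (default 0.3).
#' @param sparsityTarget Target edge density among the filtered taxa
#'   (default 0.05).
#' @param seed Integer seed controlling the stability subsamples.
#' @param nSubsamples Number of stability subsamples (default 30).
#' @param subsampleFraction Fraction of samples drawn per subsample
#'   (default 0.8).
#' @param stability Minimum selection frequency for an edge to be retained
#'   (default 0.7).
#' @param pseudocount CLR pseudocount (default 0.5).
#' @return An \linkS4class{AssociationNetwork}.
#' @export
inferNetwork <- function(x, prevalenceFilter = 0.3, sparsityTarget = 0.05,
                         seed = 1, nSubsamples = 30, subsampleFraction = 0.8,
                         stability = 0.7, pseudocount = 0.5) {
  counts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  nSamples <- ncol(counts)
  if (nSamples < 4L)
    msipError("network inference requires at least 4 samples",
              "msipValidationError")
  keep <- rowMeans(counts > 0) >= prevalenceFilter
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < 2L)
    msipError("fewer than 2 taxa pass the prevalence filter",
              "msipValidationError")
  # lexicographic taxon order makes downstream tie-breaking reproducible
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  clr <- clrTransform(counts, pseudocount)
  r <- suppressWarnings(stats::cor(t(clr)))
  r[!is.finite(r)] <- 0
  absR <- abs(r[upper.tri(r)])
  threshold <- stats::quantile(absR, probs = 1 - sparsityTarget,
                               names = FALSE, type = 7)
  candidate <- abs(r) >= threshold
  diag(candidate) <- FALSE
  freq <- matrix(0, nrow(counts), nrow(counts))
  subSize <- max(3L, floor(subsampleFraction * nSamples))
  withSeed(seed, {
    for (b in seq_len(nSubsamples)) {
      idx <- sample.int(nSamples, subSize)
      rb <- suppressWarnings(stats::cor(t(clr[, idx, drop = FALSE])))
      rb[!is.finite(rb)] <- 0
      freq <- freq + (abs(rb) >= threshold)
    }
  })
  adj <- candidate & (freq / nSubsamples >= stability)
  adj <- adj | t(adj) # symmetry guard (should already hold)
  dimnames(adj) <- dimnames(r)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  AssociationNetwork(g, provenance = list(
    method = "clr_correlation_stability (association stand-in)",
    pseudocount = pseudocount, prevalence_filter = prevalenceFilter,
    sparsity_target = sparsityTarget, threshold = threshold,
    n_subsamples = nSubsamples, subsample_fraction = subsampleFraction,
    stability = stability, seed = seed))
}

#' Detect network modules by greedy modularity maximization
#'
#' Modules (communities) from fast greedy modularity optimization; nodes of
#' isolated components, including singletons, form their own modules. The
#' result is deterministic for a fixed vertex order; vertices are processed
#' in lexicographic name order.
#'
#' @param network An \linkS4class{AssociationNetwork} or igraph graph.
#' @param seed Unused (kept for interface stability); the algorithm is
#'   deterministic.
#' @return Named integer vector mapping node name to module id.
#' @export
detectModules <- function(network, seed = NULL) {
  g <- if (is(network, "AssociationNetwork")) networkGraph(network)
       else network
  nm <- igraph::V(g)$name
  g <- igraph::permute(g, match(nm, sort(nm)))
  if (igraph::ecount(g) == 0L) {
    mem <- seq_len(igraph::vcount(g))
  } else {
    cl <- igraph::cluster_fast_greedy(g)
    mem <- igraph::membership(cl)
  }
  out <- structure(as.integer(mem), names = igraph::V(g)$name)
  out[order(names(out))]
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For each node i with degree \eqn{k_i}: Zi is the z-score of its
#' within-module degree relative to the other members of its module (0 when
#' the module's within-degree standard deviation is zero); Pi is the
#' participation coefficient \eqn{1 - \sum_s (k_{is}/k_i)^2} over modules s
#' (0 for isolated nodes).
#'
#' @param network An \linkS4class{AssociationNetwork} or igraph graph.
#' @param membership Named integer vector of module ids covering all nodes.
#' @return data.frame with columns node, module, degree, within_degree,
#'   zi, pi.
#' @export
ziPi <- function(network, membership) {
  g <- if (is(network, "AssociationNetwork")) networkGraph(network)
       else network
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(membership)))
    msipError("membership must cover all network nodes",
              "msipValidationError")
  mem <- membership[nodes]
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  k <- rowSums(adj)
  # within-degree and per-module degree split
  kWithin <- vapply(seq_along(nodes), function(i)
    sum(adj[i, mem == mem[i]]), numeric(1))
  zi <- numeric(length(nodes))
  for (m in unique(mem)) {
    idx <- which(mem == m)
    mu <- mean(kWithin[idx])
    sdv <- stats::sd(kWithin[idx])
    zi[idx] <- if (is.na(sdv) || sdv == 0) 0 else (kWithin[idx] - mu) / sdv
  }
  pi <- vapply(seq_along(nodes), function(i) {
    if (k[i] == 0) return(0)
    kis <- tapply(adj[i, ], mem, sum)
    1 - sum((kis / k[i])^2)
  }, numeric(1))
  data.frame(node = nodes, module = as.integer(mem),
             degree = unname(k), within_degree = kWithin,
             zi = zi, pi = pi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Topological role from Zi-Pi thresholds
#'
#' Role classification in the (Zi, Pi) plane with the conventional
#' thresholds: module hubs (Zi > 2.5, Pi <= 0.62) hold their own module
#' together; connectors (Zi <= 2.5, Pi > 0.62) link modules; network hubs
#' (Zi > 2.5, Pi > 0.62) do both; all remaining nodes are peripherals.
#' Boundary semantics are exact: Zi strictly greater than 2.5, Pi
#' inclusive at 0.62 for hubs and strictly greater for connectors.
#'
#' @param zi,pi Numeric vectors of equal length.
#' @param ziThreshold,piThreshold Role thresholds (defaults 2.5 and 0.62).
#' @return Character vector of roles.
#' @examples
#' classifyRole(3.0, 0.5)  # module_hub
#' classifyRole(2.5, 0.62) # peripheral
#' @export
classifyRole <- function(zi, pi, ziThreshold = 2.5, piThreshold = 0.62) {
  if (any(!is.finite(zi)) || any(!is.finite(pi)))
    msipError("zi and pi must be finite", "msipValidationError")
  ifelse(zi > ziThreshold,
         ifelse(pi > piThreshold, "network_hub", "module_hub"),
         ifelse(pi > piThreshold, "connector", "peripheral"))
}

#' Module membership with Zi-Pi roles for every node
#'
#' @param network An \linkS4class{AssociationNetwork} or igraph graph.
#' @param membership Named module vector; computed with
#'   \code{\link{detectModules}} when omitted.
#' @return A \linkS4class{ModulePartition}.
#' @export
nodeRoles <- function(network, membership = NULL) {
  if (is.null(membership)) membership <- detectModules(network)
  zp <- ziPi(network, membership)
  zp$role <- classifyRole(zp$zi, zp$pi)
  ModulePartition(zp[, c("node", "module", "zi", "pi", "role")])
}

#' Per-sample module abundances
#'
#' Sums the relative abundances of each module's member taxa within every
#' sample.
#'
#' @param membership Named module vector (node -> module id).
#' @param relAbund Taxa-by-samples relative abundance matrix containing all
#'   member taxa.
#' @return Modules-by-samples matrix of summed relative abundances.
#' @export
moduleAbundance <- function(membership, relAbund) {
  relAbund <- as.matrix(relAbund)
  missing <- setdiff(names(membership), rownames(relAbund))
  if (length(missing))
    msipError(paste0("taxa in the partition missing from the table: ",
                     paste(missing, collapse = ", ")),
              "msipValidationError")
  mods <- sort(unique(membership))
  out <- t(vapply(mods, function(m) {
    colSums(relAbund[names(membership)[membership == m], , drop = FALSE])
  }, numeric(ncol(relAbund))))
  rownames(out) <- paste0("module_", mods)
  out
}

#' Pearson correlation between module abundances and flux variables
#'
#' For every (module, flux variable) pair: Pearson's r and the two-sided p
#' value over paired samples. Pairs with fewer than 3 complete observations
#' error; zero-variance series yield \code{NA} (undefined correlation).
#'
#' @param moduleAbund Modules-by-samples matrix from
#'   \code{\link{moduleAbundance}}.
#' @param fluxTable Samples-by-variables data.frame or matrix of flux
#'   values; rows must match the columns of \code{moduleAbund}.
#' @return data.frame ordered by (module, variable): module, variable, r, p.
#' @export
moduleFluxCorrelation <- function(moduleAbund, fluxTable) {
  fluxTable <- as.data.frame(fluxTable)
  if (ncol(moduleAbund) != nrow(fluxTable))
    msipError("sample dimensions of module abundances and flux table differ",
              "msipValidationError")
  if (ncol(moduleAbund) < 3L)
    msipError("at least 3 paired observations are required",
              "msipValidationError")
  grid <- expand.grid(module = rownames(moduleAbund),
                      variable = names(fluxTable),
                      stringsAsFactors = FALSE)
  res <- mapply(function(m, v) {
    x <- moduleAbund[m, ]
    y <- fluxTable[[v]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }, grid$module, grid$variable)
  grid$r <- res[1, ]
  grid$p <- res[2, ]
  grid[order(grid$module, grid$variable), , drop = FALSE]
}
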