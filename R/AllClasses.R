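#' @import methods
NULL

# ---- PoolPartition ---------------------------------------------------------

#' PoolPartition: closed C or N compartment partition
#'
#' Holds the compartments of a carbon or nitrogen partition (amount and
#' percent of the day-0 total). Constructed by
#' \code{\link{partitionPercentages}}; the validity method enforces closure
#' (percentages sum to 100 within 0.1).
#'
#' @slot element \code{"C"} or \code{"N"}.
#' @slot table data.frame with columns compartment, amount, percent.
#' @aliases PoolPartition
#' @exportClass PoolPartition
setClass("PoolPartition",
         representation(element = "character", table = "data.frame"))

setValidity("PoolPartition", function(object) {
  msgs <- character(0)
  if (!object@element %in% c("C", "N"))
    msgs <- c(msgs, "element must be 'C' or 'N'")
  need <- c("compartment", "amount", "percent")
  if (!all(need %in% names(object@table)))
    msgs <- c(msgs, "table must have columns compartment, amount, percent")
  else {
    if (any(object@table$amount < 0))
      msgs <- c(msgs, "amounts must be non-negative")
    if (abs(sum(object@table$percent) - 100) > 0.1)
      msgs <- c(msgs, "percentages must sum to 100 within 0.1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname PoolPartition-class
#' @param element,table See slots.
#' @export
PoolPartition <- function(element, table) {
  new("PoolPartition", element = element, table = table)
}

#' @describeIn PoolPartition-class the compartment table.
#' @param x,object A \code{PoolPartition}.
#' @export
partitionTable <- function(x) x@table

#' @describeIn PoolPartition-class which element the partition describes.
#' @export
partitionElement <- function(x) x@element

setMethod("show", "PoolPartition", function(object) {
  cat(sprintf("PoolPartition (%s): %d compartments\n",
              object@element, nrow(object@table)))
  print(object@table, row.names = FALSE)
})

# ---- GradientProfile -------------------------------------------------------

#' GradientProfile: marker-gene abundance along a CsCl density gradient
#'
#' One sample's qPCR profile over the fractions of an isopycnic CsCl
#' gradient: fraction index (1-based; fraction 1 at one end of the
#' gradient), buoyant density in g/ml, and gene copy numbers. Densities
#' must be strictly monotone in the fraction index (a single orientation
#' per profile) and at least 5 fractions are required.
#'
#' @slot sampleId Sample identifier.
#' @slot gene Marker gene, one of \code{"pmoA"}, \code{"nifH"}, \code{"16S"}.
#' @slot fractions data.frame with columns fraction, density, copies.
#' @aliases GradientProfile
#' @exportClass GradientProfile
setClass("GradientProfile",
         representation(sampleId = "character", gene = "character",
                        fractions = "data.frame"))

setValidity("GradientProfile", function(object) {
  msgs <- character(0)
  if (!object@gene %in% c("pmoA", "nifH", "16S"))
    msgs <- c(msgs, "gene must be one of pmoA, nifH, 16S")
  f <- object@fractions
  need <- c("fraction", "density", "copies")
  if (!all(need %in% names(f)))
    return("fractions must have columns fraction, density, copies")
  if (nrow(f) < 5)
    msgs <- c(msgs, "at least 5 fractions are required")
  if (any(f$copies < 0))
    msgs <- c(msgs, "copies must be non-negative")
  d <- diff(f$density[order(f$fraction)])
  if (!(all(d > 0) || all(d < 0)))
    msgs <- c(msgs, "density must be strictly monotone in fraction index")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GradientProfile-class
#' @param sampleId,gene See slots.
#' @param fraction Integer fraction indices (1-based).
#' @param density Buoyant densities, g/ml.
#' @param copies Gene copies per fraction.
#' @export
GradientProfile <- function(sampleId, gene, fraction, density, copies) {
  f <- data.frame(fraction = as.integer(fraction), density = density,
                  copies = copies)
  f <- f[order(f$fraction), , drop = FALSE]
  rownames(f) <- NULL
  new("GradientProfile", sampleId = sampleId, gene = gene, fractions = f)
}

#' @describeIn GradientProfile-class the per-fraction table.
#' @param x,object A \code{GradientProfile}.
#' @export
gradientFractions <- function(x) x@fractions

#' @describeIn GradientProfile-class the sample identifier.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn GradientProfile-class the marker gene.
#' @export
markerGene <- function(x) x@gene

setMethod("show", "GradientProfile", function(object) {
  f <- object@fractions
  cat(sprintf("GradientProfile: sample '%s', gene %s, %d fractions (%.3f-%.3f g/ml)\n",
              object@sampleId, object@gene, nrow(f),
              min(f$density), max(f$density)))
})

# ---- AssociationNetwork ----------------------------------------------------

#' AssociationNetwork: undirected taxon co-occurrence network
#'
#' Wraps an undirected, unweighted \pkg{igraph} graph over taxa together
#' with a provenance record of the inference parameters (method label,
#' pseudocount, correlation threshold, stability settings, seed), so that
#' downstream module/role results remain traceable to how the network was
#' inferred.
#'
#' @slot graph An \pkg{igraph} graph (undirected, simple).
#' @slot provenance Named list of inference parameters.
#' @aliases AssociationNetwork
#' @exportClass AssociationNetwork
setClass("AssociationNetwork",
         representation(graph = "ANY", provenance = "list"))

setValidity("AssociationNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msgs <- character(0)
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g))) msgs <- c(msgs, "graph must have no self-edges")
  if (is.null(igraph::V(g)$name)) msgs <- c(msgs, "vertices must be named")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AssociationNetwork-class
#' @param graph,provenance See slots.
#' @export
AssociationNetwork <- function(graph, provenance = list()) {
  new("AssociationNetwork", graph = graph, provenance = provenance)
}

#' @describeIn AssociationNetwork-class the underlying igraph object.
#' @param x,object An \code{AssociationNetwork}.
#' @export
networkGraph <- function(x) x@graph

#' @describeIn AssociationNetwork-class the inference provenance record.
#' @export
networkProvenance <- function(x) x@provenance

#' @describeIn AssociationNetwork-class taxon (node) names.
#' @export
networkNodes <- function(x) igraph::V(x@graph)$name

setMethod("show", "AssociationNetwork", function(object) {
  g <- object@graph
  cat(sprintf("AssociationNetwork: %d nodes, %d edges (method: %s)\n",
              igraph::vcount(g), igraph::ecount(g),
              object@provenance$method %||% "unspecified"))
})

# ---- ModulePartition -------------------------------------------------------

#' ModulePartition: module membership and Zi-Pi node roles
#'
#' Per-node module assignment with within-module connectivity (Zi),
#' among-module connectivity (Pi) and the derived topological role.
#' Produced by \code{\link{nodeRoles}}.
#'
#' @slot table data.frame with columns node, module, zi, pi, role.
#' @aliases ModulePartition
#' @exportClass ModulePartition
setClass("ModulePartition", representation(table = "data.frame"))

setValidity("ModulePartition", function(object) {
  t <- object@table
  need <- c("node", "module", "zi", "pi", "role")
  if (!all(need %in% names(t)))
    return("table must have columns node, module, zi, pi, role")
  msgs <- character(0)
  if (anyDuplicated(t$node))
    msgs <- c(msgs, "each node must be assigned exactly one module")
  roles <- c("module_hub", "connector", "network_hub", "peripheral")
  if (!all(t$role %in% roles))
    msgs <- c(msgs, "unknown role label")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ModulePartition-class
#' @param table See slot.
#' @export
ModulePartition <- function(table) new("ModulePartition", table = table)

#' @describeIn ModulePartition-class the node-level table.
#' @param x,object A \code{ModulePartition}.
#' @export
roleTable <- function(x) x@table

#' @describeIn ModulePartition-class named integer vector of module ids.
#' @export
moduleMembership <- function(x) {
  structure(x@table$module, names = x@table$node)
}

setMethod("show", "ModulePartition", function(object) {
  t <- object@table
  cat(sprintf("ModulePartition: %d nodes in %d modules\n",
              nrow(t), length(unique(t$module))))
  print(table(role = t$role))
})
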