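#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd pt phyper p.adjust kmeans hclust cutree as.dist
#'   rnorm runif setNames aggregate lm coef resid var uniroot
#' @importFrom utils combn head
NULL

#' StageExperiment: abundances with a six-stage germination design
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass for
#' FPKM-scale expression or metabolite abundance matrices whose columns
#' carry a germination `stage` (integer, typically 1..6) and `replicate`
#' index in `colData`.
#'
#' Validity requires: a `stage` column of positive integers, at least two
#' samples per stage, unique row and column names, and no negative
#' abundances.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [StageExperiment()] for construction, [stages()],
#'   [stageMeans()].
#' @export
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"stage" %in% colnames(cd))
    return("colData must contain a 'stage' column")
  st <- cd$stage
  if (any(is.na(st)) || any(st != round(st)) || any(st < 1))
    return("'stage' must be positive integers")
  if (any(table(st) < 2))
    return("every stage needs at least 2 samples (replicates)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("feature (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample (column) names must be present and unique")
  a <- SummarizedExperiment::assay(object)
  if (any(a < 0, na.rm = TRUE))
    return("abundances must be non-negative")
  TRUE
})

#' Piecewise-linear water-uptake (imbibition) phase fit
#'
#' @slot breakpoints numeric, interior breakpoint times (minutes),
#'   strictly increasing.
#' @slot slopes numeric, per-segment slopes (g/min);
#'   `length(slopes) == length(breakpoints) + 1`.
#' @slot intercept numeric(1), fitted weight at the first time point's
#'   regression origin.
#' @slot rss numeric(1), residual sum of squares of the fit.
#' @slot fitted numeric, fitted weights at the observed times.
#' @slot time,weight the series the fit was computed on.
#' @export
setClass("PhaseFit",
  representation(breakpoints = "numeric", slopes = "numeric",
                 intercept = "numeric", rss = "numeric",
                 fitted = "numeric", time = "numeric", weight = "numeric"))

setValidity("PhaseFit", function(object) {
  if (length(object@breakpoints) &&
      any(diff(object@breakpoints) <= 0))
    return("breakpoints must be strictly increasing")
  if (length(object@slopes) != length(object@breakpoints) + 1L)
    return("need one more slope than breakpoints")
  TRUE
})

#' Stage-assignable K-means clustering of expression profiles
#'
#' @slot assignments named integer, gene -> cluster id (1..k).
#' @slot centroids matrix, k x 6 cluster centroids over stage-mean
#'   z-scores.
#' @slot clusterStage integer, per-cluster assigned stage (argmax of the
#'   centroid, earliest stage on ties).
#' @slot supercluster integer, per-cluster supercluster id (NA until
#'   [mergeSuperclusters()] is applied).
#' @slot wss numeric(1), total within-cluster sum of squares.
#' @export
setClass("ClusterSet",
  representation(assignments = "integer", centroids = "matrix",
                 clusterStage = "integer", supercluster = "integer",
                 wss = "numeric"))

#' Weighted coexpression network (adjacency + topological overlap)
#'
#' @slot genes character, gene ids in matrix order.
#' @slot beta numeric(1), soft-threshold power.
#' @slot adjacency matrix, unsigned adjacency `|cor|^beta`, unit diagonal.
#' @slot tom matrix, topological overlap, unit diagonal.
#' @export
setClass("CoexpressionNetwork",
  representation(genes = "character", beta = "numeric",
                 adjacency = "matrix", tom = "matrix"))

setValidity("CoexpressionNetwork", function(object) {
  A <- object@adjacency
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8)))
    return("adjacency must be symmetric")
  if (any(A < -1e-12 | A > 1 + 1e-12)) return("adjacency outside [0,1]")
  TRUE
})

#' Coexpression module set with eigengenes
#'
#' @slot labels named character, gene -> module color ("grey" =
#'   unassigned).
#' @slot eigengenes matrix, module x sample eigengene values (unit-norm
#'   rows).
#' @slot varExplained named numeric, per-module share of variance
#'   explained by the eigengene.
#' @export
setClass("ModuleSet",
  representation(labels = "character", eigengenes = "matrix",
                 varExplained = "numeric"))

#' Targeted correlation network (TCNA) graph
#'
#' Bipartite gene-metabolite edges for annotated enzyme-family members
#' plus a metabolite-metabolite pathway backbone. All computed
#' family edges are kept (so every member can be ranked); the `retained`
#' column marks edges passing the `|rho| >= rMin` display filter.
#'
#' @slot nodes data.frame with columns `id`, `type` ("gene" or
#'   "metabolite").
#' @slot edges data.frame with columns `source`, `target`, `type`,
#'   `role`, `rho`, `p`, `significant`, `sign`, `retained`.
#' @slot rMin,alpha numeric(1), thresholds the graph was built with.
#' @export
setClass("TCNAGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 rMin = "numeric", alpha = "numeric"))

setValidity("TCNAGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    key <- paste(e$source, e$target)
    if (anyDuplicated(key)) return("duplicate edges")
    bad <- e$significant & !(e$p <= object@alpha &
                             abs(e$rho) >= object@rMin)
    if (any(bad)) return("significant flag inconsistent with thresholds")
  }
  TRUE
})
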