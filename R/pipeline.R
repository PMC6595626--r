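pipelineDefaults <- function() {
  list(
    simulate = NULL,             # SimConfig fields, or NULL when inputs given
    inputs = NULL,               # directory written by writeGerminationDataset
    outputDir = "germ_out",
    seed = 1,
    de = list(mode = "reference", reference = 1, fcThreshold = 2,
              qThreshold = 0.8, pseudocount = 0.5),
    clustering = list(k = 24, nSuper = 9, nRestarts = 10,
                      rawScale = FALSE, tauSingleStage = 1.0),
    coexpression = list(beta = NULL, r2Target = 0.8, cutHeight = 0.25,
                        minSize = 30, rThreshold = 0.75, pThreshold = 0.05,
                        nHubs = 10, exportThreshold = 0.25),
    enrichment = list(alpha = 0.05, adjust = "none"),
    metabolomics = list(reference = 1, vipMin = 1.0, alpha = 0.05),
    tcna = list(rMin = 0.25, alpha = 0.05))
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(germError(sprintf("unknown config key(s): %s",
                           paste0(path, unknown, collapse = ", ")),
                   "germConfigError"))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        nm != "simulate")
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    else defaults[nm] <- user[nm]   # index form keeps explicit NULLs
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills defaults, rejects
#' unknown keys, and range-checks every threshold with a field-path
#' message. Normalization is idempotent. Exactly one of `simulate` /
#' `inputs` drives the run (an empty config defaults to simulation with
#' [simConfig()] defaults).
#'
#' @param config path to a YAML file, a nested list, or `NULL` for all
#'   defaults.
#' @return normalized config list (class `"PipelineConfig"`).
#' @export
validatePipelineConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(germError(sprintf("config file not found: %s", config),
                     "germConfigError"))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "PipelineConfig")) config <- unclass(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (!is.null(cfg$simulate) && !is.null(cfg$inputs))
    stop(germError("give either 'simulate' or 'inputs', not both",
                   "germConfigError"))
  chk <- function(val, ok, field) {
    if (!isTRUE(ok(val)))
      stop(germError(sprintf("config field '%s' out of range (value: %s)",
                             field, toString(val)), "germConfigError"))
  }
  chk(cfg$de$fcThreshold, function(v) v > 0, "de.fcThreshold")
  chk(cfg$de$qThreshold, function(v) v > 0 && v <= 1, "de.qThreshold")
  chk(cfg$clustering$k, function(v) v >= 1 && v == round(v),
      "clustering.k")
  chk(cfg$clustering$nSuper, function(v) v >= 1 && v == round(v),
      "clustering.nSuper")
  chk(cfg$coexpression$cutHeight, function(v) v > 0 && v < 1,
      "coexpression.cutHeight")
  chk(cfg$coexpression$minSize, function(v) v >= 2,
      "coexpression.minSize")
  chk(cfg$coexpression$rThreshold, function(v) v >= 0 && v <= 1,
      "coexpression.rThreshold")
  chk(cfg$enrichment$alpha, function(v) v >= 0 && v <= 1,
      "enrichment.alpha")
  chk(cfg$metabolomics$vipMin, function(v) v >= 0,
      "metabolomics.vipMin")
  chk(cfg$metabolomics$alpha, function(v) v >= 0 && v <= 1,
      "metabolomics.alpha")
  chk(cfg$tcna$rMin, function(v) v >= 0 && v <= 1, "tcna.rMin")
  chk(cfg$tcna$alpha, function(v) v >= 0 && v <= 1, "tcna.alpha")
  chk(cfg$seed, function(v) v == round(v), "seed")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full germination multi-omics pipeline
#'
#' Stages are executed in dependency order: simulate (or load) the
#' dataset, stage-wise differential expression, K-means stage clustering
#' plus supercluster merging and single-stage gene detection,
#' coexpression network with modules / eigengenes / module-stage
#' statistics / hubs, category enrichment of clusters and modules,
#' metabolite significance calls, and TCNA. All per-stage TSV/JSON
#' outputs plus a machine-readable `report.json` (paths, counts,
#' effective parameters, seed) are written under `outputDir`.
#'
#' @param config anything [validatePipelineConfig()] accepts.
#' @return (invisibly) the run report as a list.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- validatePipelineConfig(config)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, config = unclass(cfg),
                 counts = list(), outputs = list())
  note <- function(k, v) report$counts[[k]] <<- v
  outf <- function(...) {
    p <- file.path(cfg$outputDir, ...)
    report$outputs[[length(report$outputs) + 1L]] <<- p
    p
  }

  ## 1. data
  if (!is.null(cfg$inputs)) {
    ds <- readGerminationDataset(cfg$inputs)
  } else {
    sim <- cfg$simulate
    if (is.null(sim)) sim <- list()
    if (is.null(sim$seed)) sim$seed <- cfg$seed
    ds <- generateDataset(do.call(simConfig, sim))
    writeGerminationDataset(ds, outf("dataset"))
  }
  expr <- ds$expression
  note("genes", nrow(expr))
  note("metabolites", nrow(ds$metabolites))

  ## 2. differential expression
  de <- degComparisons(expr, mode = cfg$de$mode,
                       reference = cfg$de$reference,
                       fcThreshold = cfg$de$fcThreshold,
                       qThreshold = cfg$de$qThreshold,
                       pseudocount = cfg$de$pseudocount)
  for (nm in names(de))
    utils::write.table(de[[nm]]$table,
                       outf(sprintf("deg_%s.tsv", nm)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  degUnion <- unique(unlist(lapply(de, function(d) c(d$up, d$down))))
  note("deg_per_comparison",
       lapply(de, function(d) list(up = length(d$up),
                                   down = length(d$down))))
  note("deg_union", length(degUnion))
  if (length(degUnion) < max(cfg$clustering$k, cfg$coexpression$minSize))
    stop(germError("too few DEGs for clustering; lower k or add signal",
                   "germDataError"))

  ## 3. stage clustering
  prof <- preprocessProfiles(expr, degUnion,
                             scale = !cfg$clustering$rawScale)
  cl <- kmeansCluster(prof, k = cfg$clustering$k, seed = cfg$seed,
                      nRestarts = cfg$clustering$nRestarts)
  cl <- mergeSuperclusters(cl, nSuper = cfg$clustering$nSuper)
  writeClusters(cl, cfg$outputDir)
  outf("clusters.tsv"); outf("centroids.tsv")
  ssg <- singleStageGenes(expr, cfg$clustering$tauSingleStage)
  utils::write.table(
    data.frame(gene_id = names(ssg), stage = as.integer(ssg)),
    outf("single_stage_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  note("clusters", nrow(cl@centroids))
  note("single_stage_genes", length(ssg))

  ## 4. coexpression (on log2(FPKM + 1): correlations on the raw scale
  ## are dominated by the most abundant samples)
  cx <- log2(exprMatrix(expr)[degUnion, , drop = FALSE] + 1)
  beta <- cfg$coexpression$beta
  if (is.null(beta))
    beta <- pickSoftThreshold(cx,
                              r2Target = cfg$coexpression$r2Target)$beta
  net <- buildCoexpressionNetwork(cx, beta)
  labels <- detectModules(net, cutHeight = cfg$coexpression$cutHeight,
                          minSize = cfg$coexpression$minSize)
  ms <- moduleEigengenes(cx[rownames(net@adjacency), , drop = FALSE],
                         labels)
  stats <- if (nrow(ms@eigengenes))
    moduleStageCorrelation(ms, stages(expr)) else NULL
  if (!is.null(stats)) {
    stats$passes <- stats$r >= cfg$coexpression$rThreshold &
      stats$p <= cfg$coexpression$pThreshold
    utils::write.table(stats, outf("module_stage_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eg <- data.frame(module = rownames(ms@eigengenes), ms@eigengenes,
                     check.names = FALSE)
    utils::write.table(eg, outf("eigengenes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  modTab <- do.call(rbind, lapply(
    setdiff(unique(labels), "grey"), function(m) {
      gs <- names(labels)[labels == m]
      kw <- intramodularConnectivity(net, gs)
      hubs <- topHubs(kw, cfg$coexpression$nHubs)
      data.frame(gene_id = gs, module = m, k_within = kw[gs],
                 hub_rank = match(gs, hubs), stringsAsFactors = FALSE)
    }))
  if (!is.null(modTab))
    utils::write.table(modTab, outf("modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  exportNetwork(net@tom, cfg$coexpression$exportThreshold,
                cfg$outputDir, "network")
  outf("network.tsv"); outf("network.sif"); outf("network.graphml")
  note("beta", beta)
  note("modules", nrow(ms@eigengenes))

  ## 5. enrichment: per supercluster and per module
  enr <- list()
  a <- cl@assignments
  for (scid in sort(unique(cl@supercluster))) {
    gs <- names(a)[cl@supercluster[a] == scid]
    enr[[length(enr) + 1L]] <-
      enrichAll(gs, ds$annotation, alpha = cfg$enrichment$alpha,
                adjust = cfg$enrichment$adjust,
                setName = sprintf("SC%d", scid))
  }
  for (m in setdiff(unique(labels), "grey"))
    enr[[length(enr) + 1L]] <-
      enrichAll(names(labels)[labels == m], ds$annotation,
                alpha = cfg$enrichment$alpha,
                adjust = cfg$enrichment$adjust,
                setName = paste0("module_", m))
  enr <- do.call(rbind, enr)
  utils::write.table(enr, outf("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("enriched_significant", sum(enr$significant))

  ## 6. metabolomics
  mcalls <- callChangedMetabolites(ds$metabolites,
                                   reference = cfg$metabolomics$reference,
                                   vipMin = cfg$metabolomics$vipMin,
                                   alpha = cfg$metabolomics$alpha)
  utils::write.table(mcalls, outf("metabolite_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("metabolite_calls", sum(mcalls$significant))

  ## 7. TCNA
  tg <- buildTCNA(stageMeans(expr), stageMeans(ds$metabolites),
                  ds$enzymeMap, ds$pathwayEdges,
                  rMin = cfg$tcna$rMin, alpha = cfg$tcna$alpha)
  exportTCNA(tg, cfg$outputDir)
  outf("tcna_edges.tsv"); outf("tcna.sif"); outf("tcna.graphml")
  outf("candidate_genes.tsv")
  note("tcna_edges", nrow(tg@edges))
  note("tcna_significant", sum(tg@edges$significant))

  report$outputs <- unique(unlist(report$outputs))
  jsonlite::write_json(report, file.path(cfg$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
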