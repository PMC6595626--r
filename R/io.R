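# TSV writers keep full double precision (%.17g) so written matrices
# read back bit-identical.
writeMatrixTSV <- function(m, path, idCol) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idCol, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
}

readMatrixTSV <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

sampleStages <- function(sampleIds) {
  st <- as.integer(sub("^S(\\d+)R\\d+$", "\\1", sampleIds))
  if (any(is.na(st)))
    stop(germError("sample ids must follow the S<stage>R<rep> convention",
                   "germDataError"))
  st
}

#' Write a generated dataset to TSV/JSON files
#'
#' Writes `expression.tsv`, `metabolites.tsv` (sample columns named
#' `S<stage>R<rep>`), `annotation.tsv`, `enzyme_map.tsv`,
#' `pathway_edges.tsv`, `truth.json`, and a `manifest.json` echoing the
#' seed, the configuration, and per-file row/column counts.
#'
#' @param dataset a [generateDataset()] result.
#' @param dir writable output directory (created if absent).
#' @return (invisibly) the manifest as a list.
#' @export
writeGerminationDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  put <- function(name, rows, cols) {
    files[[name]] <<- list(rows = rows, cols = cols)
  }
  em <- SummarizedExperiment::assay(dataset$expression)
  writeMatrixTSV(em, file.path(dir, "expression.tsv"), "gene_id")
  put("expression.tsv", nrow(em), ncol(em))
  mm <- SummarizedExperiment::assay(dataset$metabolites)
  writeMatrixTSV(mm, file.path(dir, "metabolites.tsv"), "metabolite_id")
  put("metabolites.tsv", nrow(mm), ncol(mm))
  for (nm in c("annotation", "enzymeMap", "pathwayEdges")) {
    fn <- c(annotation = "annotation.tsv", enzymeMap = "enzyme_map.tsv",
            pathwayEdges = "pathway_edges.tsv")[[nm]]
    utils::write.table(dataset[[nm]], file.path(dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    put(fn, nrow(dataset[[nm]]), ncol(dataset[[nm]]))
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put("truth.json", length(dataset$truth), NA)
  manifest <- list(seed = dataset$config$seed,
                   config = unclass(dataset$config), files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [writeGerminationDataset()]
#'
#' @param dir directory containing the files.
#' @return list with the same structure as [generateDataset()] output
#'   (the `config` element is restored from the manifest).
#' @export
readGerminationDataset <- function(dir) {
  em <- readMatrixTSV(file.path(dir, "expression.tsv"))
  mm <- readMatrixTSV(file.path(dir, "metabolites.tsv"))
  expression <- StageExperiment(em, sampleStages(colnames(em)),
                                assayName = "fpkm")
  metabolites <- StageExperiment(mm, sampleStages(colnames(mm)))
  rd <- function(fn) utils::read.delim(file.path(dir, fn),
                                       stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  list(expression = expression, metabolites = metabolites,
       annotation = rd("annotation.tsv"),
       enzymeMap = rd("enzyme_map.tsv"),
       pathwayEdges = rd("pathway_edges.tsv"),
       truth = truth, config = manifest$config)
}
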