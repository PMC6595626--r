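#' Construct a StageExperiment
#'
#' Wraps a feature x sample abundance matrix together with its stage
#' design. Column names follow the `S<stage>R<replicate>` convention when
#' not supplied.
#'
#' @param abundance numeric matrix, features (genes or metabolites) in
#'   rows, samples in columns; non-negative.
#' @param stage integer vector, one germination stage index per column.
#' @param replicate optional integer vector of within-stage replicate
#'   indices; derived from column order when `NULL`.
#' @param assayName name for the single assay (default `"abundance"`).
#' @return A [StageExperiment-class] object.
#' @examples
#' m <- matrix(rexp(5 * 12), 5, 12,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' se <- StageExperiment(m, stage = rep(1:6, each = 2))
#' stages(se)
#' @export
StageExperiment <- function(abundance, stage, replicate = NULL,
                            assayName = "abundance") {
  abundance <- as.matrix(abundance)
  stage <- as.integer(stage)
  if (length(stage) != ncol(abundance))
    stop(germError("one stage per sample required", "germDataError"))
  if (is.null(replicate)) {
    replicate <- integer(length(stage))
    for (s in unique(stage)) replicate[stage == s] <- seq_len(sum(stage == s))
  }
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("S%dR%d", stage, replicate)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("f%04d", seq_len(nrow(abundance)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(abundance), assayName),
    colData = S4Vectors::DataFrame(stage = stage, replicate = replicate,
                                   row.names = colnames(abundance)))
  methods::new("StageExperiment", se)
}

#' @describeIn StageExperiment stage index of every sample.
#' @param x a `StageExperiment`.
#' @export
stages <- function(x) SummarizedExperiment::colData(x)$stage

#' Per-stage arithmetic means of abundances
#'
#' Averages replicate columns within each stage, on the original
#' (untransformed) scale.
#'
#' @param x a [StageExperiment-class], or a numeric matrix (features x
#'   samples) if `stage` is given.
#' @param stage stage index per column; ignored for `StageExperiment`
#'   input.
#' @return matrix, features x stages (columns named by stage, ascending).
#' @export
stageMeans <- function(x, stage = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    stage <- stages(x)
    x <- SummarizedExperiment::assay(x)
  }
  if (is.null(stage)) stop(germError("stage design required", "germDataError"))
  x <- as.matrix(x)
  lv <- sort(unique(stage))
  out <- vapply(lv, function(s) rowMeans(x[, stage == s, drop = FALSE]),
                numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), as.character(lv)))
  out
}

setMethod("show", "StageExperiment", function(object) {
  st <- stages(object)
  cat("StageExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  stages:", paste(sprintf("%d(n=%d)", sort(unique(st)),
                                 as.integer(table(st))), collapse = " "),
      "\n")
})

# typed conditions used across the package
germError <- function(msg, class) {
  structure(class = c(class, "germError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
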