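#' FPKM normalization of a count matrix
#'
#' `FPKM = 1e9 * c / (N * L)` for a count `c`, library size `N`
#' (total mapped fragments) and transcript length `L` in bp.
#'
#' @param counts integer gene x sample matrix of fragment counts.
#' @param geneLengths transcript lengths (bp), one per gene, all > 0.
#' @param librarySizes total mapped fragments per sample, all > 0.
#' @param stage optional stage index per sample; when given, a
#'   [StageExperiment-class] is returned, otherwise a plain matrix.
#' @return FPKM matrix or `StageExperiment` (assay `"fpkm"`).
#' @export
computeFPKM <- function(counts, geneLengths, librarySizes, stage = NULL) {
  counts <- as.matrix(counts)
  if (any(geneLengths <= 0))
    stop(germError("zero or negative gene length", "germDataError"))
  if (any(librarySizes <= 0))
    stop(germError("library sizes must be positive", "germDataError"))
  fpkm <- 1e9 * sweep(counts, 2, librarySizes, "/") / geneLengths
  if (is.null(stage)) return(fpkm)
  StageExperiment(fpkm, stage, assayName = "fpkm")
}

#' Empirical within-stage noise distribution for two compared stages
#'
#' For every unordered replicate pair within each of the two stages and
#' every gene, one `(|M|, D)` point is recorded, where
#' `M = log2((x_i + c) / (x_j + c))` and `D = |x_i - x_j|` after
#' pseudocount `c`. Points are pooled across genes and both stages and
#' form the null cloud against which signal `(|M|, D)` pairs are scored.
#'
#' @param expr a [StageExperiment-class] (FPKM scale).
#' @param stageA,stageB the two stages being compared (each needs >= 2
#'   replicates).
#' @param pseudocount added to all values before ratios (default 0.5;
#'   keeps M finite and symmetric).
#' @return data.frame with columns `absM`, `D`, one row per (gene,
#'   replicate pair).
#' @export
noiseDistribution <- function(expr, stageA, stageB, pseudocount = 0.5) {
  st <- stages(expr)
  x <- SummarizedExperiment::assay(expr)
  pts <- list()
  for (s in c(stageA, stageB)) {
    cols <- which(st == s)
    if (length(cols) < 2)
      stop(germError(sprintf("stage %s has fewer than 2 replicates", s),
                     "germDataError"))
    prs <- utils::combn(cols, 2)
    for (j in seq_len(ncol(prs))) {
      xi <- x[, prs[1, j]] + pseudocount
      xj <- x[, prs[2, j]] + pseudocount
      pts[[length(pts) + 1L]] <-
        data.frame(absM = abs(log2(xi / xj)), D = abs(xi - xj))
    }
  }
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}

#' Differential-expression probability table for one stage comparison
#'
#' Per gene, `M` is the log2 ratio and `D` the absolute difference of the
#' two stage means (pseudocount added), and the probability of
#' differential expression is the fraction of noise points strictly
#' dominated by the signal:
#' `q = #\{|M_noise| < |M| and D_noise < D\} / #noise` (ties count as not
#' dominated).
#'
#' @inheritParams noiseDistribution
#' @param noise the pooled noise cloud from [noiseDistribution()]; must
#'   be non-empty.
#' @return data.frame (one row per gene): `gene_id`, `M`, `D`, `q`,
#'   `fold_change` (`2^|M|`), `direction` (`"up"` iff `M > 0`, i.e.
#'   higher in `stageA`), and `comparison`.
#' @export
deProbability <- function(expr, stageA, stageB, noise,
                          pseudocount = 0.5) {
  if (is.null(noise) || nrow(noise) == 0)
    stop(germError("noise distribution is empty", "germDataError"))
  st <- stages(expr)
  x <- SummarizedExperiment::assay(expr)
  mA <- rowMeans(x[, st == stageA, drop = FALSE]) + pseudocount
  mB <- rowMeans(x[, st == stageB, drop = FALSE]) + pseudocount
  M <- log2(mA / mB)
  D <- abs(mA - mB)
  # strict dominance count via sorted noise |M| and a rank trick would
  # be O(n log n); the direct comparison is clear and fast enough here
  nm <- noise$absM; nd <- noise$D
  q <- vapply(seq_along(M), function(i)
    mean(nm < abs(M[i]) & nd < D[i]), numeric(1))
  data.frame(gene_id = rownames(x), M = M, D = D, q = q,
             fold_change = 2^abs(M),
             direction = ifelse(M > 0, "up", "down"),
             comparison = sprintf("stage%s_vs_stage%s", stageA, stageB),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from a probability table
#'
#' A gene is called iff `fold_change >= fcThreshold` AND
#' `q >= qThreshold` (both inclusive, as printed in the originating
#' criteria "fold change >= 2 and p >= 0.8").
#'
#' @param table a [deProbability()] table.
#' @param fcThreshold fold-change threshold (>= 1).
#' @param qThreshold probability threshold in (0, 1].
#' @return list with elements `up`, `down` (gene-id vectors) and `table`
#'   (the input with an added logical `called` column).
#' @export
callDEGs <- function(table, fcThreshold = 2, qThreshold = 0.8) {
  if (fcThreshold <= 0 || qThreshold <= 0)
    stop(germError("thresholds must be positive", "germConfigError"))
  called <- table$fold_change >= fcThreshold & table$q >= qThreshold
  table$called <- called
  list(up = table$gene_id[called & table$direction == "up"],
       down = table$gene_id[called & table$direction == "down"],
       table = table)
}

#' Run all stage-wise DE comparisons
#'
#' Either every stage against the reference stage (default: stage 1, the
#' dry seed) or successive stages.
#'
#' @inheritParams noiseDistribution
#' @param mode `"reference"` or `"successive"`.
#' @param reference reference stage for `mode = "reference"`.
#' @param fcThreshold,qThreshold passed to [callDEGs()].
#' @return named list of [callDEGs()] results, one per comparison.
#' @export
degComparisons <- function(expr, mode = c("reference", "successive"),
                           reference = 1, fcThreshold = 2,
                           qThreshold = 0.8, pseudocount = 0.5) {
  mode <- match.arg(mode)
  st <- sort(unique(stages(expr)))
  pairs <- if (mode == "reference")
    lapply(setdiff(st, reference), function(s) c(s, reference))
  else lapply(seq_len(length(st) - 1L), function(i) c(st[i + 1], st[i]))
  out <- lapply(pairs, function(p) {
    nz <- noiseDistribution(expr, p[1], p[2], pseudocount)
    callDEGs(deProbability(expr, p[1], p[2], nz, pseudocount),
             fcThreshold, qThreshold)
  })
  names(out) <- vapply(pairs, function(p)
    sprintf("stage%s_vs_stage%s", p[1], p[2]), character(1))
  out
}
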