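#' Standardized stage-mean profiles for clustering
#'
#' Per gene: stage means of `log2(FPKM + 1)`, then z-scored across the
#' six stages. Zero-variance (flat) genes cannot be standardized and are
#' dropped with a warning. Clustering on z-scores rather than raw FPKM
#' keeps Euclidean K-means from being dominated by expression magnitude;
#' raw-scale profiles are available via `scale = FALSE`.
#'
#' @param expr a [StageExperiment-class] (FPKM scale).
#' @param genes gene ids to profile (e.g. the DEG union); default all.
#' @param scale z-score across stages (default `TRUE`).
#' @return matrix, genes x stages.
#' @export
preprocessProfiles <- function(expr, genes = rownames(expr),
                               scale = TRUE) {
  if (length(genes) == 0)
    stop(germError("empty gene set", "germDataError"))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop(germError(sprintf("%d genes absent from the matrix",
                           length(missing)), "germDataError"))
  sm <- stageMeans(expr)[genes, , drop = FALSE]
  prof <- log2(sm + 1)
  if (!scale) return(prof)
  sds <- apply(prof, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    prof <- prof[sds > 0, , drop = FALSE]
  }
  t(apply(prof, 1, function(v) (v - mean(v)) / sd(v)))
}

#' Euclidean K-means clustering of stage profiles
#'
#' Best of `nRestarts` K-means solutions by total within-cluster sum of
#' squares, deterministic given `seed`. `k = nrow(profiles)` returns the
#' trivial one-gene-per-cluster solution.
#'
#' @param profiles genes x stages matrix from [preprocessProfiles()].
#' @param k number of clusters (default 24).
#' @param seed integer seed.
#' @param nRestarts random restarts (default 10).
#' @return A [ClusterSet-class]; cluster stages are assigned via
#'   [assignClusterStage()], superclusters are `NA` until
#'   [mergeSuperclusters()].
#' @export
kmeansCluster <- function(profiles, k = 24, seed = 1, nRestarts = 10) {
  n <- nrow(profiles)
  if (n < k)
    stop(germError(sprintf("%d genes < k = %d clusters", n, k),
                   "germDataError"))
  if (n == k) {
    assign <- setNames(seq_len(n), rownames(profiles))
    cent <- profiles
  } else {
    set.seed(seed)
    km <- tryCatch(
      kmeans(profiles, centers = k, nstart = nRestarts, iter.max = 100),
      error = function(e)
        kmeans(profiles, centers = k, nstart = nRestarts,
               iter.max = 100, algorithm = "Lloyd"))
    assign <- setNames(km$cluster, rownames(profiles))
    cent <- km$centers
  }
  stg <- vapply(seq_len(k), function(i)
    assignClusterStage(cent[i, ]), integer(1))
  wss <- sum(vapply(seq_len(k), function(i) {
    rows <- profiles[assign == i, , drop = FALSE]
    sum(sweep(rows, 2, cent[i, ])^2)
  }, numeric(1)))
  methods::new("ClusterSet",
               assignments = setNames(as.integer(assign), names(assign)),
               centroids = cent, clusterStage = stg,
               supercluster = rep(NA_integer_, k), wss = wss)
}

#' Assign a cluster to its peak stage
#'
#' The stage with the highest centroid value; exact ties go to the
#' earliest stage, with a message.
#'
#' @param centroid numeric of length 6.
#' @return integer stage in 1..6.
#' @export
assignClusterStage <- function(centroid) {
  if (length(centroid) != 6)
    stop(germError("centroid must have one value per stage (6)",
                   "germDataError"))
  mx <- max(centroid)
  hits <- which(centroid == mx)
  if (length(hits) > 1)
    message(sprintf("centroid peak tie at stages %s; using stage %d",
                    paste(hits, collapse = ","), hits[1]))
  as.integer(hits[1])
}

#' Merge K-means clusters into superclusters
#'
#' Average-linkage hierarchical clustering of cluster centroids under the
#' correlation distance `1 - cor`, cut to exactly `nSuper` groups.
#' Correlation distance makes the merge invariant to centroid scaling;
#' zero-variance centroids are treated as uncorrelated (`cor = 0`).
#'
#' @param clusters a [ClusterSet-class].
#' @param nSuper number of superclusters (default 9).
#' @return the `ClusterSet` with its `supercluster` slot filled.
#' @export
mergeSuperclusters <- function(clusters, nSuper = 9) {
  k <- nrow(clusters@centroids)
  if (nSuper < 1)
    stop(germError("nSuper must be >= 1", "germConfigError"))
  if (nSuper > k)
    stop(germError("nSuper exceeds the number of clusters",
                   "germConfigError"))
  cc <- safeCor(t(clusters@centroids))
  hc <- hclust(as.dist(1 - cc), method = "average")
  clusters@supercluster <- as.integer(cutree(hc, k = nSuper))
  clusters
}

# Pearson correlation with zero-variance columns defined as cor = 0
safeCor <- function(m) {
  sds <- apply(m, 2, sd)
  cc <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
    diag(cc) <- 1
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Genes expressed at exactly one stage
#'
#' Stage-mean FPKM at or above `tau` in exactly one stage and below
#' `tau` in all others (e.g. stage-restricted transcription factors).
#'
#' @param expr a [StageExperiment-class].
#' @param tau expression threshold in FPKM (default 1.0).
#' @return named integer: the single expressed stage, named by gene id.
#' @export
singleStageGenes <- function(expr, tau = 1.0) {
  sm <- stageMeans(expr)
  above <- sm >= tau
  sel <- rowSums(above) == 1L
  setNames(vapply(which(sel), function(i) which(above[i, ])[1],
                  integer(1)),
           rownames(sm)[sel])
}

setMethod("show", "ClusterSet", function(object) {
  k <- nrow(object@centroids)
  cat("ClusterSet:", length(object@assignments), "genes in", k,
      "clusters\n")
  cat("  cluster stages:",
      paste(object@clusterStage, collapse = " "), "\n")
  if (!all(is.na(object@supercluster)))
    cat("  superclusters:",
        paste(object@supercluster, collapse = " "), "\n")
  cat("  total WSS:", signif(object@wss, 5), "\n")
})

#' Export a ClusterSet as TSV
#'
#' Writes `clusters.tsv` (gene_id, cluster, stage, supercluster) and
#' `centroids.tsv`.
#'
#' @param clusters a [ClusterSet-class].
#' @param dir output directory.
#' @export
writeClusters <- function(clusters, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- clusters@assignments
  df <- data.frame(gene_id = names(a), cluster = as.integer(a),
                   stage = clusters@clusterStage[a],
                   supercluster = clusters@supercluster[a])
  utils::write.table(df, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cent <- data.frame(cluster = seq_len(nrow(clusters@centroids)),
                     clusters@centroids, check.names = FALSE)
  utils::write.table(cent, file.path(dir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("clusters.tsv", "centroids.tsv")))
}
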